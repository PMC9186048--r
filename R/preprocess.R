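new_preprocess_report <- function(rule, removed, input_n, imputed_cells = 0L,
                                  params = list()) {
  structure(list(rules = list(list(rule = rule, removed = removed,
                                   n_removed = length(removed),
                                   n_input = input_n,
                                   n_retained = input_n - length(removed),
                                   imputed_cells = imputed_cells,
                                   params = params))),
            class = "preprocess_report")
}

#' Combine preprocessing reports from successive steps
#' @param ... `preprocess_report` objects in pipeline order
#' @return a single `preprocess_report`
#' @export
combine_reports <- function(...) {
  reps <- list(...)
  structure(list(rules = do.call(c, lapply(reps, `[[`, "rules"))),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:\n")
  for (r in x$rules)
    cat(sprintf("  %-22s %5d -> %5d features (-%d%s)\n", r$rule, r$n_input,
                r$n_retained, r$n_removed,
                if (r$imputed_cells > 0)
                  sprintf(", %d cells imputed", r$imputed_cells) else ""))
  invisible(x)
}

#' Blank-channel filtering
#'
#' A feature is retained only if, in every study sample where it was
#' observed, its intensity is at least `ratio` times the summarised blank
#' intensity (a feature not detected in the blank has blank intensity 0 and
#' always passes). Missing study cells are left to the missingness rule,
#' which runs next in the pipeline.
#'
#' @param table study `feature_table` (raw intensities)
#' @param blanks blank-channel `feature_table`; must cover every feature of
#'   `table` (a feature absent from the blank table is an error, never a
#'   silent pass)
#' @param ratio required sample/blank ratio (default 1.5)
#' @param summary how blank replicates are aggregated: "mean" (default) or
#'   "max"
#' @return list with the filtered `table` and a `report`
#' @export
blank_filter <- function(table, blanks, ratio = 1.5,
                         summary = c("mean", "max")) {
  summary <- match.arg(summary)
  stopifnot(ratio > 0)
  missing_blank <- setdiff(feature_ids(table), feature_ids(blanks))
  if (length(missing_blank))
    stop("feature(s) absent from blank table: ",
         paste(utils::head(missing_blank, 5), collapse = ", "),
         if (length(missing_blank) > 5) ", ...")
  b <- blanks$intensities[match(feature_ids(table), feature_ids(blanks)), ,
                          drop = FALSE]
  b[is.na(b)] <- 0   # not detected in blank
  bsum <- if (summary == "mean") rowMeans(b) else apply(b, 1, max)
  thr <- ratio * bsum
  ok <- vapply(seq_len(nrow(table$intensities)), function(i) {
    x <- table$intensities[i, ]
    all(x[!is.na(x)] >= thr[i])
  }, logical(1))
  removed <- feature_ids(table)[!ok]
  out <- ft_keep_features(table, feature_ids(table)[ok])
  out <- ft_log_step(out, "blank_filter", ratio = ratio, summary = summary)
  list(table = out,
       report = new_preprocess_report("blank_filter", removed,
                                      nrow(table$intensities),
                                      params = list(ratio = ratio,
                                                    summary = summary)))
}

#' Missingness filtering and half-minimum imputation
#'
#' Features missing in at least `drop_threshold` of the samples are removed
#' (exactly at the threshold counts as removed); remaining missing cells are
#' replaced by half the per-feature minimum observed intensity. Observed
#' cells are never altered.
#'
#' @param table a `feature_table` (raw intensities)
#' @param drop_threshold missingness fraction in (0, 1]
#' @return list with the filtered+imputed `table` and a `report`
#' @export
missingness_filter_impute <- function(table, drop_threshold = 0.5) {
  stopifnot(drop_threshold > 0, drop_threshold <= 1)
  m <- table$intensities
  frac_missing <- rowMeans(is.na(m))
  drop <- frac_missing >= drop_threshold | frac_missing == 1
  removed <- feature_ids(table)[drop]
  out <- ft_keep_features(table, feature_ids(table)[!drop])
  mm <- out$intensities
  n_imputed <- 0L
  for (i in which(rowSums(is.na(mm)) > 0)) {
    fill <- 0.5 * min(mm[i, ], na.rm = TRUE)
    nai <- is.na(mm[i, ])
    mm[i, nai] <- fill
    n_imputed <- n_imputed + sum(nai)
  }
  out$intensities <- mm
  out <- ft_log_step(out, "missingness_filter_impute",
                     drop_threshold = drop_threshold)
  list(table = out,
       report = new_preprocess_report("missingness_filter_impute", removed,
                                      nrow(m), imputed_cells = n_imputed,
                                      params = list(drop_threshold =
                                                      drop_threshold)))
}

#' Detection-fraction filtering
#'
#' Retains features whose detected (non-missing) sample fraction is strictly
#' greater than `min_detected` — the ">80% of study samples" rule of the
#' primary human screen, or ">20%" for the sensitivity screen. Missing cells
#' are left missing (no imputation in this path).
#'
#' @param table a `feature_table`
#' @param min_detected detection fraction in \[0, 1\]
#' @return list with the filtered `table` and a `report`
#' @export
detection_filter <- function(table, min_detected = 0.8) {
  stopifnot(min_detected >= 0, min_detected <= 1)
  frac <- rowMeans(!is.na(table$intensities))
  keep <- frac > min_detected
  removed <- feature_ids(table)[!keep]
  out <- ft_keep_features(table, feature_ids(table)[keep])
  out <- ft_log_step(out, "detection_filter", min_detected = min_detected)
  list(table = out,
       report = new_preprocess_report("detection_filter", removed,
                                      nrow(table$intensities),
                                      params = list(min_detected =
                                                      min_detected)))
}

#' Generalized log transformation
#'
#' Variance-stabilising transform `glog(x) = log2((x + sqrt(x^2 + a^2)) / 2)`
#' applied cell-wise; `glog(0) = log2(a/2)` and `glog(x) -> log2(x)` for
#' `x >> a`. The scale parameter defaults to the smallest positive observed
#' intensity in the table and is recorded in the table's provenance.
#'
#' @param table a `feature_table` with non-negative intensities
#' @param a positive scale parameter, or `NULL`/"auto" for the per-table
#'   minimum positive intensity
#' @return the transformed `feature_table`
#' @export
glog_transform <- function(table, a = NULL) {
  m <- table$intensities
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities; glog needs x >= 0")
  if (is.null(a) || identical(a, "auto")) {
    pos <- m[!is.na(m) & m > 0]
    if (!length(pos)) stop("no positive intensities to set glog scale from")
    a <- min(pos)
  }
  stopifnot(is.numeric(a), a > 0)
  table$intensities[] <- log2((m + sqrt(m^2 + a^2)) / 2)
  ft_log_step(table, "glog_transform", a = a)
}

glog_inverse <- function(y, a) {
  u <- 2^y
  u - a^2 / (4 * u)
}

#' Location-scale batch standardisation
#'
#' Per feature, each batch's values are centred and scaled to the pooled
#' mean and SD, so after adjustment every batch has the pooled mean (and SD,
#' when the batch SD is positive). This is a deliberate simplification of
#' empirical-Bayes batch correction: no shrinkage of the per-batch location
#' and scale estimates is performed. Apply on the glog scale.
#'
#' @param table a `feature_table` (glog scale)
#' @param meta sample metadata with a `batch` column covering the table's
#'   samples; every batch must have at least 2 samples
#' @return the adjusted `feature_table` (identical input when only one batch
#'   is present)
#' @export
batch_adjust <- function(table, meta) {
  meta <- meta_align(meta, table)
  batch <- as.factor(meta$batch)
  if (nlevels(batch) < 2L) return(table)
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("singleton batch(es): ", paste(names(sizes)[sizes < 2], collapse = ", "),
         "; merge them before adjustment")
  m <- table$intensities
  pooled_mean <- rowMeans(m, na.rm = TRUE)
  pooled_sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  for (b in levels(batch)) {
    j <- which(batch == b)
    mb <- rowMeans(m[, j, drop = FALSE], na.rm = TRUE)
    sb <- apply(m[, j, drop = FALSE], 1, stats::sd, na.rm = TRUE)
    scale <- ifelse(sb > 0 & pooled_sd > 0, pooled_sd / sb, 1)
    m[, j] <- (m[, j, drop = FALSE] - mb) * scale + pooled_mean
  }
  table$intensities <- m
  ft_log_step(table, "batch_adjust", n_batches = nlevels(batch))
}

#' Run the fixed preprocessing pipeline
#'
#' Worm mode: blank_filter -> missingness_filter_impute -> glog_transform
#' (no batch adjustment; none was needed for the worm data). Human mode:
#' detection_filter -> glog_transform -> batch_adjust (the human screen
#' retains well-detected features rather than imputing, and was acquired in
#' batches). The order is fixed and recorded in provenance.
#'
#' @param table raw `feature_table`
#' @param blanks blank-channel table (worm mode)
#' @param meta sample metadata (human mode, for batch)
#' @param config a [run_config()]
#' @param mode "worm" or "human"
#' @return list with the processed `table` and the combined `report`
#' @export
preprocess_pipeline <- function(table, blanks = NULL, meta = NULL,
                                config = run_config(),
                                mode = c("worm", "human")) {
  mode <- match.arg(mode)
  if (mode == "worm") {
    stopifnot(!is.null(blanks))
    s1 <- blank_filter(table, blanks, ratio = config$blank_ratio,
                       summary = config$blank_summary)
    s2 <- missingness_filter_impute(s1$table, config$drop_missing)
    out <- glog_transform(s2$table, config$glog_a)
    list(table = out, report = combine_reports(s1$report, s2$report))
  } else {
    s1 <- detection_filter(table, config$detect_min)
    out <- glog_transform(s1$table, config$glog_a)
    if (!is.null(meta)) out <- batch_adjust(out, meta)
    list(table = out, report = s1$report)
  }
}
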