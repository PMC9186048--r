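#' Construct a feature table
#'
#' A `feature_table` holds an untargeted LC-HRMS feature matrix: one row per
#' m/z x retention-time feature, one column per sample. Intensities are raw
#' detector units until [glog_transform()] is applied; missing values (`NA`)
#' mean "not detected", zeros are observed values.
#'
#' @param features data.frame with columns `feature_id` (unique), `mz`
#'   (Th, > 0), `rt` (seconds, >= 0) and optionally `mode` (acquisition
#'   context, e.g. `"HILIC-pos"`). If `feature_id` is absent it is derived
#'   as `M<mz>T<rt>`.
#' @param intensities numeric matrix, `nrow(features)` x number of samples,
#'   non-negative or `NA`. Column names are the sample identifiers.
#' @param provenance list of processing records (transforms applied, filter
#'   settings); appended to by the preprocessing functions.
#' @return An object of class `feature_table` with elements `features`,
#'   `intensities` and `provenance`.
#' @examples
#' ft <- feature_table(
#'   data.frame(mz = c(129.0661, 334.1410), rt = c(89, 86)),
#'   matrix(c(1e5, 2e5, 3e5, 4e5), nrow = 2,
#'          dimnames = list(NULL, c("s1", "s2"))))
#' ft
#' @export
feature_table <- function(features, intensities, provenance = list()) {
  stopifnot(is.data.frame(features))
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(features$feature_id)) {
    features$feature_id <- sprintf("M%.4fT%.0f", features$mz, features$rt)
  }
  features$feature_id <- as.character(features$feature_id)
  if (is.null(features$mode)) features$mode <- NA_character_
  rownames(features) <- NULL
  rownames(intensities) <- features$feature_id
  x <- structure(list(features = features, intensities = intensities,
                      provenance = provenance),
                 class = "feature_table")
  validate_feature_table(x)
}

validate_feature_table <- function(x) {
  f <- x$features
  m <- x$intensities
  if (nrow(f) == 0L) stop("feature table is empty")
  if (nrow(m) != nrow(f))
    stop("intensity matrix has ", nrow(m), " rows but ", nrow(f), " features")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("sample identifiers must be present and unique")
  if (anyDuplicated(f$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  if (!all(f$mz > 0)) stop("all m/z values must be > 0")
  if (!all(f$rt >= 0)) stop("all retention times must be >= 0")
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  m/z range %.4f-%.4f, RT range %.0f-%.0f s\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt)))
  na <- sum(is.na(x$intensities))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", na,
              100 * na / length(x$intensities)))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Sample identifiers of a feature table
#' @param x a `feature_table`
#' @return character vector of sample ids (column order)
#' @export
sample_ids <- function(x) colnames(x$intensities)

#' Feature identifiers of a feature table
#' @param x a `feature_table`
#' @return character vector of feature ids (row order)
#' @export
feature_ids <- function(x) x$features$feature_id

# Subset to a set of feature ids (order preserved from the table).
ft_keep_features <- function(x, keep_ids) {
  idx <- x$features$feature_id %in% keep_ids
  feature_table(x$features[idx, , drop = FALSE],
                x$intensities[idx, , drop = FALSE],
                provenance = x$provenance)
}

# Record a processing step in the table's provenance.
ft_log_step <- function(x, step, ...) {
  x$provenance <- c(x$provenance, list(c(list(step = step), list(...))))
  x
}

#' Validate a sample metadata table
#'
#' Checks a metadata data.frame against a feature table: every study sample
#' column must have a metadata row, `sample_id` must be unique, and `p_tau`
#' (if present) must be non-negative.
#'
#' @param meta data.frame with at least `sample_id`; typical columns are
#'   `role` (study/blank/qc), `diagnosis`, `p_tau` (pg/mL), `age`, `sex`,
#'   `batch`, `strain`, `treatment`.
#' @param table optional `feature_table` whose samples must be covered.
#' @return `meta`, invisibly validated (with `role` defaulted to "study").
#' @export
validate_metadata <- function(meta, table = NULL) {
  stopifnot(is.data.frame(meta), !is.null(meta$sample_id))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (is.null(meta$role)) meta$role <- "study"
  if (!is.null(meta$p_tau) && any(meta$p_tau < 0, na.rm = TRUE))
    stop("p_tau must be >= 0")
  if (!is.null(table)) {
    missing <- setdiff(sample_ids(table), meta$sample_id)
    if (length(missing))
      stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  meta
}

# Align metadata rows to the columns of a feature table (study samples only
# unless roles is given).
meta_align <- function(meta, table, roles = NULL) {
  meta <- validate_metadata(meta, table)
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  if (!is.null(roles)) meta <- meta[meta$role %in% roles, , drop = FALSE]
  meta
}
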