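dir_sign <- function(x) {
  out <- rep("0", length(x))
  out[!is.na(x) & x > 0] <- "+"
  out[!is.na(x) & x < 0] <- "-"
  out
}

#' Metabolome-wide association by covariate-adjusted linear regression
#'
#' Per feature, ordinary least squares of (glog) intensity on a continuous
#' outcome plus covariates; the reported p-value is the two-sided t-test on
#' the outcome coefficient. Features whose design becomes rank deficient
#' (after complete-case removal) are flagged, not silently dropped. An
#' auxiliary Benjamini-Hochberg column is provided for convenience; the
#' downstream screen uses raw p-values.
#'
#' @param table preprocessed `feature_table`
#' @param meta sample metadata covering the table's samples
#' @param outcome metadata column name of the numeric outcome (e.g. `p_tau`)
#' @param covariates metadata column names adjusted for (factors are
#'   expanded to indicator contrasts); e.g. `c("sex", "age", "batch")`
#' @return data.frame: `feature_id`, `model`, `estimate` (glog units per
#'   outcome unit), `direction`, `p_value`, `p_bh`, `flag`
#' @export
mwas_linear <- function(table, meta, outcome, covariates = character()) {
  meta <- meta_align(meta, table)
  y_out <- meta[[outcome]]
  if (is.null(y_out)) stop("unknown outcome column '", outcome, "'")
  if (!is.numeric(y_out)) stop("outcome must be numeric")
  if (stats::sd(y_out, na.rm = TRUE) == 0 || all(is.na(y_out)))
    stop("outcome is constant across samples")
  df <- data.frame(.outcome = y_out)
  for (cv in covariates) {
    if (is.null(meta[[cv]])) stop("unknown covariate column '", cv, "'")
    df[[cv]] <- if (is.character(meta[[cv]])) factor(meta[[cv]]) else meta[[cv]]
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c(".outcome", covariates),
                                       collapse = " + "))), df)
  if (nrow(X) < nrow(df)) stop("missing values in outcome/covariates")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more parameters (", p, ") than samples allow (n = ", n, ")")

  Y <- t(table$intensities)          # samples x features
  complete <- !apply(is.na(Y), 2, any)
  est <- se <- rep(NA_real_, ncol(Y))
  flag <- rep("", ncol(Y))
  dfree <- rep(NA_real_, ncol(Y))

  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient design (collinear covariates)")
  # closed-form OLS for all complete features at once
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    B <- qr.coef(qrX, Yc)                       # p x m
    R <- Yc - X %*% B
    rss <- colSums(R^2)
    s2 <- rss / (n - p)
    XtXinv_jj <- chol2inv(qr.R(qrX))[2, 2]      # outcome coefficient
    est[complete] <- B[2, ]
    se[complete] <- sqrt(s2 * XtXinv_jj)
    dfree[complete] <- n - p
  }
  for (j in which(!complete)) {                 # complete-case refits
    ok <- !is.na(Y[, j])
    Xj <- X[ok, , drop = FALSE]
    if (sum(ok) <= p || qr(Xj)$rank < p) { flag[j] <- "rank_deficient"; next }
    fit <- stats::lm.fit(Xj, Y[ok, j])
    rdf <- sum(ok) - p
    s2 <- sum(fit$residuals^2) / rdf
    covb <- chol2inv(qr.R(fit$qr))
    est[j] <- fit$coefficients[2]
    se[j] <- sqrt(s2 * covb[2, 2])
    dfree[j] <- rdf
  }
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), dfree)
  pval[!is.na(se) & se == 0] <- ifelse(est[!is.na(se) & se == 0] == 0, 1, 0)
  data.frame(feature_id = feature_ids(table), model = "linear",
             estimate = est, direction = dir_sign(est), p_value = pval,
             p_bh = stats::p.adjust(pval, "BH"), flag = flag,
             row.names = NULL)
}

#' Per-feature Welch two-sample t-tests
#'
#' Compares feature intensities between exactly two groups with the
#' unequal-variance (Welch) t-test. The estimate is mean(group 2) minus
#' mean(group 1), with group order fixed by `levels` (or the factor/sort
#' order of the grouping column).
#'
#' @param table preprocessed `feature_table`
#' @param meta sample metadata
#' @param group metadata column with exactly two levels, each n >= 2
#' @param levels optional explicit group order `c(reference, comparison)`
#' @return data.frame: `feature_id`, `model`, `estimate`, `direction`,
#'   `p_value`, `p_bh`
#' @export
ttest_two_group <- function(table, meta, group, levels = NULL) {
  meta <- meta_align(meta, table)
  g <- meta[[group]]
  if (is.null(g)) stop("unknown group column '", group, "'")
  g <- factor(g, levels = levels %||% sort(unique(as.character(g))))
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (min(n1, n2) < 2L) stop("each group needs n >= 2")
  m <- table$intensities
  x1 <- m[, g == levels(g)[1], drop = FALSE]
  x2 <- m[, g == levels(g)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  se <- sqrt(v1 / n1 + v2 / n2)
  tstat <- (m2 - m1) / se
  dfree <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pval <- 2 * stats::pt(-abs(tstat), dfree)
  # degenerate zero-variance features
  zero <- !is.na(se) & se == 0
  tstat[zero] <- ifelse(m2[zero] == m1[zero], 0, Inf * sign(m2 - m1)[zero])
  pval[zero] <- ifelse(m2[zero] == m1[zero], 1, 0)
  data.frame(feature_id = feature_ids(table), model = "ttest",
             estimate = m2 - m1, direction = dir_sign(m2 - m1),
             p_value = pval, p_bh = stats::p.adjust(pval, "BH"),
             row.names = NULL)
}

#' Per-feature two-way ANOVA with interaction
#'
#' Fits `intensity ~ A * B` per feature and reports type-II F-tests for both
#' main effects and the interaction (for balanced designs these coincide
#' with the classical sequential sums of squares). When any omnibus p-value
#' falls below `alpha`, Tukey's HSD on the cell means (studentized-range
#' adjusted, using the ANOVA error term) is attached for that feature.
#'
#' @param table preprocessed `feature_table` or a plain numeric matrix
#'   (rows = responses, columns = samples)
#' @param meta sample metadata with the two factor columns
#' @param factorA,factorB metadata column names (e.g. strain, treatment)
#' @param alpha omnibus threshold that triggers the post hoc test
#' @param posthoc compute Tukey HSD contrasts
#' @return list with `results` (data.frame: `feature_id`, `p_A`, `p_B`,
#'   `p_interaction`, marginal-difference estimates and directions) and
#'   `posthoc` (named list of Tukey contrast data.frames)
#' @export
anova_twoway <- function(table, meta, factorA = "strain",
                         factorB = "treatment", alpha = 0.05,
                         posthoc = TRUE) {
  if (inherits(table, "feature_table")) {
    m <- table$intensities
    meta <- meta_align(meta, table)
  } else {
    m <- as.matrix(table)
    meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  }
  A <- factor(meta[[factorA]]); B <- factor(meta[[factorB]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need at least 2 levels")
  cells <- table(A, B)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (all(cells == 1L))
    stop("need >= 2 observations in at least one cell for an error term")

  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  res <- data.frame(feature_id = ids, model = "anova2",
                    p_A = NA_real_, p_B = NA_real_,
                    p_interaction = NA_real_,
                    estimate_A = NA_real_, estimate_B = NA_real_)
  post <- list()
  cell <- interaction(A, B, sep = ":")
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    fit <- stats::lm(y ~ A * B)
    a2 <- car::Anova(fit, type = 2)
    res$p_A[i] <- a2["A", "Pr(>F)"]
    res$p_B[i] <- a2["B", "Pr(>F)"]
    res$p_interaction[i] <- a2["A:B", "Pr(>F)"]
    # marginal (unweighted cell-mean) differences, last level minus first
    cm <- tapply(y, list(A, B), mean)
    res$estimate_A[i] <- mean(cm[nlevels(A), ]) - mean(cm[1, ])
    res$estimate_B[i] <- mean(cm[, nlevels(B)]) - mean(cm[, 1])
    if (posthoc &&
        any(c(res$p_A[i], res$p_B[i], res$p_interaction[i]) < alpha,
            na.rm = TRUE)) {
      tk <- stats::TukeyHSD(stats::aov(y ~ cell))$cell
      post[[ids[i]]] <- data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL)
    }
  }
  res$direction_A <- dir_sign(res$estimate_A)
  res$direction_B <- dir_sign(res$estimate_B)
  list(results = res, posthoc = post)
}

#' Select significant features from association results
#'
#' Filters one model family's results at `p < alpha` for the chosen term and
#' carries each feature's direction of association — the input to pathway
#' enrichment and cross-species overlap.
#'
#' @param results data.frame from [mwas_linear()] / [ttest_two_group()], or
#'   the `$results` element of [anova_twoway()]
#' @param alpha significance threshold (raw p-values)
#' @param term which p-value to screen: "outcome" (linear/ttest models), or
#'   "A"/"B"/"interaction" for two-way ANOVA results
#' @return data.frame: `feature_id`, `direction`, `p_value`
#' @export
significant_features <- function(results, alpha = 0.05, term = "outcome") {
  if (term == "outcome") {
    if (is.null(results$p_value)) stop("results carry no 'p_value' column")
    p <- results$p_value
    dirs <- results$direction
  } else if (term %in% c("A", "B", "interaction")) {
    col <- paste0("p_", term)
    if (is.null(results[[col]])) stop("unknown term '", term, "' for results")
    p <- results[[col]]
    dirs <- switch(term,
                   A = results$direction_A,
                   B = results$direction_B,
                   interaction = rep("0", nrow(results)))  # no natural sign
  } else stop("unknown term '", term, "'")
  keep <- !is.na(p) & p < alpha
  data.frame(feature_id = results$feature_id[keep],
             direction = dirs[keep], p_value = p[keep], row.names = NULL)
}
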