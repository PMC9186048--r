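# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each rule with plain loops, so the vectorised
# implementations are checked against a second, independent route.

random_raw_table <- function(n_features = 30, n_samples = 8,
                             missing_prob = 0.15, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n_features * n_samples, meanlog = 8, sdlog = 1.5),
              n_features, n_samples,
              dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  m[matrix(runif(length(m)) < missing_prob, nrow(m))] <- NA
  feature_table(data.frame(mz = sort(runif(n_features, 85, 1250)),
                           rt = runif(n_features, 30, 300)), m)
}

random_blank_table <- function(table, n_blanks = 3, seed = 2) {
  set.seed(seed)
  nf <- nrow(table$intensities)
  b <- matrix(rlnorm(nf * n_blanks, meanlog = 6, sdlog = 2), nf, n_blanks,
              dimnames = list(NULL, paste0("blank", seq_len(n_blanks))))
  feature_table(table$features, b)
}

# the 1.5x blank rule, feature by feature
oracle_blank_keep <- function(m, b, ratio, summary = "mean") {
  b[is.na(b)] <- 0
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    bs <- if (summary == "mean") mean(b[i, ]) else max(b[i, ])
    obs <- m[i, !is.na(m[i, ])]
    keep[i] <- all(obs >= ratio * bs)
  }
  keep
}

# missingness removal + half-minimum imputation, cell by cell
oracle_missingness <- function(m, thr) {
  keep <- logical(nrow(m))
  out <- m
  for (i in seq_len(nrow(m))) {
    fm <- mean(is.na(m[i, ]))
    keep[i] <- fm < thr && fm < 1
    if (keep[i] && any(is.na(m[i, ])))
      out[i, is.na(m[i, ])] <- 0.5 * min(m[i, ], na.rm = TRUE)
  }
  list(keep = keep, m = out[keep, , drop = FALSE])
}

oracle_detection_keep <- function(m, min_detected) {
  apply(m, 1, function(x) mean(!is.na(x)) > min_detected)
}

# classical balanced two-way ANOVA sums of squares
oracle_anova2 <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  grand <- mean(y)
  cm <- tapply(y, list(A, B), mean)
  na <- table(A)[1]; nb <- table(B)[1]   # balanced
  nc <- table(A, B)[1, 1]
  ssa <- sum(table(A) * (tapply(y, A, mean) - grand)^2)
  ssb <- sum(table(B) * (tapply(y, B, mean) - grand)^2)
  ssab <- nc * sum((cm - outer(tapply(y, A, mean), tapply(y, B, mean), "+") +
                      grand)^2)
  sse <- sum((y - cm[cbind(A, B)])^2)
  dfa <- nlevels(A) - 1; dfb <- nlevels(B) - 1; dfab <- dfa * dfb
  dfe <- length(y) - nlevels(A) * nlevels(B)
  list(F_A = (ssa / dfa) / (sse / dfe),
       F_B = (ssb / dfb) / (sse / dfe),
       F_AB = (ssab / dfab) / (sse / dfe),
       p_AB = pf((ssab / dfab) / (sse / dfe), dfab, dfe, lower.tail = FALSE),
       ss = c(A = ssa, B = ssb, AB = ssab, E = sse))
}

# product-limit estimator by direct recursion
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  tmax <- max(time)
  tt <- c(0, ut[ut <= tmax])
  ss <- c(1, surv[ut <= tmax])
  auc <- sum(ss * diff(c(tt, tmax)))
  list(time = ut, surv = surv, mean = auc)
}

# log-rank statistic from the expected/observed decomposition
oracle_logrank <- function(time, event, group) {
  g <- factor(group)
  ut <- sort(unique(time[event == 1]))
  U <- V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == levels(g)[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1])
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# brute-force (feature, compound, adduct) annotation triples
oracle_annotation_triples <- function(features, library, adducts, tol_ppm) {
  out <- character()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(library))) {
      for (k in seq_len(nrow(adducts))) {
        theo <- (library$monoisotopic_mass[j] + adducts$mass_shift[k] +
                   adducts$n13C[k] * 1.003355) / abs(adducts$charge[k])
        ppm <- (features$mz[i] - theo) / theo * 1e6
        if (abs(ppm) <= tol_ppm)
          out <- c(out, paste(features$feature_id[i],
                              library$compound_id[j], adducts$name[k],
                              sep = "|"))
      }
    }
  }
  sort(out)
}
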