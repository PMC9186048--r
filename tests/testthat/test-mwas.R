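glog_table <- function(m) {
  feature_table(data.frame(mz = seq_len(nrow(m)) + 100,
                           rt = seq_len(nrow(m))), m)
}

test_that("a feature equal to the outcome fits perfectly", {
  set.seed(1)
  out <- rnorm(30, 50, 10)
  m <- matrix(out, 1, 30, dimnames = list(NULL, paste0("s", 1:30)))
  meta <- data.frame(sample_id = colnames(m), p_tau = out)
  res <- mwas_linear(glog_table(m), meta, "p_tau")
  expect_equal(res$estimate, 1.0, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$direction, "+")
})

test_that("OLS with a binary predictor equals the pooled-variance t-test", {
  set.seed(2)
  g <- rep(c(0, 1), each = 10)
  m <- matrix(rnorm(200), 10, 20, dimnames = list(NULL, paste0("s", 1:20)))
  meta <- data.frame(sample_id = colnames(m), grp = g)
  res <- mwas_linear(glog_table(m), meta, "grp")
  for (i in 1:10) {
    tt <- t.test(m[i, g == 1], m[i, g == 0], var.equal = TRUE)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$estimate[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-10)
  }
})

test_that("linear MWAS matches per-feature lm with covariates, NAs included", {
  set.seed(3)
  n <- 40
  meta <- data.frame(sample_id = paste0("s", 1:n), p_tau = rlnorm(n, 3, 0.5),
                     age = rnorm(n, 68, 8), sex = sample(c("M", "F"), n, TRUE),
                     batch = sample(c("b1", "b2"), n, TRUE))
  m <- matrix(rnorm(20 * n), 20, n, dimnames = list(NULL, meta$sample_id))
  m[1, 1:3] <- NA   # a feature needing a complete-case refit
  res <- mwas_linear(glog_table(m), meta, "p_tau", c("sex", "age", "batch"))
  for (i in c(1, 5, 17)) {
    fit <- summary(lm(m[i, ] ~ p_tau + sex + age + batch, data = meta))
    expect_equal(res$estimate[i], fit$coefficients["p_tau", 1],
                 tolerance = 1e-10)
    expect_equal(res$p_value[i], fit$coefficients["p_tau", 4],
                 tolerance = 1e-10)
  }
})

test_that("linear MWAS validates its inputs", {
  m <- matrix(rnorm(20), 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  meta <- data.frame(sample_id = colnames(m), p_tau = rep(5, 10))
  expect_error(mwas_linear(glog_table(m), meta, "p_tau"), "constant")
  meta$p_tau <- rlnorm(10)
  expect_error(mwas_linear(glog_table(m), meta, "nope"), "unknown outcome")
  small <- glog_table(m[, 1:2])
  expect_error(mwas_linear(small, meta[1:2, ], "p_tau"), "parameters")
})

test_that("Welch t-tests match the textbook computation", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  meta <- data.frame(sample_id = colnames(m),
                     strain = rep(c("A", "B"), each = 3))
  res <- ttest_two_group(glog_table(m), meta, "strain",
                         levels = c("A", "B"))
  tt <- t.test(c(4, 5, 6), c(1, 2, 3))      # Welch by default
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$estimate, 3)
  expect_equal(res$direction, "+")

  # identical groups: t = 0, p = 1
  m2 <- matrix(rep(c(1, 2, 3), 2), 1, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  res2 <- ttest_two_group(glog_table(m2), meta, "strain")
  expect_equal(res2$p_value, 1)
  expect_equal(res2$estimate, 0)

  # random features agree with stats::t.test
  set.seed(4)
  m3 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  res3 <- ttest_two_group(glog_table(m3), meta, "strain",
                          levels = c("A", "B"))
  for (i in 1:10)
    expect_equal(res3$p_value[i],
                 t.test(m3[i, 4:6], m3[i, 1:3])$p.value, tolerance = 1e-12)

  expect_error(ttest_two_group(glog_table(m3[, 1:3]), meta[1:3, ], "strain"),
               "two levels")
})

test_that("two-way ANOVA matches brute-force sums of squares", {
  set.seed(5)
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     strain = rep(c("wt", "tau"), each = 10),
                     treatment = rep(rep(c("DMSO", "DDT"), each = 5), 2))
  m <- matrix(rnorm(8 * 20), 8, 20, dimnames = list(NULL, meta$sample_id))
  fit <- anova_twoway(glog_table(m), meta, "strain", "treatment",
                      posthoc = FALSE)
  for (i in 1:8) {
    orc <- oracle_anova2(m[i, ], meta$strain, meta$treatment)
    expect_equal(fit$results$p_interaction[i], orc$p_AB, tolerance = 1e-8)
    got_F <- qf(fit$results$p_A[i], 1, 16, lower.tail = FALSE)
    expect_equal(got_F, orc$F_A, tolerance = 1e-8)
  }
})

test_that("exactly additive balanced cells give zero interaction SS", {
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     strain = rep(c("wt", "tau"), each = 4),
                     treatment = rep(rep(c("DMSO", "DDT"), each = 2), 2))
  # cell means additive (10, 12, 13, 15); symmetric within-cell spread
  cell_mean <- c(10, 10, 12, 12, 13, 13, 15, 15)
  y <- cell_mean + rep(c(-1, 1), 4)
  m <- matrix(y, 1, 8, dimnames = list(NULL, meta$sample_id))
  fit <- anova_twoway(glog_table(m), meta, "strain", "treatment",
                      posthoc = FALSE)
  expect_equal(fit$results$p_interaction, 1, tolerance = 1e-12)
})

test_that("ANOVA refuses empty cells and attaches Tukey contrasts", {
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     strain = rep(c("wt", "tau"), each = 6),
                     treatment = rep(rep(c("DMSO", "DDT"), each = 3), 2))
  set.seed(6)
  m <- matrix(rnorm(12, mean = rep(c(0, 0, 5, 0), each = 3)), 1, 12,
              dimnames = list(NULL, meta$sample_id))
  fit <- anova_twoway(glog_table(m), meta, "strain", "treatment")
  expect_true(length(fit$posthoc) == 1L)
  tk <- fit$posthoc[[1]]
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  expect_equal(nrow(tk), choose(4, 2))

  bad <- meta
  bad$treatment[bad$strain == "tau"] <- "DMSO"
  expect_error(anova_twoway(glog_table(m), bad, "strain", "treatment"),
               "empty design cell")
})

test_that("association results are invariant to sample column order", {
  set.seed(7)
  n <- 30
  meta <- data.frame(sample_id = paste0("s", 1:n), p_tau = rlnorm(n, 3, 0.5),
                     strain = rep(c("A", "B"), each = n / 2))
  m <- matrix(rnorm(10 * n), 10, n, dimnames = list(NULL, meta$sample_id))
  perm <- sample(n)
  t1 <- glog_table(m)
  t2 <- glog_table(m[, perm])
  expect_equal(mwas_linear(t1, meta, "p_tau"),
               mwas_linear(t2, meta, "p_tau"), tolerance = 1e-12)
  expect_equal(ttest_two_group(t1, meta, "strain"),
               ttest_two_group(t2, meta, "strain"), tolerance = 1e-12)
})

test_that("significant_features screens the requested term with direction", {
  res <- data.frame(feature_id = c("f1", "f2", "f3"),
                    direction = c("+", "-", "+"),
                    p_value = c(0.01, 0.2, 0.04))
  sel <- significant_features(res, alpha = 0.05)
  expect_equal(sel$feature_id, c("f1", "f3"))
  expect_equal(sel$direction, c("+", "+"))
  expect_equal(nrow(significant_features(res, alpha = 1)), 3L)
  expect_equal(nrow(significant_features(res[0, ], 0.05)), 0L)

  an <- data.frame(feature_id = "f1", p_A = 0.01, p_B = 0.5,
                   p_interaction = 0.03, direction_A = "-",
                   direction_B = "+")
  expect_equal(significant_features(an, term = "A")$direction, "-")
  expect_equal(nrow(significant_features(an, term = "B")), 0L)
  expect_equal(nrow(significant_features(an, term = "interaction")), 1L)
  expect_error(significant_features(an, term = "bogus"), "unknown term")
})
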