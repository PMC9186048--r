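make_table <- function(m) {
  feature_table(data.frame(mz = seq_len(nrow(m)) + 100, rt = seq_len(nrow(m))),
                m)
}

test_that("blank filter applies the 1.5x rule over all study samples", {
  m <- rbind(c(9, 9, 9), c(9, 6, 9))
  colnames(m) <- paste0("s", 1:3)
  b <- matrix(5, 2, 2, dimnames = list(NULL, c("b1", "b2")))
  tab <- make_table(m); blanks <- make_table(b)
  res <- blank_filter(tab, blanks, ratio = 1.5)
  # 9 >= 7.5 everywhere keeps the first; 6 < 7.5 removes the second
  expect_equal(feature_ids(res$table), feature_ids(tab)[1])
  expect_equal(res$report$rules[[1]]$removed, feature_ids(tab)[2])
  expect_equal(res$report$rules[[1]]$n_input, 2L)

  # a feature missing from the blank table is an error, not a pass
  expect_error(blank_filter(tab, make_table(b[1, , drop = FALSE])),
               "absent from blank")
})

test_that("missingness filter imputes half the per-feature minimum", {
  m <- rbind(c(NA, 4, 8), c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  res <- missingness_filter_impute(make_table(m), 0.5)
  expect_equal(res$table$intensities[1, 1], 2.0)   # half of min(4, 8)
  expect_equal(res$report$rules[[1]]$imputed_cells, 1L)

  # 4 of 6 missing (67% >= 50%) drops the feature; observed cells untouched
  m2 <- rbind(c(NA, NA, NA, NA, 5, 6), c(1, 2, 3, 4, 5, 6))
  colnames(m2) <- paste0("s", 1:6)
  res2 <- missingness_filter_impute(make_table(m2), 0.5)
  expect_equal(nrow(res2$table$intensities), 1L)
  expect_equal(unname(res2$table$intensities[1, ]), c(1, 2, 3, 4, 5, 6))

  # exactly 50% missing is removed (strict threshold)
  m3 <- rbind(c(NA, NA, 3, 4), c(1, 2, 3, 4))
  colnames(m3) <- paste0("s", 1:4)
  res3 <- missingness_filter_impute(make_table(m3), 0.5)
  expect_equal(nrow(res3$table$intensities), 1L)
})

test_that("detection filter uses a strict greater-than rule", {
  m <- matrix(1, 3, 100, dimnames = list(NULL, paste0("s", 1:100)))
  m[1, 1:19] <- NA   # detected in 81/100
  m[2, 1:20] <- NA   # detected in 80/100
  out <- detection_filter(make_table(m), 0.8)$table
  expect_equal(nrow(out$intensities), 2L)
  expect_false(feature_ids(make_table(m))[2] %in% feature_ids(out))
  # min_detected 0 retains everything with at least one detection
  expect_equal(nrow(detection_filter(make_table(m), 0)$table$intensities), 3L)
})

test_that("the three filters equal brute-force re-application on random tables", {
  for (seed in 1:30) {
    tab <- random_raw_table(40, 10, missing_prob = 0.25, seed = seed)
    blanks <- random_blank_table(tab, seed = seed + 1000)
    m <- tab$intensities

    bf <- blank_filter(tab, blanks, 1.5)
    expect_identical(feature_ids(bf$table),
                     feature_ids(tab)[oracle_blank_keep(m,
                                                        blanks$intensities,
                                                        1.5)])
    mf <- missingness_filter_impute(tab, 0.5)
    orc <- oracle_missingness(m, 0.5)
    expect_identical(feature_ids(mf$table), feature_ids(tab)[orc$keep])
    expect_equal(unname(mf$table$intensities), unname(orc$m))

    df <- detection_filter(tab, 0.6)
    expect_identical(feature_ids(df$table),
                     feature_ids(tab)[oracle_detection_keep(m, 0.6)])

    # bookkeeping: removed + retained equals the input count
    for (res in list(bf, mf, df))
      expect_equal(res$report$rules[[1]]$n_removed +
                     res$report$rules[[1]]$n_retained,
                   nrow(m))
  }
})

test_that("glog matches its closed form, monotonicity and log2 limit", {
  m <- matrix(c(0, 4), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  out <- glog_transform(make_table(m), a = 2)
  expect_equal(out$intensities[1, 1], 0)        # log2((0 + 2)/2)
  expect_equal(out$intensities[1, 2], log2((4 + sqrt(16 + 4)) / 2))

  set.seed(2)
  x <- sort(runif(100, 0, 1e5))
  y <- log2((x + sqrt(x^2 + 1)) / 2)
  expect_true(all(diff(y) > 0))                 # strictly increasing

  big <- matrix(1e6, 1, 1, dimnames = list(NULL, "s1"))
  out2 <- glog_transform(make_table(big), a = 1)
  expect_equal(out2$intensities[1, 1], log2(1e6), tolerance = 1e-9)

  neg <- matrix(-1, 1, 1, dimnames = list(NULL, "s1"))
  expect_error(glog_transform(make_table(neg), a = 1), "negative")
})

test_that("batch standardisation equalises batch means to the pooled mean", {
  set.seed(7)
  m <- matrix(c(rnorm(40, 10), rnorm(40, 20)), 8, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  tab <- make_table(m)
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     batch = rep(c("b1", "b2"), each = 5))
  adj <- batch_adjust(tab, meta)
  for (i in 1:8) {
    pooled <- mean(m[i, ])
    expect_equal(mean(adj$intensities[i, 1:5]), pooled, tolerance = 1e-10)
    expect_equal(mean(adj$intensities[i, 6:10]), pooled, tolerance = 1e-10)
  }

  # single batch is the identity
  meta1 <- data.frame(sample_id = paste0("s", 1:10), batch = "b1")
  expect_equal(batch_adjust(tab, meta1)$intensities, tab$intensities)

  # singleton batches are refused
  meta2 <- data.frame(sample_id = paste0("s", 1:10),
                      batch = c("b1", rep("b2", 9)))
  expect_error(batch_adjust(tab, meta2), "singleton")
})

test_that("a planted batch shift is removed without distorting null tests", {
  # features with a pure batch shift and no signal; the exact location-scale
  # standardisation drives the between-batch sum of squares to zero, so a
  # one-way ANOVA on batch should find nothing at all
  set.seed(11)
  n <- 60
  batch <- rep(c("b1", "b2", "b3"), each = n / 3)
  shift <- c(b1 = 0, b2 = 3, b3 = -3)
  m <- t(replicate(200, rnorm(n, 10 + shift[batch])))
  colnames(m) <- paste0("s", seq_len(n))
  tab <- make_table(m)
  meta <- data.frame(sample_id = colnames(m), batch = batch)
  adj <- batch_adjust(tab, meta)
  p_batch <- apply(adj$intensities, 1, function(y)
    summary(aov(y ~ factor(batch)))[[1]]$`Pr(>F)`[1])
  expect_true(all(p_batch > 0.999))

  # and association with a batch-independent outcome stays calibrated
  meta$p_tau <- rlnorm(n, 3, 0.5)
  res <- mwas_linear(adj, meta, "p_tau")
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("the fixed pipeline orders are reproducible and logged", {
  w <- generate_worm_experiment(worm_experiment_spec(n_features = 200),
                                seed = 5)
  r1 <- preprocess_pipeline(w$table, w$blanks, mode = "worm")
  r2 <- preprocess_pipeline(w$table, w$blanks, mode = "worm")
  expect_equal(r1$table$intensities, r2$table$intensities)
  steps <- vapply(r1$table$provenance, `[[`, "", "step")
  expect_equal(steps, c("blank_filter", "missingness_filter_impute",
                        "glog_transform"))
  expect_false(anyNA(r1$table$intensities))
})
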