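mk_assoc <- function(ids, dirs, ps) {
  data.frame(feature_id = ids, direction = dirs, p_value = ps)
}
mk_hits <- function(ids, kegg, name = kegg) {
  data.frame(feature_id = ids, compound_id = kegg, name = name,
             kegg_id = kegg, adduct = "M+H", theoretical_mz = 100,
             ppm_error = 0, id_level = 3L)
}

test_that("species results keep significant KEGG-annotated features only", {
  a <- mk_assoc(c("f1", "f2", "f3"), c("+", "-", "+"), c(0.01, 0.2, 0.03))
  h <- mk_hits(c("f1", "f3"), c("K1", "K3"))
  sr <- build_species_result(a, h, alpha = 0.05, species = "human")
  expect_equal(sr$table$kegg_id, c("K1", "K3"))
  expect_equal(sr$table$direction, c("+", "+"))

  # no significant features -> empty result
  none <- build_species_result(mk_assoc("f1", "+", 0.9), h, 0.05)
  expect_equal(nrow(none$table), 0L)

  # significant but unannotated -> empty result
  noann <- build_species_result(mk_assoc("f9", "+", 0.001), h, 0.05)
  expect_equal(nrow(noann$table), 0L)
})

test_that("conflicting directions within a KEGG ID are excluded, not voted", {
  a <- mk_assoc(c("f1", "f2"), c("+", "-"), c(0.01, 0.001))
  h <- mk_hits(c("f1", "f2"), c("K1", "K1"))
  expect_warning(sr <- build_species_result(a, h, 0.05, "worm"),
                 "conflicting")
  expect_equal(nrow(sr$table), 0L)
  expect_equal(sr$ambiguous, "K1")
})

test_that("the KEGG direction comes from the minimum-p supporting feature", {
  a <- mk_assoc(c("f1", "f2"), c("+", "+"), c(0.04, 0.001))
  h <- mk_hits(c("f1", "f2"), c("K1", "K1"))
  sr <- build_species_result(a, h, 0.05)
  expect_equal(nrow(sr$table), 1L)
  expect_equal(sr$table$p_value, 0.001)
  expect_equal(sr$table$features, "f1;f2")
})

test_that("species collapse equals a brute-force filter-join on random input", {
  set.seed(8)
  for (rep in 1:10) {
    nf <- 40
    ids <- sprintf("f%02d", 1:nf)
    assoc <- mk_assoc(ids, sample(c("+", "-"), nf, TRUE), runif(nf))
    ann_idx <- sample(nf, 25, replace = TRUE)
    hits <- mk_hits(ids[ann_idx],
                    sample(paste0("K", 1:8), 25, replace = TRUE))
    suppressWarnings(sr <- build_species_result(assoc, hits, 0.3))
    # brute force
    expected <- list()
    for (kg in unique(hits$kegg_id)) {
      feats <- unique(hits$feature_id[hits$kegg_id == kg])
      sig <- assoc[assoc$feature_id %in% feats & assoc$p_value < 0.3, ]
      if (nrow(sig) == 0) next
      if (length(unique(sig$direction)) > 1) next
      expected[[kg]] <- c(kg, sig$direction[which.min(sig$p_value)],
                          min(sig$p_value))
    }
    expect_setequal(sr$table$kegg_id, names(expected))
    for (kg in names(expected)) {
      row <- sr$table[sr$table$kegg_id == kg, ]
      expect_equal(row$direction, expected[[kg]][2])
      expect_equal(row$p_value, as.numeric(expected[[kg]][3]))
    }
  }
})

test_that("overlap requires shared KEGG ID and concordant direction", {
  a <- build_species_result(mk_assoc(c("f1", "f2"), c("+", "-"),
                                     c(0.01, 0.01)),
                            mk_hits(c("f1", "f2"), c("K1", "K2")), 0.05, "h")
  b <- build_species_result(mk_assoc(c("g1", "g2"), c("+", "+"),
                                     c(0.02, 0.02)),
                            mk_hits(c("g1", "g2"), c("K1", "K2")), 0.05, "w")
  ov <- concordant_overlap(a, b)
  expect_equal(ov$overlap$kegg_id, "K1")      # K2 discordant
  expect_equal(ov$discordant, "K2")

  # disjoint KEGG sets -> empty report
  c2 <- build_species_result(mk_assoc("x1", "+", 0.01),
                             mk_hits("x1", "K9"), 0.05, "w2")
  expect_equal(concordant_overlap(a, c2)$n_overlap, 0L)

  # mismatched alpha is refused
  d <- build_species_result(mk_assoc("f1", "+", 0.01),
                            mk_hits("f1", "K1"), 0.10, "d")
  expect_error(concordant_overlap(a, d), "different alpha")
})

test_that("overlap is symmetric and monotone in alpha", {
  set.seed(9)
  ids <- sprintf("f%02d", 1:30)
  assoc1 <- mk_assoc(ids, sample(c("+", "-"), 30, TRUE), runif(30))
  assoc2 <- mk_assoc(ids, sample(c("+", "-"), 30, TRUE), runif(30))
  hits <- mk_hits(ids, paste0("K", rep(1:15, 2)))
  for (alpha in c(0.2, 0.5)) {
    suppressWarnings({
      a <- build_species_result(assoc1, hits, alpha, "s1")
      b <- build_species_result(assoc2, hits, alpha, "s2")
    })
    ab <- concordant_overlap(a, b)
    ba <- concordant_overlap(b, a)
    expect_setequal(ab$overlap$kegg_id, ba$overlap$kegg_id)
  }
  suppressWarnings({
    s1_lo <- build_species_result(assoc1, hits, 0.2, "s1")
    s2_lo <- build_species_result(assoc2, hits, 0.2, "s2")
    s1_hi <- build_species_result(assoc1, hits, 0.6, "s1")
    s2_hi <- build_species_result(assoc2, hits, 0.6, "s2")
  })
  lo <- concordant_overlap(s1_lo, s2_lo)
  hi <- concordant_overlap(s1_hi, s2_hi)
  # monotone in alpha, except for IDs that turn direction-ambiguous (and are
  # therefore excluded) once more features become significant
  ambiguous_hi <- union(s1_hi$ambiguous, s2_hi$ambiguous)
  stable <- setdiff(lo$overlap$kegg_id, c(ambiguous_hi, hi$discordant))
  expect_true(all(stable %in% hi$overlap$kegg_id))
})

test_that("planted concordant compounds are recovered end-to-end", {
  st <- generate_crossspecies_study(seed = 11)
  cfg <- run_config()
  hp <- preprocess_pipeline(st$human$table, meta = st$human$metadata,
                            config = cfg, mode = "human")
  lr <- mwas_linear(hp$table, st$human$metadata, "p_tau",
                    c("sex", "age", "batch"))
  sr_h <- build_species_result(
    lr, search_annotations(hp$table, st$library, "positive"), 0.05, "human")
  wp <- preprocess_pipeline(st$worm$table, st$worm$blanks, config = cfg,
                            mode = "worm")
  tt <- ttest_two_group(wp$table, st$worm$metadata, "strain",
                        levels = c("nonaggregating", "aggregating"))
  sr_w <- build_species_result(
    tt, search_annotations(wp$table, st$library, "positive"), 0.05, "worm")
  ov <- concordant_overlap(sr_h, sr_w)
  expect_identical(sort(ov$overlap$kegg_id), st$truth$concordant_kegg)
  expect_false(any(st$truth$discordant_kegg %in% ov$overlap$kegg_id))
})
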