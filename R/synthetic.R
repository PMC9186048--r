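# Synthetic data generators
#
# These emulate the statistical structure the pipeline assumes: a three-group
# human cohort (NC/MCI/AD) with CSF p-tau as a continuous outcome and
# batch-structured LC-HRMS feature matrices, factorial worm experiments,
# blank channels, extracellular-flux traces, and lifespan records. Every
# generator is a pure function of (spec, seed) and returns ground truth
# sufficient to score the downstream stages.

rtruncnorm0 <- function(n, mean, sd) {
  # normal truncated at zero (non-negative biomarker/age draws)
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Specification of a synthetic human cohort matrix
#'
#' Defaults reproduce the study demographics: plasma n = 46/51/45 and CSF
#' n = 25/26/27 for NC/AD/MCI; CSF p-tau (pg/mL) 32+/-14, 74+/-30, 51+/-25
#' in the plasma cohort (32+/-13, 79+/-32, 53+/-20 in the CSF subset); group
#' ages and male fractions from the same table; ~7,250 plasma and ~6,030 CSF
#' features.
#'
#' @param matrix "plasma" or "csf"
#' @param n optional named vector overriding the default group sizes
#'   (`c(NC = , AD = , MCI = )`)
#' @param n_features number of m/z features
#' @param assoc_fraction fraction of features truly associated with p-tau
#' @param effect_size planted slope magnitude, in noise-SD per p-tau-SD
#' @param noise_sd residual SD on the glog scale
#' @param baseline_mean,baseline_sd per-feature baseline glog intensity
#' @param n_batches analysis batches; `batch_shift_sd` is the SD of the
#'   per-feature, per-batch additive shift (glog units)
#' @param batch_shift_sd see above
#' @param miss_center,miss_scale logistic detection-limit model: a cell with
#'   glog intensity y is missing with probability
#'   `plogis((miss_center - y) / miss_scale)`
#' @param glog_a glog scale parameter used to back-transform to raw
#'   intensities
#' @param mz_range,rt_range uniform ranges for feature m/z (Th) and RT (s)
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(matrix = c("plasma", "csf"), n = NULL,
                        n_features = NULL,
                        assoc_fraction = 0.05, effect_size = 1,
                        noise_sd = 1, baseline_mean = 14, baseline_sd = 2,
                        n_batches = 3, batch_shift_sd = 0.5,
                        miss_center = 9, miss_scale = 1.5, glog_a = 1,
                        mz_range = c(85, 1250), rt_range = c(30, 300)) {
  matrix <- match.arg(matrix)
  demo <- if (matrix == "plasma") {
    list(n = c(NC = 46, AD = 51, MCI = 45),
         ptau_mean = c(NC = 32, AD = 74, MCI = 51),
         ptau_sd = c(NC = 14, AD = 30, MCI = 25),
         age_mean = c(NC = 66.5, AD = 65.9, MCI = 69.4),
         age_sd = c(NC = 8.7, AD = 8.9, MCI = 6.6),
         male_frac = c(NC = 0.30, AD = 0.35, MCI = 0.48),
         n_features_default = 7249L)
  } else {
    list(n = c(NC = 25, AD = 26, MCI = 27),
         ptau_mean = c(NC = 32, AD = 79, MCI = 53),
         ptau_sd = c(NC = 13, AD = 32, MCI = 20),
         age_mean = c(NC = 66.2, AD = 64.8, MCI = 70.2),
         age_sd = c(NC = 8.2, AD = 8.2, MCI = 6.2),
         male_frac = c(NC = 0.28, AD = 0.38, MCI = 0.55),
         n_features_default = 6028L)
  }
  if (!is.null(n)) {
    stopifnot(setequal(names(n), names(demo$n)))
    demo$n <- n[names(demo$n)]
  }
  stopifnot(all(demo$n > 0), assoc_fraction >= 0, assoc_fraction <= 1,
            noise_sd >= 0, n_batches >= 1)
  structure(c(demo,
              list(matrix = matrix,
                   n_features = as.integer(n_features %||%
                                             demo$n_features_default),
                   assoc_fraction = assoc_fraction,
                   effect_size = effect_size, noise_sd = noise_sd,
                   baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                   n_batches = n_batches, batch_shift_sd = batch_shift_sd,
                   miss_center = miss_center, miss_scale = miss_scale,
                   glog_a = glog_a, mz_range = mz_range,
                   rt_range = rt_range)),
            class = "cohort_spec")
}

# Generate one cohort matrix from its spec. planted: optional data.frame
# (compound_id, kegg_id, monoisotopic_mass, sign, effect) of compounds whose
# M+H features are forced among the associated set.
generate_cohort_matrix <- function(spec, seed, planted = NULL) {
  set.seed(seed)
  groups <- rep(names(spec$n), spec$n)
  n <- length(groups)
  meta <- data.frame(
    sample_id = sprintf("%s_%03d", spec$matrix, seq_len(n)),
    role = "study", diagnosis = groups,
    p_tau = rtruncnorm0(n, spec$ptau_mean[groups], spec$ptau_sd[groups]),
    age = rtruncnorm0(n, spec$age_mean[groups], spec$age_sd[groups]),
    sex = ifelse(stats::runif(n) < spec$male_frac[groups], "M", "F"),
    batch = sample(rep_len(paste0("b", seq_len(spec$n_batches)), n)),
    row.names = NULL)

  nf <- spec$n_features
  n_planted <- length(if (is.null(planted)) NULL else planted$compound_id)
  n_assoc <- max(round(spec$assoc_fraction * nf), n_planted)
  mz <- stats::runif(nf, spec$mz_range[1], spec$mz_range[2])
  rt <- stats::runif(nf, spec$rt_range[1], spec$rt_range[2])
  assoc_idx <- if (n_assoc > 0) sample.int(nf, n_assoc) else integer()
  slope <- rep(0, nf)
  sgn <- rep(0L, nf)
  planted_idx <- integer()
  compound_id <- kegg_id <- rep(NA_character_, nf)
  if (n_assoc > 0) {
    ptau_sd_pooled <- stats::sd(meta$p_tau)
    sgn[assoc_idx] <- sample(c(-1L, 1L), n_assoc, replace = TRUE)
    slope[assoc_idx] <- sgn[assoc_idx] * spec$effect_size * spec$noise_sd /
      ptau_sd_pooled
    if (n_planted > 0) {
      planted_idx <- assoc_idx[seq_len(n_planted)]
      pi <- planted_idx
      mz[pi] <- planted$monoisotopic_mass + PROTON_MASS   # exact M+H
      sgn[pi] <- planted$sign
      eff <- planted$effect %||% rep(spec$effect_size, n_planted)
      slope[pi] <- planted$sign * eff * spec$noise_sd / ptau_sd_pooled
      compound_id[pi] <- planted$compound_id
      kegg_id[pi] <- planted$kegg_id
    }
  }

  baseline <- stats::rnorm(nf, spec$baseline_mean, spec$baseline_sd)
  # planted compounds are abundant, well-detected metabolites
  baseline[planted_idx] <- spec$baseline_mean + 2 * spec$baseline_sd
  shifts <- matrix(stats::rnorm(nf * spec$n_batches, 0, spec$batch_shift_sd),
                   nf, spec$n_batches,
                   dimnames = list(NULL, paste0("b", seq_len(spec$n_batches))))
  ptau_c <- meta$p_tau - mean(meta$p_tau)
  y <- baseline +
    outer(slope, ptau_c) +
    shifts[, meta$batch] +
    matrix(stats::rnorm(nf * n, 0, spec$noise_sd), nf, n)
  x <- glog_inverse(y, spec$glog_a)
  x[x < 0] <- 0
  p_miss <- stats::plogis((spec$miss_center - y) / spec$miss_scale)
  x[matrix(stats::runif(nf * n), nf, n) < p_miss] <- NA
  colnames(x) <- meta$sample_id

  feats <- data.frame(mz = mz, rt = rt,
                      mode = paste0(spec$matrix, "-C18pos"))
  table <- feature_table(feats, x)
  truth <- data.frame(feature_id = feature_ids(table),
                      associated = seq_len(nf) %in% assoc_idx,
                      slope = slope, sign = sgn,
                      compound_id = compound_id, kegg_id = kegg_id,
                      row.names = NULL)
  list(table = table, metadata = meta, truth = truth)
}

#' Generate a synthetic human cohort (plasma + CSF matrices)
#'
#' Draws per-group p-tau and age from zero-truncated normals with the cohort
#' moments, assigns sex and batch, and simulates feature intensities on the
#' glog scale as baseline + slope x p-tau + batch shift + noise, then
#' back-transforms and applies intensity-dependent (detection-limit)
#' missingness. Associated features carry a planted slope of
#' `effect_size` noise-SD per p-tau-SD.
#'
#' @param spec_plasma,spec_csf [cohort_spec()] objects for the two matrices
#' @param seed integer seed (the CSF matrix uses `seed + 1`)
#' @param planted_plasma,planted_csf optional planted-compound data.frames
#'   (`compound_id`, `kegg_id`, `monoisotopic_mass`, `sign`, optional
#'   `effect`) whose protonated ions are placed exactly at associated
#'   features
#' @return list with `plasma` and `csf` sub-lists (`table`, `truth`),
#'   combined `metadata`, and `truth` (per-matrix ground-truth tables)
#' @export
generate_human_cohort <- function(spec_plasma = cohort_spec("plasma"),
                                  spec_csf = cohort_spec("csf"),
                                  seed = 1L, planted_plasma = NULL,
                                  planted_csf = NULL) {
  pl <- generate_cohort_matrix(spec_plasma, seed, planted_plasma)
  cs <- generate_cohort_matrix(spec_csf, seed + 1L, planted_csf)
  list(plasma = pl[c("table", "truth")], csf = cs[c("table", "truth")],
       metadata = rbind(pl$metadata, cs$metadata),
       truth = list(plasma = pl$truth, csf = cs$truth))
}

#' Specification of a synthetic worm experiment
#'
#' Defaults describe the strain-contrast experiment: nonaggregating vs
#' aggregating strains, 6 replicates of ~500 pooled worms per group, 1,000
#' features. Supplying two `treatments` levels turns it into the full
#' strain x DDT factorial. Effects are planted additively on the glog scale.
#'
#' @param strains character vector of strain levels (>= 2 for a contrast)
#' @param treatments `NULL` for a one-factor contrast, or two levels
#'   (e.g. `c("DMSO", "DDT")`)
#' @param replicates samples per design cell
#' @param n_features number of m/z features
#' @param frac_strain,frac_treatment,frac_interaction fractions of features
#'   carrying each planted effect (disjoint sets)
#' @param strain_effect,treatment_effect,interaction_effect planted effect
#'   magnitudes in noise-SD units (glog scale). Main effects shift the
#'   second factor level; the interaction is planted as a sum-to-zero cell
#'   deviation (+/- effect/2 across the four cells), leaving main effects
#'   untouched
#' @param noise_sd residual SD on the glog scale
#' @param baseline_mean,baseline_sd per-feature baseline glog intensity
#' @param n_blanks blank-channel (buffer-only) samples
#' @param blank_fail_fraction fraction of features whose blank intensity is
#'   high enough to fail the 1.5x rule (background/contaminant features)
#' @param blank_low_divisor blank intensity divisor for genuine features
#'   (blank = baseline / divisor)
#' @param miss_center,miss_scale detection-limit missingness as in
#'   [cohort_spec()]
#' @param worms_per_sample pooled worms per replicate
#' @param glog_a glog scale for back-transformation
#' @param mz_range,rt_range feature m/z and RT ranges
#' @return list of class `worm_spec`
#' @export
worm_experiment_spec <- function(strains = c("nonaggregating", "aggregating"),
                                 treatments = NULL, replicates = 6,
                                 n_features = 1000,
                                 frac_strain = 0.1, frac_treatment = 0,
                                 frac_interaction = 0,
                                 strain_effect = 2, treatment_effect = 2,
                                 interaction_effect = 2, noise_sd = 1,
                                 baseline_mean = 14, baseline_sd = 2,
                                 n_blanks = 3, blank_fail_fraction = 0.35,
                                 blank_low_divisor = 20,
                                 miss_center = 9, miss_scale = 1.5,
                                 worms_per_sample = 500, glog_a = 1,
                                 mz_range = c(85, 1250),
                                 rt_range = c(30, 300)) {
  stopifnot(length(strains) >= 2 || !is.null(treatments), replicates >= 1,
            n_features >= 1)
  if (!is.null(treatments) && length(treatments) < 2)
    stop("interaction designs need >= 2 treatment levels")
  if (replicates < 2 && noise_sd > 0)
    warning("fewer than 2 replicates per cell leaves no error degrees of ",
            "freedom for ANOVA")
  structure(list(strains = strains, treatments = treatments,
                 replicates = replicates, n_features = as.integer(n_features),
                 frac_strain = frac_strain, frac_treatment = frac_treatment,
                 frac_interaction = frac_interaction,
                 strain_effect = strain_effect,
                 treatment_effect = treatment_effect,
                 interaction_effect = interaction_effect,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, n_blanks = n_blanks,
                 blank_fail_fraction = blank_fail_fraction,
                 blank_low_divisor = blank_low_divisor,
                 miss_center = miss_center, miss_scale = miss_scale,
                 worms_per_sample = worms_per_sample, glog_a = glog_a,
                 mz_range = mz_range, rt_range = rt_range),
            class = "worm_spec")
}

#' Generate a synthetic worm LC-HRMS experiment
#'
#' Cell means follow an additive strain/treatment model plus a planted
#' interaction for flagged features, on the glog scale, then back-transform
#' to raw intensities with detection-limit missingness. A blank (buffer)
#' channel is generated so the 1.5x blank rule is exercised: most features
#' sit far above the blank, while `blank_fail_fraction` of them have blank
#' levels high enough to be removed.
#'
#' @param spec a [worm_experiment_spec()]
#' @param seed integer seed
#' @param planted optional planted-compound data.frame (`compound_id`,
#'   `kegg_id`, `monoisotopic_mass`, `sign`, optional `effect`) forced onto
#'   strain-affected features at their exact M+H m/z
#' @return list: `table` (study samples), `blanks`, `metadata` (study +
#'   blank rows), `truth`
#' @export
generate_worm_experiment <- function(spec = worm_experiment_spec(),
                                     seed = 1L, planted = NULL) {
  set.seed(seed)
  trts <- spec$treatments %||% "none"
  design <- expand.grid(rep = seq_len(spec$replicates),
                        strain = spec$strains, treatment = trts,
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  meta <- data.frame(
    sample_id = sprintf("worm_%s_%s_r%d", design$strain, design$treatment,
                        design$rep),
    role = "study", strain = design$strain,
    treatment = if (identical(trts, "none")) NA_character_
                else design$treatment,
    n_worms = spec$worms_per_sample, row.names = NULL)

  nf <- spec$n_features
  mz <- stats::runif(nf, spec$mz_range[1], spec$mz_range[2])
  rt <- stats::runif(nf, spec$rt_range[1], spec$rt_range[2])

  n_planted <- length(if (is.null(planted)) NULL else planted$compound_id)
  n_strain <- max(round(spec$frac_strain * nf), n_planted)
  n_trt <- round(spec$frac_treatment * nf)
  n_int <- round(spec$frac_interaction * nf)
  idx <- sample.int(nf, n_strain + n_trt + n_int)
  strain_idx <- idx[seq_len(n_strain)]
  trt_idx <- idx[n_strain + seq_len(n_trt)]
  int_idx <- idx[n_strain + n_trt + seq_len(n_int)]

  eff_strain <- eff_trt <- eff_int <- rep(0, nf)
  sgn <- rep(0L, nf)
  planted_idx <- integer()
  compound_id <- kegg_id <- rep(NA_character_, nf)
  if (n_strain > 0) {
    sgn[strain_idx] <- sample(c(-1L, 1L), n_strain, replace = TRUE)
    eff_strain[strain_idx] <- sgn[strain_idx] * spec$strain_effect *
      spec$noise_sd
    if (n_planted > 0) {
      planted_idx <- strain_idx[seq_len(n_planted)]
      pi <- planted_idx
      mz[pi] <- planted$monoisotopic_mass + PROTON_MASS
      sgn[pi] <- planted$sign
      eff <- planted$effect %||% rep(spec$strain_effect, n_planted)
      eff_strain[pi] <- planted$sign * eff * spec$noise_sd
      compound_id[pi] <- planted$compound_id
      kegg_id[pi] <- planted$kegg_id
    }
  }
  if (n_trt > 0)
    eff_trt[trt_idx] <- sample(c(-1, 1), n_trt, TRUE) *
      spec$treatment_effect * spec$noise_sd
  if (n_int > 0)
    eff_int[int_idx] <- sample(c(-1, 1), n_int, TRUE) *
      spec$interaction_effect * spec$noise_sd

  # additive model on the last strain / last treatment levels, plus a
  # sum-to-zero interaction deviation (+/- effect/2 across the four cells)
  # that leaves both main effects untouched
  is_s2 <- as.numeric(design$strain == spec$strains[length(spec$strains)])
  is_t2 <- as.numeric(design$treatment == trts[length(trts)]) *
    (length(trts) > 1)
  int_code <- if (length(trts) > 1)
    2 * (is_s2 - 0.5) * (is_t2 - 0.5) else rep(0, n)   # +/- 0.5 pattern
  baseline <- stats::rnorm(nf, spec$baseline_mean, spec$baseline_sd)
  # planted compounds are abundant, well-detected metabolites
  baseline[planted_idx] <- spec$baseline_mean + 2 * spec$baseline_sd
  y <- baseline +
    outer(eff_strain, is_s2) + outer(eff_trt, is_t2) +
    outer(eff_int, int_code) +
    matrix(stats::rnorm(nf * n, 0, spec$noise_sd), nf, n)
  x <- glog_inverse(y, spec$glog_a)
  x[x < 0] <- 0
  p_miss <- stats::plogis((spec$miss_center - y) / spec$miss_scale)
  x[matrix(stats::runif(nf * n), nf, n) < p_miss] <- NA
  colnames(x) <- meta$sample_id

  feats <- data.frame(mz = mz, rt = rt, mode = "HILIC-pos")
  table <- feature_table(feats, x)

  # blank channel on the raw scale; planted endogenous compounds are absent
  # from the buffer blank
  blank_fail <- stats::runif(nf) < spec$blank_fail_fraction
  blank_fail[planted_idx] <- FALSE
  base_raw <- glog_inverse(baseline, spec$glog_a)
  blank_level <- base_raw / ifelse(blank_fail, 1.2, spec$blank_low_divisor)
  blank_level[planted_idx] <- base_raw[planted_idx] / 1000
  bx <- matrix(blank_level * exp(stats::rnorm(nf * spec$n_blanks, 0, 0.1)),
               nf, spec$n_blanks)
  colnames(bx) <- sprintf("blank_%02d", seq_len(spec$n_blanks))
  blanks <- feature_table(feats, bx)
  meta_blanks <- data.frame(sample_id = colnames(bx), role = "blank",
                            strain = NA_character_,
                            treatment = NA_character_, n_worms = 0,
                            row.names = NULL)

  truth <- data.frame(feature_id = feature_ids(table),
                      strain_effect = eff_strain, treatment_effect = eff_trt,
                      interaction_effect = eff_int, sign = sgn,
                      blank_fail = blank_fail,
                      compound_id = compound_id, kegg_id = kegg_id,
                      row.names = NULL)
  list(table = table, blanks = blanks,
       metadata = rbind(meta, meta_blanks), truth = truth)
}

#' Generate synthetic extracellular-flux (OCR) traces
#'
#' Builds 18-measurement per-well traces under the worm injection protocol:
#' a baseline plateau at `(basal + nonmito) * n_worms`, a post-FCCP plateau
#' at `(maximal + nonmito) * n_worms`, and a post-azide plateau at
#' `nonmito * n_worms`, plus measurement noise. Group parameters are
#' per-worm rates (pmol O2/min/worm).
#'
#' @param groups data.frame with `strain`, `treatment`, `basal`, `maximal`,
#'   `nonmito` (per-worm plateau parameters)
#' @param wells_per_group wells simulated per group
#' @param worms_range integer range of worms plated per well (study protocol
#'   plated 3-30)
#' @param noise_sd per-measurement noise SD (pmol O2/min per well)
#' @param seed integer seed
#' @return data.frame: `well_id`, `strain`, `treatment`, `n_worms`,
#'   measurement columns `m01`..`m18`
#' @export
generate_ocr_traces <- function(groups, wells_per_group = 12,
                                worms_range = c(3, 30), noise_sd = 5,
                                seed = 1L) {
  stopifnot(all(c("strain", "treatment", "basal", "maximal", "nonmito") %in%
                  names(groups)))
  if (any(worms_range < 1) || any(worms_range > 10000))
    stop("worms per well must lie in [1, 10000]")
  set.seed(seed)
  proto <- ocr_protocol()
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    do.call(rbind, lapply(seq_len(wells_per_group), function(w) {
      nw <- sample(seq(worms_range[1], worms_range[2]), 1)
      plateau <- c(rep((groups$basal[g] + groups$nonmito[g]) * nw, 5),
                   rep((groups$maximal[g] + groups$nonmito[g]) * nw, 9),
                   rep(groups$nonmito[g] * nw, 4))
      meas <- plateau + stats::rnorm(proto$n_measurements, 0, noise_sd)
      out <- data.frame(well_id = sprintf("%s_%s_w%02d", groups$strain[g],
                                          groups$treatment[g], w),
                        strain = groups$strain[g],
                        treatment = groups$treatment[g], n_worms = nw)
      out[sprintf("m%02d", seq_len(proto$n_measurements))] <- as.list(meas)
      out
    }))
  })
  do.call(rbind, rows)
}

#' Generate synthetic lifespan records
#'
#' Weibull-distributed lifespans with the specified group means (default:
#' the four observed group means — wildtype 24 d, nonaggregating 19.4 d,
#' aggregating 8 d, aggregating+DDT 11.8 d) and independent uniform
#' censoring: a censored animal is observed for a uniform fraction of its
#' lifespan.
#'
#' @param group_means named numeric vector of mean lifespans (days, > 0)
#' @param shape Weibull shape (> 0; steep worm survival curves motivate the
#'   default of 4)
#' @param n_per_group animals per group
#' @param censor_rate probability an animal is censored, in \[0, 1)
#' @param seed integer seed
#' @return data.frame: `id`, `group`, `time` (days), `event`
#' @export
generate_survival <- function(group_means = c(wildtype = 24,
                                              nonaggregating = 19.4,
                                              aggregating = 8,
                                              aggregating_DDT = 11.8),
                              shape = 4, n_per_group = 120,
                              censor_rate = 0.05, seed = 1L) {
  stopifnot(all(group_means > 0), shape > 0,
            censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  out <- lapply(names(group_means), function(g) {
    scale <- group_means[[g]] / gamma(1 + 1 / shape)
    t_death <- stats::rweibull(n_per_group, shape, scale)
    cens <- stats::runif(n_per_group) < censor_rate
    time <- ifelse(cens, t_death * stats::runif(n_per_group), t_death)
    data.frame(id = sprintf("%s_%03d", g, seq_len(n_per_group)),
               group = g, time = pmax(time, 1e-6),
               event = as.integer(!cens), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Build a synthetic compound library
#'
#' Compounds with well-separated masses (spacing far exceeding the 10 ppm
#' tolerance) and sequential KEGG-style identifiers, used to plant
#' recoverable annotations.
#'
#' @param n number of compounds
#' @param mass_range mass range (Da)
#' @param seed integer seed
#' @return compound library data.frame
#' @export
synthetic_library <- function(n = 50, mass_range = c(100, 900), seed = 1L) {
  set.seed(seed)
  mass <- sort(stats::runif(n, mass_range[1], mass_range[2]))
  # enforce >= 0.5 Da spacing so annotations are unambiguous
  mass <- mass + cumsum(c(0, pmax(0, 0.5 - diff(mass))))
  data.frame(compound_id = sprintf("SYN%04d", seq_len(n)),
             name = sprintf("synthetic-compound-%04d", seq_len(n)),
             kegg_id = sprintf("C9%04d", seq_len(n)),
             formula = NA_character_, monoisotopic_mass = mass,
             row.names = NULL)
}

#' Generate a planted pathway-enrichment case
#'
#' Builds a reference feature list annotated against a synthetic library, a
#' significant subset in which 80% of the features map into one planted
#' pathway, and a pathway collection of the planted pathway plus random
#' background pathways — the ingredients for validating the permutation
#' enrichment test.
#'
#' @param seed integer seed
#' @param n_ref reference features; `n_sig` of them are "significant"
#' @param n_sig see above
#' @param n_pathways total pathways (1 planted + background)
#' @param pathway_size compounds per pathway
#' @param planted_fraction fraction of significant features mapped into the
#'   planted pathway
#' @return list: `sig`, `ref` (feature data.frames), `pathways`, `library`,
#'   `planted_pathway` (its name)
#' @export
generate_enrichment_case <- function(seed = 1L, n_ref = 400, n_sig = 40,
                                     n_pathways = 8, pathway_size = 25,
                                     planted_fraction = 0.8) {
  set.seed(seed)
  lib <- synthetic_library(n = 200, seed = seed)
  # reference features: each placed at the M+H of a random library compound
  comp <- sample(seq_len(nrow(lib)), n_ref, replace = TRUE)
  ref <- data.frame(feature_id = sprintf("F%04d", seq_len(n_ref)),
                    mz = lib$monoisotopic_mass[comp] + PROTON_MASS,
                    rt = stats::runif(n_ref, 30, 300))
  planted <- sample(lib$kegg_id, pathway_size)
  # significant list: planted_fraction of features map into the planted set
  in_path <- which(lib$kegg_id[comp] %in% planted)
  out_path <- setdiff(seq_len(n_ref), in_path)
  n_in <- min(round(planted_fraction * n_sig), length(in_path))
  sig_idx <- c(sample(in_path, n_in),
               sample(out_path, n_sig - n_in))
  sig <- ref[sig_idx, , drop = FALSE]
  pathways <- c(list(planted_pathway = planted),
                lapply(seq_len(n_pathways - 1), function(i)
                  sample(lib$kegg_id, pathway_size)))
  names(pathways) <- c("planted_pathway",
                       sprintf("background_%02d", seq_len(n_pathways - 1)))
  class(pathways) <- "pathway_sets"
  list(sig = sig, ref = ref, pathways = pathways, library = lib,
       planted_pathway = "planted_pathway")
}

#' Generate a paired human/worm study with planted cross-species overlap
#'
#' Creates a shared compound library, plants `n_concordant` compounds with
#' the same association sign in the human CSF matrix and the worm strain
#' contrast, and `n_discordant` compounds with opposite signs — exercising
#' both branches of the direction-concordance rule. Planted compounds get a
#' strong effect (3 noise-SD) so recovery reflects the rule, not power.
#'
#' @param seed integer seed
#' @param n_concordant,n_discordant shared compounds planted with equal /
#'   opposite signs
#' @param n_features_human,n_features_worm matrix sizes
#' @return list: `human` (cohort matrix output), `worm` (experiment output),
#'   `library`, `truth` (`concordant_kegg`, `discordant_kegg`, per-compound
#'   signs)
#' @export
generate_crossspecies_study <- function(seed = 1L, n_concordant = 4,
                                        n_discordant = 2,
                                        n_features_human = 1500,
                                        n_features_worm = 1000) {
  set.seed(seed)
  lib <- synthetic_library(n = 40, seed = seed)
  n_shared <- n_concordant + n_discordant
  shared <- lib[sample(nrow(lib), n_shared), , drop = FALSE]
  sign_h <- sample(c(-1L, 1L), n_shared, replace = TRUE)
  sign_w <- sign_h
  if (n_discordant > 0)
    sign_w[n_concordant + seq_len(n_discordant)] <-
      -sign_h[n_concordant + seq_len(n_discordant)]

  planted_h <- data.frame(compound_id = shared$compound_id,
                          kegg_id = shared$kegg_id,
                          monoisotopic_mass = shared$monoisotopic_mass,
                          sign = sign_h, effect = 3)
  planted_w <- data.frame(compound_id = shared$compound_id,
                          kegg_id = shared$kegg_id,
                          monoisotopic_mass = shared$monoisotopic_mass,
                          sign = sign_w, effect = 3)

  human <- generate_cohort_matrix(cohort_spec("csf",
                                              n_features = n_features_human),
                                  seed + 1L, planted = planted_h)
  worm <- generate_worm_experiment(
    worm_experiment_spec(n_features = n_features_worm, strain_effect = 3),
    seed + 2L, planted = planted_w)
  list(human = human, worm = worm, library = lib,
       truth = list(concordant_kegg = sort(shared$kegg_id[seq_len(n_concordant)]),
                    discordant_kegg = sort(shared$kegg_id[n_concordant +
                                                            seq_len(n_discordant)]),
                    sign_human = sign_h, sign_worm = sign_w,
                    shared = shared))
}
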