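# Monoisotopic masses (Da) of the most abundant isotope, CODATA/AME-derived.
# Covers CHNOPS, halogens, and the alkali/selenium symbols needed for common
# ESI adducts.
MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Se = 79.9165213,
  Si = 27.9769265325,
  B  = 11.0093054,
  Li = 7.01600455,
  Mg = 23.985041700,
  Ca = 39.96259098,
  Fe = 55.9349375,
  Zn = 63.9291422
)

ELECTRON_MASS <- 0.00054857990907
PROTON_MASS <- unname(MONOISOTOPIC_MASS["H"] - ELECTRON_MASS)  # 1.00727645
C13_SPACING <- 1.003355   # 13C - 12C, Da

#' Monoisotopic mass of a molecular formula
#'
#' Parses Hill-notation element-count strings (e.g. `"C5H10N2O3"`) and sums
#' count x most-abundant-isotope mass. Vectorised over `formula`.
#'
#' @param formula character vector of formulas
#' @return numeric vector of monoisotopic masses (Da)
#' @examples
#' formula_mass("H2O")        # 18.010565
#' formula_mass("C5H10N2O3")  # glutamine, 146.06914
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) stop("empty formula")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (paste(tokens, collapse = "") != f)
      stop("malformed formula: '", f, "'")
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(MONOISOTOPIC_MASS))
        stop("unknown element '", el, "' in formula '", f, "'")
      total <- total + n * MONOISOTOPIC_MASS[[el]]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Built-in adduct registries
#'
#' Returns the adduct rules for one ionisation polarity. Each rule gives the
#' mass shift added to the neutral monoisotopic mass before division by
#' |charge|. Cationic shifts use the electron-corrected convention: the
#' attached ion contributes its element mass minus one electron per positive
#' charge (proton 1.0072765, Na+ 22.9892207, K+ 38.9631581); anionic shifts
#' add the electron back. `isotopes = TRUE` appends an `[M+1]` variant of
#' every rule, offset by one 13C-12C spacing (1.003355 Da) per charge.
#'
#' @param polarity "positive" or "negative"
#' @param isotopes include `[M+1]` isotopologue variants of each rule
#' @return data.frame with columns `name`, `mass_shift` (Da), `charge`,
#'   `polarity`, `n13C`
#' @export
adduct_registry <- function(polarity = c("positive", "negative"),
                            isotopes = TRUE) {
  polarity <- match.arg(polarity)
  h2o <- formula_mass("H2O")
  acn <- formula_mass("C2H3N")
  nh3 <- formula_mass("NH3")
  na_ion <- unname(MONOISOTOPIC_MASS["Na"] - ELECTRON_MASS)
  k_ion <- unname(MONOISOTOPIC_MASS["K"] - ELECTRON_MASS)
  reg <- if (polarity == "positive") {
    data.frame(
      name = c("M+H", "M+Na", "M+K", "M+NH4", "M-H2O+H", "M-2H2O+H",
               "M+ACN+H", "M+ACN+Na", "M+2H"),
      mass_shift = c(PROTON_MASS, na_ion, k_ion, nh3 + PROTON_MASS,
                     PROTON_MASS - h2o, PROTON_MASS - 2 * h2o,
                     acn + PROTON_MASS, acn + na_ion, 2 * PROTON_MASS),
      charge = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L))
  } else {
    data.frame(
      name = c("M-H", "M-H2O-H", "M+Cl", "M+CH3COO"),
      mass_shift = c(-PROTON_MASS, -PROTON_MASS - h2o,
                     unname(MONOISOTOPIC_MASS["Cl"]) + ELECTRON_MASS,
                     formula_mass("C2H3O2") + ELECTRON_MASS),
      charge = c(-1L, -1L, -1L, -1L))
  }
  reg$polarity <- polarity
  reg$n13C <- 0L
  if (isotopes) {
    iso <- reg
    iso$name <- paste0(iso$name, " [M+1]")
    iso$n13C <- 1L
    reg <- rbind(reg, iso)
  }
  reg
}

#' Theoretical m/z of an adduct ion
#'
#' `m/z = (M + mass_shift) / |charge| + n13C * 1.003355 / |charge|`, where the
#' shift already carries the electron correction (see [adduct_registry()]).
#'
#' @param mass neutral monoisotopic mass (Da), > 0; vectorised
#' @param rule one row of an adduct registry (list or single-row data.frame)
#' @return theoretical m/z (Th)
#' @examples
#' reg <- adduct_registry("positive", isotopes = FALSE)
#' adduct_mz(146.06914, reg[reg$name == "M-H2O+H", ])  # glutamine water loss
#' @export
adduct_mz <- function(mass, rule) {
  stopifnot(all(mass > 0), rule$charge != 0)
  z <- abs(rule$charge)
  mz <- (mass + rule$mass_shift) / z + rule$n13C * C13_SPACING / z
  if (any(mz <= 0))
    stop("adduct '", rule$name, "' yields non-positive m/z")
  mz
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values (Th), > 0
#' @return `(observed - theoretical) / theoretical * 1e6`
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  stopifnot(all(observed_mz > 0), all(theoretical_mz > 0))
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Annotate m/z features against a compound library
#'
#' For every feature, every (compound, adduct) pair whose theoretical m/z is
#' within `tol_ppm` of the observed m/z becomes an annotation hit. Confidence
#' levels follow the four-tier convention: level 3 when the feature matches a
#' single compound, level 4 when multiple isobaric compounds match, level 2
#' when an M+1 isotope partner feature (delta m/z = 1.003355/|z| within
#' tolerance, retention time within `rt_window`) co-occurs in the feature
#' list, and level 1 only for features in `ms2_confirmed`.
#'
#' @param features a `feature_table` or data.frame with `feature_id`, `mz`,
#'   `rt`
#' @param library compound library data.frame (see [read_compound_library()])
#' @param adducts adduct registry data.frame, or `"positive"`/`"negative"`
#' @param tol_ppm mass tolerance (ppm, inclusive)
#' @param rt_window co-elution window for isotope pairing (seconds)
#' @param ms2_confirmed feature ids with external MS2 confirmation
#' @return data.frame of hits: `feature_id`, `compound_id`, `name`,
#'   `kegg_id`, `adduct`, `theoretical_mz`, `ppm_error`, `id_level`, sorted
#'   by feature, compound, adduct.
#' @export
search_annotations <- function(features, library, adducts = "positive",
                               tol_ppm = 10, rt_window = 5,
                               ms2_confirmed = character()) {
  if (inherits(features, "feature_table")) features <- features$features
  if (is.character(adducts)) adducts <- adduct_registry(adducts)
  if (nrow(adducts) == 0L) stop("empty adduct registry")
  library <- validate_compound_library(library)

  # all (compound, adduct) theoretical m/z
  grid <- expand.grid(ci = seq_len(nrow(library)), ai = seq_len(nrow(adducts)))
  theo <- (library$monoisotopic_mass[grid$ci] +
             adducts$mass_shift[grid$ai] +
             adducts$n13C[grid$ai] * C13_SPACING) /
    abs(adducts$charge[grid$ai])

  hits <- lapply(seq_len(nrow(features)), function(i) {
    ppm <- ppm_error(features$mz[i], theo)
    sel <- which(abs(ppm) <= tol_ppm & theo > 0)
    if (!length(sel)) return(NULL)
    data.frame(feature_id = features$feature_id[i],
               compound_id = library$compound_id[grid$ci[sel]],
               name = library$name[grid$ci[sel]],
               kegg_id = library$kegg_id[grid$ci[sel]],
               adduct = adducts$name[grid$ai[sel]],
               charge = adducts$charge[grid$ai[sel]],
               theoretical_mz = theo[sel],
               ppm_error = ppm[sel])
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(feature_id = character(), compound_id = character(),
                      name = character(), kegg_id = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), id_level = integer()))

  # level 3 vs 4: count distinct matching compounds per feature
  ncomp <- tapply(hits$compound_id, hits$feature_id,
                  function(x) length(unique(x)))
  hits$id_level <- ifelse(as.vector(ncomp[hits$feature_id]) > 1L, 4L, 3L)

  # level 2: an M+1 isotope partner feature co-elutes
  fidx <- match(hits$feature_id, features$feature_id)
  for (k in seq_len(nrow(hits))) {
    z <- abs(hits$charge[k])
    partner_mz <- features$mz[fidx[k]] + C13_SPACING / z
    dppm <- abs(ppm_error(features$mz, partner_mz))
    drt <- abs(features$rt - features$rt[fidx[k]])
    ok <- dppm <= tol_ppm & drt <= rt_window &
      features$feature_id != hits$feature_id[k]
    if (any(ok)) hits$id_level[k] <- min(hits$id_level[k], 2L)
  }

  hits$id_level[hits$feature_id %in% ms2_confirmed] <- 1L
  hits$charge <- NULL
  hits <- hits[order(hits$feature_id, hits$compound_id, hits$adduct), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
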