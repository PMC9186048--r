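#' Read a feature table from TSV/CSV
#'
#' Expects the first two columns to be m/z and retention time (names
#' configurable), the remaining columns sample intensities. Non-numeric
#' intensity cells become missing with a warning that counts them; an empty
#' cell or `"NA"` is missing without warning. Zeros are observed values.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param mz_col,rt_col column names holding m/z and retention time.
#' @param mode acquisition context label stored on every feature.
#' @param sep field separator; default inferred from the extension.
#' @param transpose set `TRUE` if the file stores samples as rows.
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, mz_col = "mz", rt_col = "rt",
                               mode = NA_character_, sep = NULL,
                               transpose = FALSE) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  if (transpose) {
    # samples-as-rows layout: first column is the sample id
    ids <- raw[[1L]]
    mat <- t(as.matrix(raw[-1L]))
    raw <- data.frame(name = rownames(mat), mat, check.names = FALSE)
    names(raw)[-1L] <- ids
    # mz/rt must be encoded in the feature name "M<mz>T<rt>"
    mm <- regmatches(raw$name, regexec("^M([0-9.]+)T([0-9.]+)$", raw$name))
    if (any(lengths(mm) != 3L))
      stop("transposed input requires feature names of the form M<mz>T<rt>")
    raw[[mz_col]] <- vapply(mm, `[`, "", 2L)
    raw[[rt_col]] <- vapply(mm, `[`, "", 3L)
    raw$name <- NULL
  }
  if (nrow(raw) == 0L) stop("empty feature table: ", path)
  if (!all(c(mz_col, rt_col) %in% names(raw)))
    stop("missing m/z / RT columns '", mz_col, "', '", rt_col, "'")
  mz <- as.numeric(raw[[mz_col]])
  rt <- as.numeric(raw[[rt_col]])
  dup <- duplicated(paste(signif(mz, 12), signif(rt, 12)))
  if (any(dup))
    stop("duplicate feature rows (same mz+rt): rows ",
         paste(which(dup), collapse = ", "))
  samp_cols <- setdiff(names(raw), c(mz_col, rt_col, "feature_id"))
  chr <- as.matrix(raw[samp_cols])
  suppressWarnings(num <- matrix(as.numeric(chr), nrow = nrow(chr),
                                 dimnames = list(NULL, samp_cols)))
  bad <- sum(!is.na(chr) & is.na(num))
  if (bad > 0)
    warning(bad, " non-numeric intensity cell(s) set to missing in ", path)
  fid <- if ("feature_id" %in% names(raw)) raw$feature_id else NULL
  feature_table(data.frame(feature_id = fid %||% sprintf("M%.4fT%.0f", mz, rt),
                           mz = mz, rt = rt, mode = mode),
                num)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table to TSV/CSV
#'
#' Inverse of [read_feature_table()]: columns `feature_id`, `mz`, `rt`, then
#' one column per sample; missing values written as `NA`.
#'
#' @param x a `feature_table`
#' @param path output path; `.csv` writes comma-separated.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  out <- data.frame(feature_id = x$features$feature_id,
                    mz = x$features$mz, rt = x$features$rt,
                    x$intensities, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV/CSV
#'
#' @param path file with a `sample_id` column plus covariate/design columns
#'   (`role`, `diagnosis`, `p_tau`, `age`, `sex`, `batch`, `strain`,
#'   `treatment`, ...).
#' @param sep field separator; inferred from the extension by default.
#' @return validated data.frame (see [validate_metadata()]).
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  validate_metadata(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")))
}

#' Read pathway definitions from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`; members
#' are KEGG compound identifiers. Duplicate members within a line are stored
#' once; duplicate pathway names are an error.
#'
#' @param path GMT file path
#' @return named list of character vectors of member IDs, with per-pathway
#'   `description` attributes; class `pathway_sets`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  names(parts) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(parts)))
    stop("duplicate pathway names in ", path)
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    attr(members, "description") <- p[2L]
    members
  })
  structure(sets, class = "pathway_sets")
}

#' Write pathway definitions to a GMT file
#' @param sets named list of member-ID vectors (as from [read_gmt()])
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a compound library
#'
#' TSV with columns `compound_id`, `name`, optional `kegg_id`, and at least
#' one of `formula` (Hill notation) or `monoisotopic_mass` (Da). Records with
#' a formula get their mass computed via [formula_mass()]; when both are
#' given they must agree to 1e-6 Da.
#'
#' @param path TSV file
#' @param sep field separator
#' @return data.frame with a populated `monoisotopic_mass` column
#' @export
read_compound_library <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  lib <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), quote = "")
  validate_compound_library(lib)
}

validate_compound_library <- function(lib) {
  stopifnot(is.data.frame(lib), !is.null(lib$compound_id))
  if (is.null(lib$kegg_id)) lib$kegg_id <- NA_character_
  if (is.null(lib$formula)) lib$formula <- NA_character_
  if (is.null(lib$monoisotopic_mass)) lib$monoisotopic_mass <- NA_real_
  lib$monoisotopic_mass <- as.numeric(lib$monoisotopic_mass)
  none <- is.na(lib$formula) & is.na(lib$monoisotopic_mass)
  if (any(none))
    stop("compound(s) with neither formula nor mass: ",
         paste(lib$compound_id[none], collapse = ", "))
  has_f <- !is.na(lib$formula)
  fm <- rep(NA_real_, nrow(lib))
  fm[has_f] <- formula_mass(lib$formula[has_f])
  both <- has_f & !is.na(lib$monoisotopic_mass)
  off <- both & abs(fm - lib$monoisotopic_mass) > 1e-6
  if (any(off, na.rm = TRUE))
    stop("formula/mass disagreement (> 1e-6 Da) for: ",
         paste(lib$compound_id[which(off)], collapse = ", "))
  lib$monoisotopic_mass[has_f] <- fm[has_f]
  if (any(lib$monoisotopic_mass <= 0)) stop("non-positive monoisotopic mass")
  lib
}

#' Run configuration
#'
#' Bundles the thresholds and tuning parameters the pipeline uses, with the
#' study defaults: blank ratio 1.5, 50% missingness cutoff, >80% detection
#' for the primary human screen (20% for the sensitivity screen), alpha 0.05,
#' 10 ppm annotation tolerance, and a single integer seed that governs every
#' randomized step. The config (including the seed) is embedded in result
#' objects so a run is reproducible from its outputs.
#'
#' @param blank_ratio sample/blank intensity ratio required to keep a feature
#' @param blank_summary how blank replicates are summarised ("mean" or "max")
#' @param drop_missing missingness fraction at/above which a feature is dropped
#' @param detect_min detection fraction that must be strictly exceeded
#' @param alpha significance screen for association tests
#' @param tol_ppm annotation mass tolerance (ppm)
#' @param rt_window RT co-elution window for isotope pairing (seconds)
#' @param adducts adduct registry selector ("positive" or "negative")
#' @param n_perm permutation count for pathway enrichment
#' @param glog_a glog scale parameter, or "auto" (minimum positive intensity)
#' @param seed integer seed for all randomized operations
#' @return list of class `run_config`
#' @export
run_config <- function(blank_ratio = 1.5, blank_summary = "mean",
                       drop_missing = 0.5, detect_min = 0.8, alpha = 0.05,
                       tol_ppm = 10, rt_window = 5, adducts = "positive",
                       n_perm = 1000, glog_a = "auto", seed = 1L) {
  stopifnot(blank_ratio > 0, drop_missing > 0, drop_missing <= 1,
            detect_min >= 0, detect_min <= 1, n_perm >= 1, tol_ppm > 0)
  structure(list(blank_ratio = blank_ratio, blank_summary = blank_summary,
                 drop_missing = drop_missing, detect_min = detect_min,
                 alpha = alpha, tol_ppm = tol_ppm, rt_window = rt_window,
                 adducts = adducts, n_perm = n_perm, glog_a = glog_a,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a results object to JSON
#'
#' Wraps the payload with a schema version and the run configuration (seed
#' included) so every artifact records how it was produced.
#'
#' @param x list or data.frame payload
#' @param path output path
#' @param config optional [run_config()] to embed
#' @return `path`, invisibly
#' @export
write_results_json <- function(x, path, config = NULL) {
  payload <- list(schema_version = "1.0", config = unclass(config),
                  results = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
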