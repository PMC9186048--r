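#' Map m/z features to putative compounds
#'
#' Annotates the features against the library and returns the union of
#' matching compound IDs. Annotation ambiguity is retained: one feature may
#' contribute several isobaric compounds, as putative-annotation enrichment
#' methods expect.
#'
#' @param features `feature_table` or data.frame (`feature_id`, `mz`, `rt`)
#' @param library compound library (see [read_compound_library()])
#' @param adducts adduct registry or `"positive"`/`"negative"`
#' @param tol_ppm mass tolerance (ppm)
#' @return character vector of unique compound IDs
#' @export
map_features_to_compounds <- function(features, library,
                                      adducts = "positive", tol_ppm = 10) {
  hits <- search_annotations(features, library, adducts, tol_ppm)
  unique(hits$compound_id)
}

# feature_id -> set of KEGG ids, via annotation (NA kegg dropped)
feature_kegg_map <- function(features, library, adducts, tol_ppm) {
  hits <- search_annotations(features, library, adducts, tol_ppm)
  hits <- hits[!is.na(hits$kegg_id), , drop = FALSE]
  split(hits$kegg_id, factor(hits$feature_id,
                             levels = unique(hits$feature_id))) |>
    lapply(unique)
}

#' Permutation-based pathway enrichment of significant m/z features
#'
#' Mummichog-style over-representation on putative annotations: significant
#' and reference feature lists are mapped to KEGG compounds; for each
#' pathway, `hits` counts the significant compounds in the pathway,
#' `expected` is the pathway's reference-compound overlap scaled by
#' `|sig| / |reference|`, and `enrichment_ratio = hits / expected`.
#' Significance is calibrated by drawing `|sig|` features uniformly without
#' replacement from the reference list `n_perm` times, re-mapping each draw,
#' and reporting `p_perm = (1 + #\{permuted hits >= observed\}) / (n_perm + 1)`.
#'
#' @param sig_features significant feature data.frame (`feature_id`, `mz`,
#'   `rt`); must be a subset of `ref_features`
#' @param ref_features reference universe: all features surviving
#'   preprocessing
#' @param pathways `pathway_sets` (named list of KEGG-ID vectors)
#' @param library compound library
#' @param adducts adduct registry or polarity name
#' @param tol_ppm mass tolerance (ppm)
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed for the permutation draws
#' @return data.frame sorted by `p_perm` then decreasing ratio: `pathway`,
#'   `hits`, `pathway_size_in_reference`, `expected`, `enrichment_ratio`,
#'   `p_perm`, `overlap_compounds`; attributes record `n_perm` and `seed`.
#' @export
pathway_enrichment <- function(sig_features, ref_features, pathways, library,
                               adducts = "positive", tol_ppm = 10,
                               n_perm = 1000, seed = 1L) {
  if (inherits(sig_features, "feature_table")) sig_features <- sig_features$features
  if (inherits(ref_features, "feature_table")) ref_features <- ref_features$features
  if (length(pathways) == 0L) stop("empty pathway collection")
  if (n_perm < 100) stop("n_perm must be >= 100 for a stable permutation p")
  extra <- setdiff(sig_features$feature_id, ref_features$feature_id)
  if (length(extra))
    stop("significant features not in the reference list: ",
         paste(utils::head(extra, 5), collapse = ", "))

  f2k <- feature_kegg_map(ref_features, library, adducts, tol_ppm)
  ref_kegg <- unique(unlist(f2k, use.names = FALSE))
  sig_kegg <- unique(unlist(f2k[intersect(sig_features$feature_id,
                                          names(f2k))], use.names = FALSE))
  n_sig <- nrow(sig_features); n_ref <- nrow(ref_features)

  size_ref <- vapply(pathways, function(p) length(intersect(p, ref_kegg)),
                     integer(1))
  obs_hits <- vapply(pathways, function(p) length(intersect(p, sig_kegg)),
                     integer(1))
  overlap <- vapply(pathways, function(p)
    paste(sort(intersect(p, sig_kegg)), collapse = ";"), "")
  expected <- size_ref * n_sig / n_ref
  ratio <- ifelse(expected > 0, obs_hits / expected, 0)

  # permutation null: resample significant-sized feature lists
  set.seed(seed)
  ref_ids <- ref_features$feature_id
  exceed <- integer(length(pathways))
  for (b in seq_len(n_perm)) {
    draw <- sample(ref_ids, n_sig)
    kegg_b <- unique(unlist(f2k[intersect(draw, names(f2k))],
                            use.names = FALSE))
    hits_b <- vapply(pathways, function(p) length(intersect(p, kegg_b)),
                     integer(1))
    exceed <- exceed + (hits_b >= obs_hits)
  }
  p_perm <- (1 + exceed) / (n_perm + 1)

  out <- data.frame(pathway = names(pathways), hits = obs_hits,
                    pathway_size_in_reference = size_ref,
                    expected = expected, enrichment_ratio = ratio,
                    p_perm = p_perm, overlap_compounds = overlap,
                    row.names = NULL)
  out <- out[order(out$p_perm, -out$enrichment_ratio), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}
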