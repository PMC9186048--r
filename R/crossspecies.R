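#' Collapse one species' results to KEGG-level associations
#'
#' Keeps features significant at `alpha` that carry at least one
#' KEGG-annotated hit, then collapses to one entry per KEGG ID. The entry's
#' direction is that of its minimum-p supporting feature; KEGG IDs whose
#' supporting features disagree in sign are flagged ambiguous, excluded from
#' the result, and reported in the `ambiguous` element (never silently
#' resolved by vote).
#'
#' @param assoc association results with `feature_id`, `direction`,
#'   `p_value` (e.g. from [mwas_linear()], [ttest_two_group()], or
#'   [significant_features()])
#' @param hits annotation hits from [search_annotations()]
#' @param alpha significance threshold
#' @param species label carried into overlap reports
#' @return object of class `species_result`: `table` (data.frame `kegg_id`,
#'   `name`, `direction`, `p_value`, `features`), `ambiguous` (excluded KEGG
#'   IDs), `species`, `alpha`
#' @export
build_species_result <- function(assoc, hits, alpha = 0.05,
                                 species = "species") {
  stopifnot(all(c("feature_id", "direction", "p_value") %in% names(assoc)))
  sig <- assoc[!is.na(assoc$p_value) & assoc$p_value < alpha &
                 assoc$direction %in% c("+", "-"), , drop = FALSE]
  k <- hits[!is.na(hits$kegg_id), , drop = FALSE]
  j <- merge(sig, k[, c("feature_id", "kegg_id", "name")], by = "feature_id")
  if (nrow(j) == 0L)
    return(structure(list(table = data.frame(kegg_id = character(),
                                             name = character(),
                                             direction = character(),
                                             p_value = numeric(),
                                             features = character()),
                          ambiguous = character(), species = species,
                          alpha = alpha),
                     class = "species_result"))
  j <- j[!duplicated(j[c("feature_id", "kegg_id")]), , drop = FALSE]
  entries <- lapply(split(j, j$kegg_id), function(d) {
    if (length(unique(d$direction)) > 1L) return(NULL)       # ambiguous
    best <- d[which.min(d$p_value), , drop = FALSE]
    data.frame(kegg_id = best$kegg_id, name = best$name,
               direction = best$direction, p_value = best$p_value,
               features = paste(sort(unique(d$feature_id)), collapse = ";"))
  })
  ambiguous <- names(entries)[vapply(entries, is.null, logical(1))]
  if (length(ambiguous))
    warning(species, ": KEGG ID(s) with conflicting association directions ",
            "excluded: ", paste(ambiguous, collapse = ", "))
  tab <- do.call(rbind, entries[!vapply(entries, is.null, logical(1))])
  tab <- tab %||% data.frame(kegg_id = character(), name = character(),
                             direction = character(), p_value = numeric(),
                             features = character())
  rownames(tab) <- NULL
  structure(list(table = tab[order(tab$kegg_id), , drop = FALSE],
                 ambiguous = ambiguous, species = species, alpha = alpha),
            class = "species_result")
}

#' @export
print.species_result <- function(x, ...) {
  cat(sprintf("species_result '%s': %d KEGG-annotated significant metabolites",
              x$species, nrow(x$table)),
      sprintf("(alpha = %g)\n", x$alpha))
  if (length(x$ambiguous))
    cat("  excluded as direction-ambiguous:",
        paste(x$ambiguous, collapse = ", "), "\n")
  invisible(x)
}

#' Direction-concordant cross-species metabolite overlap
#'
#' A metabolite overlaps between two species when it is significantly
#' associated in both, carries a KEGG annotation in both, and the direction
#' of association agrees. Shared KEGG IDs with opposite signs are reported
#' separately as discordant, never counted as overlap.
#'
#' @param a,b `species_result` objects built at the same alpha
#' @return object of class `overlap_report`: `overlap` (data.frame
#'   `kegg_id`, `name`, `direction`, per-species p-values and features),
#'   `discordant` (shared IDs with opposite signs), and the per-species
#'   counts
#' @export
concordant_overlap <- function(a, b) {
  stopifnot(inherits(a, "species_result"), inherits(b, "species_result"))
  if (!isTRUE(all.equal(a$alpha, b$alpha)))
    stop("species results built at different alpha (", a$alpha, " vs ",
         b$alpha, ")")
  m <- merge(a$table, b$table, by = "kegg_id",
             suffixes = paste0("_", make.names(c(a$species, b$species),
                                               unique = TRUE)))
  dcol <- grep("^direction_", names(m))
  conc <- m[m[[dcol[1]]] == m[[dcol[2]]], , drop = FALSE]
  disc <- m[m[[dcol[1]]] != m[[dcol[2]]], , drop = FALSE]
  names(conc)[names(conc) == grep("^name_", names(conc), value = TRUE)[1]] <-
    "name"
  conc$direction <- conc[[grep("^direction_", names(conc))[1]]]
  keep <- c("kegg_id", "name", "direction",
            grep("^(p_value|features)_", names(conc), value = TRUE))
  conc <- conc[order(conc$kegg_id), intersect(keep, names(conc)),
               drop = FALSE]
  rownames(conc) <- NULL
  structure(list(overlap = conc,
                 discordant = sort(disc$kegg_id),
                 n_overlap = nrow(conc),
                 counts = stats::setNames(c(nrow(a$table), nrow(b$table)),
                                          c(a$species, b$species)),
                 species = c(a$species, b$species), alpha = a$alpha),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report %s vs %s (alpha = %g):\n", x$species[1],
              x$species[2], x$alpha))
  cat(sprintf("  %d and %d annotated significant metabolites; %d concordant",
              x$counts[1], x$counts[2], x$n_overlap),
      sprintf("overlaps, %d discordant\n", length(x$discordant)))
  if (x$n_overlap > 0)
    print(x$overlap[c("kegg_id", "name", "direction")])
  invisible(x)
}
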