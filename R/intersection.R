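#' Normalize a metabolite name for matching
#'
#' Metabolite identity across tables is exact string match after whitespace
#' normalization. Published tables occasionally carry a formatting artifact
#' where a space inside a name is replaced by a dot (e.g. `"Butyl.methacrylate"`
#' vs `"Butyl methacrylate"`), so a dot between word characters is mapped to
#' a space. Names with genuine decimal points would be altered by this rule;
#' lipid nomenclature does not use them.
#'
#' @param x character vector of metabolite names.
#' @return normalized names.
#' @export
normalize_metabolite_name <- function(x) {
  x <- gsub("(?<=[A-Za-z0-9])\\.(?=[A-Za-z0-9])", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Common metabolites across the three classifier models of one comparison
#'
#' Partitions the overlaps of the three per-classifier feature sets into four
#' pairwise-disjoint sets: metabolites found by all three models, and those
#' found by exactly each pair (each pairwise set excludes the triple
#' intersection).
#'
#' @param knn_feats,nearcent_feats,svm_feats metabolite name sets selected by
#'   each classifier's model.
#' @return list of class `comparison_intersection` with sorted character
#'   vectors `all_three`, `knn_nearcent`, `knn_svm`, `nearcent_svm`.
#' @export
within_comparison_sets <- function(knn_feats, nearcent_feats, svm_feats) {
  k <- unique(normalize_metabolite_name(knn_feats))
  n <- unique(normalize_metabolite_name(nearcent_feats))
  s <- unique(normalize_metabolite_name(svm_feats))
  triple <- intersect(intersect(k, n), s)
  structure(list(all_three = sort(triple),
                 knn_nearcent = sort(setdiff(intersect(k, n), triple)),
                 knn_svm = sort(setdiff(intersect(k, s), triple)),
                 nearcent_svm = sort(setdiff(intersect(n, s), triple))),
            class = "comparison_intersection")
}

#' @export
print.comparison_intersection <- function(x, ...) {
  cat(sprintf("<comparison_intersection> all three: %d | KNN&NEARCENT: %d | KNN&SVM: %d | NEARCENT&SVM: %d\n",
              length(x$all_three), length(x$knn_nearcent),
              length(x$knn_svm), length(x$nearcent_svm)))
  invisible(x)
}

reported_union <- function(sets) {
  if (inherits(sets, "comparison_intersection"))
    return(unique(unlist(sets, use.names = FALSE)))
  unique(normalize_metabolite_name(unlist(sets, use.names = FALSE)))
}

#' Metabolites recurring across stage comparisons
#'
#' Given, per comparison, the reported common-metabolite sets (any of the
#' four sets from [within_comparison_sets()], or a plain name vector), lists
#' for every metabolite the comparisons containing it and nominates as
#' progression candidates those appearing in two or more comparisons —
#' metabolites whose discriminative value persists along the disease
#' progression.
#'
#' @param reported_sets named list, one element per comparison: a
#'   `comparison_intersection` or a character vector of metabolite names.
#' @return list of class `intersection_report`: `occurrence` (data frame
#'   `metabolite`, `n_comparisons`, `comparisons`, every metabolite seen) and
#'   `progression_candidates` (the subset with `n_comparisons >= 2`, sorted
#'   by count descending then name).
#' @export
cross_comparison <- function(reported_sets) {
  if (length(reported_sets) < 2L)
    stop_config("need reported sets from >= 2 comparisons")
  if (is.null(names(reported_sets)))
    stop_config("reported_sets must be named by comparison")
  per_comp <- lapply(reported_sets, reported_union)
  long <- data.frame(
    comparison = rep(names(per_comp), lengths(per_comp)),
    metabolite = unlist(per_comp, use.names = FALSE))
  occ <- lapply(split(long$comparison, long$metabolite), unique)
  df <- data.frame(metabolite = names(occ),
                   n_comparisons = lengths(occ),
                   comparisons = vapply(occ, paste, character(1),
                                        collapse = "; "),
                   row.names = NULL)
  cand <- df[df$n_comparisons >= 2L, ]
  cand <- cand[order(-cand$n_comparisons, cand$metabolite), ]
  rownames(cand) <- NULL
  structure(list(occurrence = df, progression_candidates = cand),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("<intersection_report> %d metabolites seen, %d progression candidates (>= 2 comparisons)\n",
              nrow(x$occurrence), nrow(x$progression_candidates)))
  if (nrow(x$progression_candidates))
    print(utils::head(x$progression_candidates, 10))
  invisible(x)
}
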