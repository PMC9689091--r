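# Bundled reference results from a serum-lipidomics study of T2DM
# progression: the best forward-selected model per stage comparison, the
# full comparison x classifier accuracy grid, and the published
# common-metabolite tables. Shipped as plain TSV under
# inst/extdata/reference and used as worked examples and test oracles.

reference_path <- function(file) {
  p <- system.file("extdata", "reference", file, package = "metaboga")
  if (p == "") stop_format("reference fixture %s not found", file)
  p
}

read_ref_tsv <- function(file) {
  utils::read.delim(reference_path(file), stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

#' Bundled best-model feature lists
#'
#' The forward-selected feature list of the best-performing classifier for
#' each of the five stage comparisons (5, 5, 28, 24 and 17 metabolites for
#' Control-Prediabetes, Control-T2DM, Prediabetes-T2DM, Control-DN and
#' T2DM-DN).
#'
#' @return data frame with columns `comparison`, `method`, `feature`.
#' @export
reference_model_features <- function() {
  read_ref_tsv("model_features.tsv")
}

#' Bundled comparison x classifier accuracy grid
#'
#' Average cross-validated accuracies of all 15 genetic-algorithm models
#' (5 comparisons x 3 classifiers); input for [best_models_table()].
#'
#' @return data frame with columns `comparison`, `method`,
#'   `average_accuracy`.
#' @export
reference_model_accuracies <- function() {
  read_ref_tsv("model_accuracies.tsv")
}

#' Bundled common-metabolite tables
#'
#' Per comparison, the published partition of metabolites common to the
#' three classifier models: found by all three, or by exactly one pair.
#' Suitable as `reported_sets` for [cross_comparison()].
#'
#' @return named list (one element per comparison) of lists with character
#'   vectors `all_three`, `knn_nearcent`, `knn_svm`, `nearcent_svm`.
#' @export
reference_intersections <- function() {
  df <- read_ref_tsv("common_metabolites.tsv")
  comps <- unique(df$comparison)
  sets <- c("all_three", "knn_nearcent", "knn_svm", "nearcent_svm")
  out <- lapply(comps, function(cm) {
    sub <- df[df$comparison == cm, ]
    stats::setNames(lapply(sets, function(s) sub$metabolite[sub$set == s]),
                    sets)
  })
  stats::setNames(out, comps)
}
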