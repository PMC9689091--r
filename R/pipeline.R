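#' Configuration for the full selection pipeline
#'
#' Gathers every tunable of the end-to-end analysis: inclusion filtering,
#' PQN, the genetic-algorithm blast per comparison and classifier, forward
#' selection, and reporting. All defaults mirror the standard setup
#' (5-feature chromosomes, goal fitness 1, 200 generations, 2100 bigbangs);
#' `bigbangs`, `max_generations` and `population_size` are what to reduce
#' for desk-scale runs.
#'
#' @param methods classifiers to run per comparison.
#' @param chromosome_size,goal_fitness,bigbangs,max_generations,population_size,mutation_rate,elite_count
#'   GA settings, see [ga_config()].
#' @param knn_k,svm_sigma,svm_cost classifier settings, see
#'   [classifier_spec()].
#' @param cv_splits,cv_repeats,cv_stratified cross-validation scheme, see
#'   [cv_scheme()].
#' @param forward_max_size,forward_tolerance forward-selection settings, see
#'   [forward_select()].
#' @param pqn_reference,pqn_quotient PQN settings, see [pqn_normalize()].
#' @param seed master seed; every stage's randomness derives from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(methods = c("knn", "nearcent", "svm"),
                            chromosome_size = 5L, goal_fitness = 1,
                            bigbangs = 2100L, max_generations = 200L,
                            population_size = 50L, mutation_rate = 0.05,
                            elite_count = 2L,
                            knn_k = 3L, svm_sigma = NULL, svm_cost = 1,
                            cv_splits = 5L, cv_repeats = 4L,
                            cv_stratified = TRUE,
                            forward_max_size = 30L,
                            forward_tolerance = 0.01,
                            pqn_reference = "median",
                            pqn_quotient = "median",
                            seed = 1L) {
  methods <- match.arg(methods, c("knn", "nearcent", "svm"),
                       several.ok = TRUE)
  structure(list(methods = methods,
                 chromosome_size = as.integer(chromosome_size),
                 goal_fitness = goal_fitness,
                 bigbangs = as.integer(bigbangs),
                 max_generations = as.integer(max_generations),
                 population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 knn_k = as.integer(knn_k),
                 svm_sigma = svm_sigma, svm_cost = svm_cost,
                 cv_splits = as.integer(cv_splits),
                 cv_repeats = as.integer(cv_repeats),
                 cv_stratified = isTRUE(cv_stratified),
                 forward_max_size = as.integer(forward_max_size),
                 forward_tolerance = forward_tolerance,
                 pqn_reference = pqn_reference,
                 pqn_quotient = pqn_quotient,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of the [pipeline_config()] arguments as
#' top-level keys; unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop_config("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

spec_for_method <- function(config, method) {
  switch(method,
         knn = classifier_spec("knn", k = config$knn_k),
         nearcent = classifier_spec("nearcent"),
         svm = classifier_spec("svm", sigma = config$svm_sigma,
                               cost = config$svm_cost))
}

#' Run the complete metabolite-selection pipeline
#'
#' Executes inclusion filtering, PQN normalization, the five pairwise
#' stage-comparison splits, one genetic-algorithm blast per comparison and
#' classifier, forward selection of each blast's gene rank, the accuracy
#' summary with the best model flagged per comparison, and the
#' within-/cross-comparison metabolite intersection report. Fully
#' reproducible from `config$seed`: rerunning with the same inputs and
#' configuration writes byte-identical reports.
#'
#' @param table the input samples x metabolites data: a [feature_table()], a
#'   `synthetic_dataset`, a data frame (as from
#'   `read_feature_table(strict = FALSE)`), or a CSV path.
#' @param config a [pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @param out_dir optional directory for the report bundle (`report.json`,
#'   `report.md`, one `gene_rank_*.tsv` per comparison x method,
#'   `filter_log.tsv`).
#' @return an object of class `pipeline_result`: `inclusion`, `pqn`
#'   quotients, `ga_runs`, `forward_models`, `summary`, `intersections`,
#'   `cross` and `config`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(table)) table <- read_feature_table(table, strict = FALSE)
  if (inherits(table, "synthetic_dataset")) table <- table$table

  incl <- apply_inclusion(table)
  pqn <- pqn_normalize(incl$table, reference = config$pqn_reference,
                       quotient = config$pqn_quotient)
  comparisons <- make_comparisons(pqn$table)

  scheme <- cv_scheme(config$cv_splits, config$cv_repeats,
                      config$cv_stratified, seed = config$seed)
  pairs <- expand.grid(comparison = names(comparisons),
                       method = config$methods,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(match(pairs$comparison, names(comparisons)),
                       match(pairs$method, config$methods)), ]
  ga_seeds <- spawn_seeds(config$seed, nrow(pairs))

  ga_runs <- list()
  models <- list()
  for (i in seq_len(nrow(pairs))) {
    cm <- pairs$comparison[i]
    method <- pairs$method[i]
    key <- paste(cm, method, sep = "|")
    spec <- spec_for_method(config, method)
    cfg <- ga_config(chromosome_size = config$chromosome_size,
                     goal_fitness = config$goal_fitness,
                     max_generations = config$max_generations,
                     max_solutions = config$bigbangs,
                     population_size = config$population_size,
                     mutation_rate = config$mutation_rate,
                     elite_count = config$elite_count,
                     classifier = spec, cv = scheme,
                     seed = ga_seeds[i])
    run <- tryCatch(run_blast(comparisons[[cm]], cfg), error = function(e)
      stop(sprintf("GA blast failed for %s / %s: %s", cm, method,
                   conditionMessage(e)), call. = FALSE))
    mdl <- tryCatch(
      forward_select(run$gene_rank, comparisons[[cm]], spec = spec,
                     scheme = scheme, max_size = config$forward_max_size,
                     tolerance = config$forward_tolerance),
      error = function(e)
        stop(sprintf("forward selection failed for %s / %s: %s", cm, method,
                     conditionMessage(e)), call. = FALSE))
    ga_runs[[key]] <- run
    models[[key]] <- mdl
  }

  summary_df <- best_models_table(unname(models))

  intersections <- NULL
  cross <- NULL
  if (all(c("knn", "nearcent", "svm") %in% config$methods)) {
    intersections <- lapply(names(comparisons), function(cm)
      within_comparison_sets(
        models[[paste(cm, "knn", sep = "|")]]$features,
        models[[paste(cm, "nearcent", sep = "|")]]$features,
        models[[paste(cm, "svm", sep = "|")]]$features))
    names(intersections) <- names(comparisons)
    cross <- cross_comparison(intersections)
  }

  result <- structure(list(inclusion = incl,
                           quotients = pqn$quotients,
                           comparisons = names(comparisons),
                           ga_runs = ga_runs,
                           forward_models = models,
                           summary = summary_df,
                           intersections = intersections,
                           cross = cross,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d comparisons x %d methods = %d forward models\n",
              length(x$comparisons), length(x$config$methods),
              length(x$forward_models)))
  print(x$summary)
  if (!is.null(x$cross)) {
    cat("progression candidates:\n")
    print(x$cross$progression_candidates)
  }
  invisible(x)
}

report_as_list <- function(result) {
  models <- lapply(unname(result$forward_models), function(m)
    list(comparison = m$comparison, method = m$method,
         features = m$features, chosen_size = m$chosen_size,
         average_accuracy = m$average_accuracy,
         size_curve = m$size_curve))
  out <- list(seed = result$config$seed,
              methods = result$config$methods,
              bigbangs = result$config$bigbangs,
              comparisons = result$comparisons,
              quotients = as.list(result$quotients),
              models = models,
              summary = result$summary)
  if (!is.null(result$intersections)) {
    out$intersections <- lapply(result$intersections, unclass)
    out$progression_candidates <- result$cross$progression_candidates
  }
  out
}

#' Write the machine- and human-readable report bundle
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_as_list(result),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_filter_log(result$inclusion, file.path(out_dir, "filter_log.tsv"))
  for (key in names(result$ga_runs)) {
    run <- result$ga_runs[[key]]
    rk <- data.frame(rank = seq_along(run$gene_rank),
                     feature = run$feature_names[run$gene_rank],
                     frequency = as.integer(
                       run$gene_frequency[run$gene_rank]))
    fname <- paste0("gene_rank_", gsub("[^A-Za-z0-9]+", "_", key), ".tsv")
    utils::write.table(rk, file.path(out_dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  writeLines(report_markdown(result), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_markdown <- function(result) {
  lines <- c("# Metabolite selection report", "",
             "## Model accuracies", "")
  s <- result$summary
  lines <- c(lines,
             "| comparison | method | average accuracy | best |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %.4f | %s |", s$comparison, s$method,
                     s$average_accuracy, ifelse(s$best, "**yes**", "")))
  for (key in names(result$forward_models)) {
    m <- result$forward_models[[key]]
    lines <- c(lines, "",
               sprintf("## %s / %s (%d features, accuracy %.4f)",
                       m$comparison, m$method, m$chosen_size,
                       m$average_accuracy),
               "", paste0("- ", m$features))
  }
  if (!is.null(result$cross)) {
    pc <- result$cross$progression_candidates
    lines <- c(lines, "", "## Progression candidates", "")
    lines <- c(lines, if (nrow(pc))
      sprintf("- %s (%d comparisons: %s)", pc$metabolite,
              pc$n_comparisons, pc$comparisons)
      else "(none)")
  }
  lines
}
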