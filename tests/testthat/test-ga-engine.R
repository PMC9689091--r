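fast_scheme <- cv_scheme(5, 1, TRUE, seed = 1)

test_that("configuration invariants are enforced", {
  expect_error(ga_config(goal_fitness = 0), class = "metaboga_config_error")
  expect_error(ga_config(max_generations = 0),
               class = "metaboga_config_error")
  expect_error(ga_config(population_size = 1),
               class = "metaboga_config_error")
  expect_error(ga_config(elite_count = 50, population_size = 50),
               class = "metaboga_config_error")
  ds <- planted_comparison(n_per_group = 5, n_features = 4, n_planted = 1,
                           seed = 1)
  cfg <- ga_config(chromosome_size = 10, max_solutions = 1,
                   max_generations = 1, cv = fast_scheme)
  expect_error(evolve_one(ds$comparison, cfg, 1),
               "chromosome_size", class = "metaboga_config_error")
})

test_that("a perfect feature present everywhere stops the search at generation 0", {
  # one feature separates the classes perfectly and chromosomes cover 2 of
  # 3 features, so a modest generation-0 population is sure to carry it
  ds <- planted_comparison(n_per_group = 10, n_features = 3, n_planted = 1,
                           effect = 60, noise_sd = 1, seed = 31)
  cfg <- ga_config(chromosome_size = 2, goal_fitness = 1,
                   max_generations = 50, max_solutions = 1,
                   population_size = 20,
                   classifier = classifier_spec("nearcent"),
                   cv = fast_scheme, seed = 7)
  sol <- evolve_one(ds$comparison, cfg, bigbang_seed = 101)
  expect_equal(sol$generations, 0L)
  expect_equal(sol$fitness, 1)
  expect_length(sol$trace, 1L)
})

test_that("one-generation searches return the fitter evaluated chromosome", {
  ds <- planted_comparison(n_per_group = 8, n_features = 10, n_planted = 2,
                           effect = 2, noise_sd = 1, seed = 32)
  cfg <- ga_config(chromosome_size = 3, goal_fitness = 1,
                   max_generations = 1, max_solutions = 1,
                   population_size = 2, elite_count = 1,
                   cv = fast_scheme, seed = 3)
  sol <- evolve_one(ds$comparison, cfg, bigbang_seed = 55)
  expect_lte(length(sol$trace), 2L)
  expect_equal(sol$fitness, max(sol$trace))
  # the reported fitness is reproducible from the reported genes
  redo <- cv_average_accuracy(ds$comparison, features = sol$genes,
                              spec = cfg$classifier, scheme = cfg$cv)
  expect_equal(redo$average_accuracy, sol$fitness)
})

test_that("chromosome validity and monotone best fitness hold across searches", {
  ds <- planted_comparison(n_per_group = 8, n_features = 15, n_planted = 2,
                           effect = 2, noise_sd = 1, seed = 33)
  cfg <- ga_config(chromosome_size = 4, goal_fitness = 1,
                   max_generations = 6, max_solutions = 6,
                   population_size = 12, cv = fast_scheme, seed = 13)
  run <- run_blast(ds$comparison, cfg)
  for (sol in run$solutions) {
    expect_length(sol$genes, 4L)
    expect_false(anyDuplicated(sol$genes) > 0)
    expect_true(all(sol$genes >= 1 & sol$genes <= 15))
    expect_true(all(diff(sol$trace) >= 0))
    expect_true(all(sol$trace >= 0 & sol$trace <= 1))
  }
})

test_that("gene frequency is conserved and ranks are a deterministic permutation", {
  ds <- planted_comparison(n_per_group = 6, n_features = 12, n_planted = 1,
                           effect = 3, noise_sd = 1, seed = 34)
  cfg <- ga_config(chromosome_size = 3, max_generations = 3,
                   max_solutions = 1, population_size = 8,
                   cv = fast_scheme, seed = 2)
  one <- run_blast(ds$comparison, cfg)
  expect_equal(sum(one$gene_frequency), 3L)

  cfg7 <- ga_config(chromosome_size = 3, max_generations = 3,
                    max_solutions = 7, population_size = 8,
                    cv = fast_scheme, seed = 2)
  many <- run_blast(ds$comparison, cfg7)
  expect_equal(sum(many$gene_frequency), 3L * 7L)
  expect_setequal(many$gene_rank, 1:12)
  # frequency ties broken by feature index
  fr <- unname(many$gene_frequency)
  expect_identical(many$gene_rank, order(-fr, seq_along(fr)))
})

test_that("blasts are deterministic and reduced runs are prefixes", {
  ds <- planted_comparison(n_per_group = 6, n_features = 10, n_planted = 2,
                           effect = 2, noise_sd = 1, seed = 35)
  mk <- function(nb) ga_config(chromosome_size = 3, max_generations = 3,
                               max_solutions = nb, population_size = 8,
                               cv = fast_scheme, seed = 77)
  a <- run_blast(ds$comparison, mk(5))
  b <- run_blast(ds$comparison, mk(5))
  expect_identical(a$gene_frequency, b$gene_frequency)
  expect_identical(lapply(a$solutions, `[[`, "genes"),
                   lapply(b$solutions, `[[`, "genes"))
  shorter <- run_blast(ds$comparison, mk(3))
  expect_identical(lapply(shorter$solutions, `[[`, "genes"),
                   lapply(a$solutions[1:3], `[[`, "genes"))
})

test_that("the best chromosome matches exhaustive enumeration at small scale", {
  ds <- planted_comparison(n_per_group = 8, n_features = 12, n_planted = 2,
                           effect = 4, noise_sd = 1, seed = 36)
  spec <- classifier_spec("knn")
  combos <- utils::combn(12, 2)
  exhaustive <- apply(combos, 2L, function(g)
    cv_average_accuracy(ds$comparison, features = g, spec = spec,
                        scheme = fast_scheme)$average_accuracy)
  cfg <- ga_config(chromosome_size = 2, max_generations = 8,
                   max_solutions = 8, population_size = 16,
                   classifier = spec, cv = fast_scheme, seed = 5)
  run <- run_blast(ds$comparison, cfg)
  best <- max(vapply(run$solutions, `[[`, numeric(1), "fitness"))
  expect_equal(best, max(exhaustive))
  # and the planted pair is the exhaustive optimum
  top_pair <- combos[, which.max(exhaustive)]
  expect_setequal(top_pair, 1:2)
})

test_that("rank stability separates converged top genes from churn", {
  ds <- planted_comparison(n_per_group = 10, n_features = 20, n_planted = 2,
                           effect = 4, noise_sd = 1, seed = 37)
  cfg <- ga_config(chromosome_size = 3, max_generations = 5,
                   max_solutions = 12, population_size = 12,
                   cv = fast_scheme, seed = 11)
  run <- run_blast(ds$comparison, cfg)
  stab <- rank_stability(run, window = 6)
  expect_length(stab, 20L)
  # planted features' ranks settle more than the average noise feature
  expect_lte(mean(stab[1:2]), mean(stab[-(1:2)]))
  expect_warning(rank_stability(run, window = 50), "clipped")
  expect_error(rank_stability(
    run_blast(ds$comparison,
              ga_config(chromosome_size = 3, max_generations = 1,
                        max_solutions = 1, population_size = 4,
                        cv = fast_scheme, seed = 1)), 3),
    "snapshots", class = "metaboga_config_error")
})

test_that("fully converged runs have zero rank dispersion everywhere", {
  # one overwhelming planted feature and single-gene chromosomes: every
  # bigbang settles on that gene, the frequency support never changes, and
  # every feature's rank -- including the tie-broken absent tail -- is frozen
  ds <- planted_comparison(n_per_group = 10, n_features = 8, n_planted = 1,
                           effect = 30, noise_sd = 1, seed = 38)
  cfg <- ga_config(chromosome_size = 1, max_generations = 8,
                   max_solutions = 5, population_size = 48,
                   classifier = classifier_spec("nearcent"),
                   cv = fast_scheme, seed = 3)
  run <- run_blast(ds$comparison, cfg)
  solutions <- lapply(run$solutions, `[[`, "genes")
  expect_length(unique(solutions), 1L)
  expect_identical(solutions[[1]], 1L)
  stab <- rank_stability(run, window = ncol(run$rank_trace))
  expect_true(all(stab == 0))
  # absent features sit at the index-ordered tail
  expect_identical(run$gene_rank, c(1L, 2:8))
})
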