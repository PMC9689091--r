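#' Genetic-algorithm search settings
#'
#' Configuration of the GALGO-style wrapper search: many independent
#' "bigbang" searches each evolve a population of fixed-size chromosomes
#' (sets of `chromosome_size` distinct feature indices) whose fitness is the
#' cross-validated average accuracy of a classifier restricted to those
#' features. A search stops as soon as `goal_fitness` is reached or after
#' `max_generations`.
#'
#' Defaults follow the usual GALGO setup for metabolomic panels:
#' 5-feature chromosomes, goal fitness 1, 200 generations, 2100 bigbangs,
#' population 50, per-gene mutation rate 0.05, 2 elites and
#' fitness-proportional (roulette) parent selection.
#'
#' @param chromosome_size features per chromosome.
#' @param goal_fitness stop a search once best fitness reaches this
#'   (in `(0, 1]`).
#' @param max_generations generation cap per bigbang.
#' @param max_solutions number of independent bigbang searches.
#' @param population_size chromosomes per generation (>= 2).
#' @param mutation_rate per-gene probability of mutating to a random unused
#'   feature.
#' @param elite_count fittest chromosomes copied unchanged each generation.
#' @param classifier a [classifier_spec()] (the fitness function).
#' @param cv a [cv_scheme()] used inside the fitness function.
#' @param seed master seed; one child seed is spawned per bigbang, so runs
#'   with fewer bigbangs are prefixes of longer runs.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(chromosome_size = 5L, goal_fitness = 1,
                      max_generations = 200L, max_solutions = 2100L,
                      population_size = 50L, mutation_rate = 0.05,
                      elite_count = 2L,
                      classifier = classifier_spec("knn"),
                      cv = cv_scheme(), seed = 1L) {
  if (goal_fitness <= 0 || goal_fitness > 1)
    stop_config("goal_fitness must be in (0, 1]")
  if (max_generations < 1) stop_config("max_generations must be >= 1")
  if (max_solutions < 1) stop_config("max_solutions (bigbangs) must be >= 1")
  if (population_size < 2) stop_config("population_size must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_config("mutation_rate must be in [0, 1]")
  if (elite_count < 0 || elite_count >= population_size)
    stop_config("elite_count must be in [0, population_size)")
  stopifnot(inherits(classifier, "classifier_spec"),
            inherits(cv, "cv_scheme"))
  structure(list(chromosome_size = as.integer(chromosome_size),
                 goal_fitness = goal_fitness,
                 max_generations = as.integer(max_generations),
                 max_solutions = as.integer(max_solutions),
                 population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 classifier = classifier, cv = cv,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Chromosome validity: exactly `size` distinct in-range gene indices.
assert_population <- function(pop, size, n_features) {
  ok <- apply(pop, 1L, function(g)
    length(g) == size && !anyDuplicated(g) && all(g >= 1L & g <= n_features))
  if (!all(ok))
    stop("internal error: invalid chromosome after genetic operator")
  invisible(TRUE)
}

# Fitness of one gene set, memoised on the sorted gene key. The cache is
# valid for one (data, classifier, cv) combination; identical subsets recur
# constantly across bigbangs, so this is what makes thousands of bigbangs
# tractable, and it cannot change any result.
chromosome_fitness <- function(genes, ctx, cache) {
  key <- paste(sort(genes), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- mean(ctx_accuracy(ctx, genes))
  cache[[key]] <- val
  val
}

# Uniform crossover of two gene sets with duplicate repair.
crossover_genes <- function(a, b, n_features) {
  pick <- stats::runif(length(a)) < 0.5
  child <- ifelse(pick, a, b)
  dup <- duplicated(child)
  if (any(dup)) {
    pool <- setdiff(union(a, b), child[!dup])
    for (i in which(dup)) {
      if (length(pool)) {
        child[i] <- pool[sample.int(length(pool), 1L)]
        pool <- setdiff(pool, child[i])
      } else {
        child[i] <- sample.int(n_features, 1L)
        while (child[i] %in% child[-i]) child[i] <- sample.int(n_features, 1L)
      }
    }
  }
  child
}

mutate_genes <- function(genes, rate, n_features) {
  hit <- stats::runif(length(genes)) < rate
  for (i in which(hit)) {
    new <- sample.int(n_features, 1L)
    while (new %in% genes) new <- sample.int(n_features, 1L)
    genes[i] <- new
  }
  genes
}

#' Run one bigbang: evolve a single population
#'
#' Initializes a random population of chromosomes, then repeatedly: evaluates
#' every chromosome's cross-validated accuracy, copies the elites, breeds
#' offspring by uniform gene crossover between roulette-selected parents and
#' mutates genes to random unused indices. Generation 0 is the evaluation of
#' the initial population; the search stops as soon as the best fitness seen
#' reaches `cfg$goal_fitness` or after `cfg$max_generations` generations.
#'
#' @param data a `comparison_dataset` (or anything [cv_average_accuracy()]
#'   accepts).
#' @param cfg a [ga_config()].
#' @param bigbang_seed seed for this search's RNG stream.
#' @param cache environment memoising fitness values (shared across bigbangs
#'   by [run_blast()]).
#' @return an object of class `ga_solution`: `genes` (sorted indices of the
#'   best chromosome seen), `fitness`, `generations` (index at which the
#'   search stopped; 0 = initial population) and `trace` (best fitness seen
#'   by each generation, non-decreasing).
#' @export
evolve_one <- function(data, cfg, bigbang_seed = cfg$seed,
                       cache = new.env(parent = emptyenv()),
                       ctx = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  ctx <- ctx %||% cv_context(data, cfg$classifier, cfg$cv)
  n_features <- ctx$n_features
  size <- cfg$chromosome_size
  if (size > n_features)
    stop_config("chromosome_size (%d) exceeds feature count (%d)",
                size, n_features)
  pop_n <- cfg$population_size

  with_seed(bigbang_seed, {
    pop <- t(vapply(seq_len(pop_n),
                    function(i) sample.int(n_features, size),
                    integer(size)))
    if (size == 1L) pop <- matrix(pop, ncol = 1L)
    best_fit <- -Inf
    best_genes <- pop[1L, ]
    trace <- numeric(0)
    gen <- 0L
    repeat {
      assert_population(pop, size, n_features)
      fit <- apply(pop, 1L, chromosome_fitness, ctx = ctx, cache = cache)
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best_genes <- pop[gen_best, ]
      }
      trace <- c(trace, best_fit)
      if (best_fit >= cfg$goal_fitness || gen >= cfg$max_generations) break
      gen <- gen + 1L

      elite_idx <- order(-fit)[seq_len(cfg$elite_count)]
      n_off <- pop_n - cfg$elite_count
      prob <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / pop_n, pop_n)
      parents <- matrix(sample.int(pop_n, 2L * n_off, replace = TRUE,
                                   prob = prob), ncol = 2L)
      offspring <- t(vapply(seq_len(n_off), function(i) {
        child <- crossover_genes(pop[parents[i, 1L], ],
                                 pop[parents[i, 2L], ], n_features)
        mutate_genes(child, cfg$mutation_rate, n_features)
      }, integer(size)))
      if (size == 1L) offspring <- matrix(offspring, ncol = 1L)
      pop <- rbind(pop[elite_idx, , drop = FALSE], offspring)
    }
    structure(list(genes = sort(best_genes), fitness = best_fit,
                   generations = gen, trace = trace),
              class = "ga_solution")
  })
}

# rank features by descending frequency, ties (including the all-zero tail)
# broken by feature index — a deterministic permutation of all features.
frequency_rank <- function(freq) {
  ord <- order(-freq, seq_along(freq))
  rank <- integer(length(freq))
  rank[ord] <- seq_along(freq)
  rank
}

#' Run a full blast: many independent bigbangs
#'
#' Executes `cfg$max_solutions` independent [evolve_one()] searches with
#' child seeds spawned deterministically from `cfg$seed` (so a reduced run is
#' a prefix of a full run) and aggregates the final chromosomes into gene
#' frequencies, a gene rank, a rank-stability trace and per-bigbang fitness
#' traces. A shared fitness cache makes repeated subsets across bigbangs
#' free.
#'
#' @param data a `comparison_dataset`.
#' @param cfg a [ga_config()].
#' @return an object of class `ga_run` with fields `solutions` (list of
#'   `ga_solution`), `gene_frequency` (named per-feature counts summing to
#'   `chromosome_size * bigbangs`), `gene_rank` (feature indices by
#'   descending frequency, ties by index), `rank_trace` (features x bigbangs
#'   matrix of rank snapshots), `fitness_traces`, `feature_names`,
#'   `comparison` and `config`.
#' @export
run_blast <- function(data, cfg) {
  stopifnot(inherits(cfg, "ga_config"))
  xy <- as_xy(data)
  n_features <- ncol(xy$x)
  ctx <- cv_context(data, cfg$classifier, cfg$cv)
  seeds <- spawn_seeds(cfg$seed, cfg$max_solutions)
  cache <- new.env(parent = emptyenv())

  freq <- integer(n_features)
  solutions <- vector("list", cfg$max_solutions)
  rank_trace <- matrix(NA_integer_, n_features, cfg$max_solutions)
  for (b in seq_len(cfg$max_solutions)) {
    sol <- evolve_one(data, cfg, bigbang_seed = seeds[b], cache = cache,
                      ctx = ctx)
    solutions[[b]] <- sol
    freq[sol$genes] <- freq[sol$genes] + 1L
    rank_trace[, b] <- frequency_rank(freq)
  }
  fn <- colnames(xy$x) %||% paste0("F", seq_len(n_features))
  structure(list(solutions = solutions,
                 gene_frequency = stats::setNames(freq, fn),
                 gene_rank = order(-freq, seq_along(freq)),
                 rank_trace = rank_trace,
                 fitness_traces = lapply(solutions, `[[`, "trace"),
                 feature_names = fn,
                 comparison = if (inherits(data, "comparison_dataset"))
                   data$name else NA_character_,
                 config = cfg),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  fits <- vapply(x$solutions, `[[`, numeric(1), "fitness")
  top <- x$gene_rank[1:min(5L, length(x$gene_rank))]
  cat(sprintf("<ga_run> %s: %d bigbangs, best fitness %.4f (mean %.4f)\n",
              x$comparison, length(x$solutions), max(fits), mean(fits)))
  cat("  top genes:", paste(x$feature_names[top], collapse = ", "), "\n")
  invisible(x)
}

#' Rank stability of each feature
#'
#' Dispersion (standard deviation) of each feature's rank over the trailing
#' `window` bigbang snapshots; 0 means the rank did not move. On converged
#' runs the top-ranked (truly discriminative) features settle to near-zero
#' dispersion while middling noise features keep churning.
#'
#' @param result a `ga_run` from [run_blast()].
#' @param window number of trailing snapshots to use (clipped, with a
#'   warning, to the number available; >= 2 required overall).
#' @return named numeric vector of per-feature rank dispersions.
#' @export
rank_stability <- function(result, window = 50L) {
  stopifnot(inherits(result, "ga_run"))
  n_snap <- ncol(result$rank_trace)
  if (n_snap < 2L) stop_config("need >= 2 rank snapshots")
  if (window > n_snap) {
    warning(sprintf("window (%d) clipped to %d available snapshots",
                    window, n_snap))
    window <- n_snap
  }
  if (window < 2L) window <- 2L
  tail_ranks <- result$rank_trace[, (n_snap - window + 1L):n_snap,
                                  drop = FALSE]
  stats::setNames(apply(tail_ranks, 1L, stats::sd), result$feature_names)
}

#' Plot the fitness evolution of a blast
#'
#' Mean (across bigbangs) of the best-fitness-so-far traces by generation,
#' with the goal fitness marked.
#'
#' @param x a `ga_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ga_run <- function(x, ...) {
  tr <- x$fitness_traces
  len <- max(lengths(tr))
  padded <- vapply(tr, function(t) c(t, rep(t[length(t)], len - length(t))),
                   numeric(len))
  avg <- if (len == 1L) mean(padded) else rowMeans(padded)
  graphics::plot(seq_len(len) - 1L, avg, type = "l", xlab = "generation",
                 ylab = "mean best fitness", ylim = c(min(avg), 1), ...)
  graphics::abline(h = x$config$goal_fitness, lty = 3, col = "red")
  invisible(x)
}
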