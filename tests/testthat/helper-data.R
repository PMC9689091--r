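# Small builders shared across test files. Everything is generated in code;
# no stored fixtures beyond the reference TSVs under inst/extdata.

# spec with no planted effects at all (dilution-only data)
dilution_only_spec <- function(...) {
  synthetic_spec(planted = data.frame(stage_a = character(),
                                      stage_b = character(),
                                      feature = integer(),
                                      effect = numeric()), ...)
}

# two-stage comparison dataset with `n_planted` features shifted by `effect`
# (in units of noise_sd) between the stages
planted_comparison <- function(n_per_group = 20, n_features = 100,
                               n_planted = 5, effect = 2, noise_sd = 1,
                               seed = 11) {
  sp <- synthetic_spec(
    n_per_group = n_per_group, n_features = n_features,
    stages = c("StageA", "StageB"),
    planted = data.frame(stage_a = "StageA", stage_b = "StageB",
                         feature = seq_len(n_planted), effect = effect),
    noise_sd = noise_sd, seed = seed)
  ds <- generate_dataset(sp)
  list(dataset = ds,
       comparison = structure(list(name = "StageA-StageB",
                                   table = ds$table,
                                   positive_label = "StageB"),
                              class = "comparison_dataset"))
}

# deterministic gaussian two-class toy set for classifier unit tests
toy_binary <- function(n = 20, p = 4, sep = 3, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
               matrix(rnorm(n / 2 * p, mean = sep), ncol = p))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = rep(c("neg", "pos"), each = n / 2))
  })
}
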