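#' Specification for a synthetic lipidomics dataset
#'
#' Describes a cohort of `n_per_group` samples per disease stage measured on
#' `n_features` metabolites. Intensities are log-normal: each feature has a
#' baseline log-mean shared across stages, per-sample log-normal noise of
#' standard deviation `noise_sd`, and a per-sample multiplicative dilution
#' factor drawn uniformly from `dilution_range`. Selected "planted" features
#' additionally shift their mean log-intensity between the two stages of a
#' comparison by a stated effect size, making them the ground-truth
#' discriminative metabolites the selection pipeline should recover.
#'
#' The default planted map mirrors the structure of real progression
#' biomarkers: five lipid species are shared between two or more stage
#' comparisons (so cross-comparison intersection reports are non-trivial),
#' topped up with comparison-specific features so every comparison has five
#' planted metabolites.
#'
#' `noise_sd` defaults to 0.1 log-units: feature tables of this kind have
#' passed a QC relative-standard-deviation filter (features with RSD > 20%
#' removed), leaving roughly 10% technical CV on retained features. The
#' default `effect` of 0.3 log-units (about a 35% fold change, 3 SD at that
#' noise) is a typical reported effect size for serum lipid markers.
#'
#' @param n_per_group samples per stage (default 20).
#' @param n_features number of metabolite features (default 717).
#' @param stages ordered stage labels; the progression order matters because
#'   planted shifts are applied to the later stage of each pair.
#' @param planted data frame with columns `stage_a`, `stage_b`, `feature`
#'   (column index) and `effect` (mean log-intensity shift applied to
#'   `stage_b` samples), or `NULL` for the default map. Sets for distinct
#'   pairs may overlap.
#' @param planted_names optional named character vector mapping feature index
#'   to a metabolite name to inject (used by the default map to give shared
#'   planted features recognizable lipid names).
#' @param effect effect size (log-units) used by the default planted map.
#' @param noise_sd log-intensity standard deviation.
#' @param dilution_range length-2 positive bounds of the per-sample dilution
#'   factor.
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log-means.
#' @param seed RNG seed; fixed seed gives bit-identical datasets.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 20,
                           n_features = 717,
                           stages = c("Control", "Prediabetes", "T2DM", "DN"),
                           planted = NULL,
                           planted_names = NULL,
                           effect = 0.3,
                           noise_sd = 0.1,
                           dilution_range = c(0.5, 2),
                           baseline_mean = 12,
                           baseline_sd = 1.5,
                           seed = 1L) {
  if (n_per_group < 2) stop_config("n_per_group must be >= 2")
  if (length(stages) < 2 || anyDuplicated(stages))
    stop_config("stages must be >= 2 distinct labels")
  if (length(dilution_range) != 2 || any(dilution_range <= 0) ||
      dilution_range[1] > dilution_range[2])
    stop_config("dilution_range must be positive bounds (lo <= hi)")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (is.null(planted)) {
    dp <- default_planted_map(stages, effect)
    planted <- dp$planted
    # the default map is laid out for the full-size cohort; on smaller
    # tables keep only the planted features that fit
    keep <- planted$feature <= n_features
    planted <- planted[keep, , drop = FALSE]
    planted_names <- planted_names %||%
      dp$names[as.integer(names(dp$names)) <= n_features]
  }
  planted <- as.data.frame(planted)
  req <- c("stage_a", "stage_b", "feature", "effect")
  if (!all(req %in% names(planted)))
    stop_config("planted map needs columns %s", paste(req, collapse = ", "))
  if (nrow(planted) > 0) {
    if (any(planted$feature < 1))
      stop_config("planted feature indices must be >= 1")
    if (max(planted$feature) > n_features)
      stop_config("n_features (%d) smaller than largest planted index (%d)",
                  n_features, max(planted$feature))
    if (!all(c(planted$stage_a, planted$stage_b) %in% stages))
      stop_config("planted map names a stage absent from `stages`")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_features = as.integer(n_features),
                 stages = as.character(stages),
                 planted = planted,
                 planted_names = planted_names,
                 noise_sd = noise_sd,
                 dilution_range = dilution_range,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Default ground truth: five shared "progression biomarker" lipids that recur
# across comparisons, plus comparison-specific fillers (5 planted features
# per stage pair).
default_planted_map <- function(stages, effect) {
  if (!identical(stages, c("Control", "Prediabetes", "T2DM", "DN"))) {
    # generic fallback: 5 features per consecutive pair, one shared feature
    pairs <- cbind(stages[-length(stages)], stages[-1])
    rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      feat <- c(1L, seq.int(2L + (i - 1L) * 4L, length.out = 4L))
      data.frame(stage_a = pairs[i, 1], stage_b = pairs[i, 2],
                 feature = feat, effect = effect)
    }))
    return(list(planted = rows, names = NULL))
  }
  shared <- c("Cer(d18:1/24:1) i2", "PC(20:3-OH/P-18:1)", "Ganoderic acid C2",
              "TG(16:0/17:1/18:1)", "GPEtn(18:0/20:4)")
  memb <- list(
    "Control-Prediabetes" = list(shared = c(1L, 2L), fill = 6:8),
    "Control-T2DM"        = list(shared = 3L,        fill = 9:12),
    "Prediabetes-T2DM"    = list(shared = c(2L, 3L), fill = 13:15),
    "Control-DN"          = list(shared = c(1L, 4L, 5L), fill = 16:17),
    "T2DM-DN"             = list(shared = c(1L, 4L, 5L), fill = 18:19))
  rows <- do.call(rbind, lapply(names(memb), function(nm) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    feat <- c(memb[[nm]]$shared, memb[[nm]]$fill)
    data.frame(stage_a = pair[1], stage_b = pair[2],
               feature = as.integer(feat), effect = effect)
  }))
  list(planted = rows, names = stats::setNames(shared, as.character(1:5)))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d stages x %d samples, %d features, %d planted rows\n",
              length(x$stages), x$n_per_group, x$n_features, nrow(x$planted)))
  invisible(x)
}

#' Generate a synthetic labeled feature table
#'
#' Draws a dataset according to a [synthetic_spec()]. Ground truth (planted
#' map and per-sample dilution factors) is returned alongside the table and
#' is never written into the data file, so downstream code cannot peek.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: list with `table` (a
#'   [feature_table()]), `planted` (the planted map with metabolite names
#'   attached), `dilutions` (named per-sample factors) and `spec`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_per_group = 3, n_features = 30))
#' dim(ds$table)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_stage <- length(spec$stages)
    n <- spec$n_per_group * n_stage
    p <- spec$n_features
    stages <- rep(spec$stages, each = spec$n_per_group)
    sample_ids <- sprintf("S%03d", seq_len(n))

    feat_names <- make_metabolite_names(p)
    if (!is.null(spec$planted_names)) {
      idx <- as.integer(names(spec$planted_names))
      feat_names[idx] <- unname(spec$planted_names)
    }
    if (anyDuplicated(feat_names))
      feat_names <- make.unique(feat_names, sep = " dup")

    baseline <- stats::rnorm(p, spec$baseline_mean, spec$baseline_sd)
    shift <- matrix(0, n, p)
    if (nrow(spec$planted) > 0) {
      for (r in seq_len(nrow(spec$planted))) {
        j <- spec$planted$feature[r]
        in_b <- stages == spec$planted$stage_b[r]
        shift[in_b, j] <- shift[in_b, j] + spec$planted$effect[r]
      }
    }
    logi <- matrix(baseline, n, p, byrow = TRUE) + shift +
      matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    dil <- stats::runif(n, spec$dilution_range[1], spec$dilution_range[2])
    intens <- exp(logi) * dil
    colnames(intens) <- feat_names
    rownames(intens) <- sample_ids

    planted <- spec$planted
    if (nrow(planted) > 0)
      planted$metabolite <- feat_names[planted$feature]
    structure(list(table = feature_table(intens, stages, sample_ids),
                   planted = planted,
                   dilutions = stats::setNames(dil, sample_ids),
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$table)
  cat(sprintf("  planted: %d feature-pair assignments on %d distinct features\n",
              nrow(x$planted), length(unique(x$planted$feature))))
  invisible(x)
}

# Lipid-style metabolite names, deterministic under the active RNG stream.
make_metabolite_names <- function(n) {
  classes <- c("TG", "PC", "PE", "SM", "Cer", "GPCho", "GPEtn", "DG", "PA",
               "PS", "CE", "MG", "PG", "LPC")
  nm <- character(n)
  for (i in seq_len(n)) {
    cl <- classes[(i %% length(classes)) + 1L]
    c1 <- sample(12:26, 1); d1 <- sample(0:6, 1)
    c2 <- sample(12:26, 1); d2 <- sample(0:6, 1)
    nm[i] <- if (cl %in% c("TG", "DG")) {
      sprintf("%s(%d:%d/%d:%d/%d:%d)", cl, c1, d1, c2, d2,
              sample(12:26, 1), sample(0:6, 1))
    } else if (cl %in% c("SM", "Cer")) {
      sprintf("%s(d18:%d/%d:%d)", cl, sample(0:2, 1), c1, d1)
    } else {
      sprintf("%s(%d:%d/%d:%d)", cl, c1, d1, c2, d2)
    }
  }
  # duplicate isomers get the " i2", " i3"... suffix used in LC-MS reports
  while (anyDuplicated(nm)) {
    d <- duplicated(nm)
    rep_id <- stats::ave(seq_len(n), nm, FUN = seq_along)
    nm[d] <- sprintf("%s i%d", nm[d], rep_id[d])
  }
  nm
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' The table goes to `path` as CSV; the ground truth (planted map and
#' dilutions) goes to `<path>.truth.json` so tests can recover it without it
#' ever entering the data file.
#'
#' @param ds a `synthetic_dataset` from [generate_dataset()].
#' @param path CSV path for the table.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  write_feature_table(ds$table, path)
  truth <- list(planted = ds$planted,
                dilutions = as.list(ds$dilutions))
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
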