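#' Apply the cohort inclusion filter
#'
#' Generic completeness/label filtering of a raw sample table before any
#' analysis. A sample is retained when (a) its stage label is one of the
#' recognized stages and (b) its metabolite profile is complete (no missing
#' intensities). Feature columns that are non-numeric are dropped first
#' (the table must contain only metabolomics), and any feature column still
#' missing values across the retained samples is dropped. Every exclusion is
#' recorded in a filter log.
#'
#' @param x a data frame with columns `sample_id`, `stage` and one column per
#'   metabolite (e.g. from `read_feature_table(path, strict = FALSE)`), or a
#'   [feature_table()] (returned unchanged apart from the stage filter).
#' @param stages recognized stage labels.
#' @return a list of class `inclusion_result`: `table` (clean
#'   [feature_table()]) and `log` (data frame `sample_id`, `rule`, `detail`;
#'   write with [write_filter_log()]).
#' @export
apply_inclusion <- function(x, stages = c("Control", "Prediabetes", "T2DM", "DN")) {
  if (inherits(x, "feature_table")) x <- as.data.frame(x)
  if (!is.data.frame(x) || !all(c("sample_id", "stage") %in% names(x)))
    stop_format("expected a data frame with sample_id and stage columns")
  log <- list()
  note <- function(id, rule, detail)
    log[[length(log) + 1L]] <<- data.frame(sample_id = id, rule = rule,
                                           detail = detail)

  feat_cols <- setdiff(names(x), c("sample_id", "stage"))
  numeric_ok <- vapply(x[feat_cols], function(v)
    is.numeric(v) || all(is.na(v) | !is.na(suppressWarnings(as.numeric(v)))),
    logical(1))
  for (fc in feat_cols[!numeric_ok])
    note(NA_character_, "non_numeric_feature",
         sprintf("feature \"%s\" dropped: not numeric", fc))
  feat_cols <- feat_cols[numeric_ok]
  if (length(feat_cols) == 0L)
    stop_format("no numeric metabolite columns found")
  mat <- vapply(x[feat_cols],
                function(v) suppressWarnings(as.numeric(as.character(v))),
                numeric(nrow(x)))
  if (nrow(x) == 1L) mat <- matrix(mat, nrow = 1L)
  colnames(mat) <- feat_cols

  keep <- rep(TRUE, nrow(x))
  bad_stage <- is.na(x$stage) | !(x$stage %in% stages)
  for (i in which(bad_stage))
    note(x$sample_id[i], "unrecognized_stage",
         sprintf("stage \"%s\" not in {%s}", x$stage[i],
                 paste(stages, collapse = ", ")))
  keep <- keep & !bad_stage
  incomplete <- rowSums(is.na(mat)) > 0L
  for (i in which(incomplete & keep)) {
    j <- which(is.na(mat[i, ]))[1L]
    note(x$sample_id[i], "incomplete_profile",
         sprintf("missing intensity for \"%s\"", feat_cols[j]))
  }
  keep <- keep & !incomplete
  if (!any(keep)) stop_format("no samples survive inclusion")

  mat <- mat[keep, , drop = FALSE]
  col_missing <- colSums(is.na(mat)) > 0L
  for (fc in colnames(mat)[col_missing])
    note(NA_character_, "incomplete_feature",
         sprintf("feature \"%s\" dropped: missing values among retained samples", fc))
  mat <- mat[, !col_missing, drop = FALSE]

  tab <- feature_table(mat, x$stage[keep], x$sample_id[keep])
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(sample_id = character(), rule = character(),
               detail = character())
  structure(list(table = tab, log = log_df), class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("<inclusion_result> %d samples retained, %d exclusions logged\n",
              nrow(x$table$intensities), nrow(x$log)))
  invisible(x)
}

#' Write an inclusion filter log as TSV
#' @param result an `inclusion_result` from [apply_inclusion()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(result, path) {
  utils::write.table(result$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: a reference spectrum is computed across
#' samples (median per feature by default), each sample's per-feature
#' quotients against the reference are aggregated into one most-likely
#' quotient (median by default), and the sample is divided by it. PQN assumes
#' most signals vary only through overall sample concentration, so the
#' central quotient estimates the dilution factor; features where the sample
#' or the reference is zero are excluded from the quotient.
#'
#' `regions` optionally restricts which features enter the quotient (a list
#' of `c(lower, upper)` column-index windows); `power` raises intensities to
#' the n-th power inside the quotient (the n-th root is taken afterwards so
#' quotients stay on the dilution scale). Both default to the standard
#' whole-spectrum, power-1 analysis.
#'
#' @param table a [feature_table()] with positive intensities.
#' @param reference how to build the reference spectrum: `"median"` (default)
#'   or `"mean"` over samples.
#' @param quotient how to aggregate per-feature quotients: `"median"`
#'   (default) or `"mean"`.
#' @param regions optional list of feature-index windows `c(lo, hi)`;
#'   non-overlapping and within bounds.
#' @param power positive exponent applied to intensities inside the quotient.
#' @return a list of class `pqn_result`: `table` (normalized
#'   [feature_table()]) and `quotients` (named per-sample normalization
#'   factors).
#' @export
pqn_normalize <- function(table, reference = c("median", "mean"),
                          quotient = c("median", "mean"),
                          regions = NULL, power = 1) {
  stopifnot(inherits(table, "feature_table"))
  reference <- match.arg(reference)
  quotient <- match.arg(quotient)
  if (power <= 0) stop_config("power must be > 0")
  x <- table$intensities
  p <- ncol(x)

  use <- seq_len(p)
  if (!is.null(regions)) {
    bounds <- do.call(rbind, lapply(regions, function(r) {
      if (length(r) != 2 || r[1] > r[2] || r[1] < 1 || r[2] > p)
        stop_config("region (%s) out of bounds for %d features",
                    paste(r, collapse = ", "), p)
      r
    }))
    ord <- order(bounds[, 1])
    bounds <- bounds[ord, , drop = FALSE]
    if (nrow(bounds) > 1 &&
        any(bounds[-1, 1] <= bounds[-nrow(bounds), 2]))
      stop_config("regions must be non-overlapping")
    use <- unlist(lapply(seq_len(nrow(bounds)),
                         function(i) bounds[i, 1]:bounds[i, 2]))
  }

  ref_fun <- if (reference == "median") stats::median else mean
  ref <- apply(x[, use, drop = FALSE], 2L, ref_fun)
  zero_ref <- ref <= 0
  if (any(zero_ref)) {
    warning(sprintf("%d reference features are zero and were excluded from quotients",
                    sum(zero_ref)))
    use <- use[!zero_ref]
    ref <- ref[!zero_ref]
  }
  if (length(use) == 0L) stop_config("no usable features for the quotient")

  agg <- if (quotient == "median") stats::median else mean
  q <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, use]
    ok <- xi > 0
    if (!any(ok))
      stop_format("sample \"%s\" has no nonzero feature usable for the quotient",
                  table$sample_ids[i])
    agg((xi[ok] / ref[ok])^power)^(1 / power)
  }, numeric(1))
  names(q) <- table$sample_ids

  structure(list(table = feature_table(x / q, table$stages,
                                       table$sample_ids),
                 quotients = q,
                 reference = reference, quotient = quotient),
            class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat(sprintf("<pqn_result> %d samples; quotients in [%.3g, %.3g] (%s reference, %s quotient)\n",
              length(x$quotients), min(x$quotients), max(x$quotients),
              x$reference, x$quotient))
  invisible(x)
}

comparison_pairs <- function() {
  list("Control-Prediabetes" = c("Control", "Prediabetes"),
       "Control-T2DM"        = c("Control", "T2DM"),
       "Prediabetes-T2DM"    = c("Prediabetes", "T2DM"),
       "Control-DN"          = c("Control", "DN"),
       "T2DM-DN"             = c("T2DM", "DN"))
}

#' Split a four-stage table into the five pairwise comparisons
#'
#' Builds the five two-class sub-datasets Control-Prediabetes, Control-T2DM,
#' Prediabetes-T2DM, Control-DN and T2DM-DN (in that order), each restricted
#' to samples of the two stages and keeping the input sample order. The
#' positive label is the later stage in the progression.
#'
#' @param table a [feature_table()] containing all four stages.
#' @return named list of five `comparison_dataset` objects (fields `name`,
#'   `table`, `positive_label`).
#' @export
make_comparisons <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  pairs <- comparison_pairs()
  needed <- unique(unlist(pairs))
  missing <- setdiff(needed, unique(table$stages))
  if (length(missing))
    stop_format("stage(s) absent from table: %s",
                paste(missing, collapse = ", "))
  out <- lapply(names(pairs), function(nm) {
    pair <- pairs[[nm]]
    keep <- table$stages %in% pair
    structure(list(name = nm,
                   table = feature_table(
                     table$intensities[keep, , drop = FALSE],
                     table$stages[keep], table$sample_ids[keep]),
                   positive_label = pair[2]),
              class = "comparison_dataset")
  })
  stats::setNames(out, names(pairs))
}

#' @export
print.comparison_dataset <- function(x, ...) {
  cat(sprintf("<comparison_dataset> %s: %d samples x %d features (positive = %s)\n",
              x$name, nrow(x$table$intensities), ncol(x$table$intensities),
              x$positive_label))
  invisible(x)
}
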