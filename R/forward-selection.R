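#' Forward selection of the most compact accurate model
#'
#' Walks down a gene rank adding one feature at a time, evaluating each
#' nested model's cross-validated average accuracy, and chooses the smallest
#' model whose accuracy is within `tolerance` of the curve's maximum — the
#' "most compact and accurate" rule. Exact ties between sizes go to the
#' smaller model.
#'
#' @param rank ordered feature indices or names (typically
#'   `ga_run$gene_rank`); the first `max_size` entries are considered.
#' @param data a `comparison_dataset`.
#' @param spec a [classifier_spec()].
#' @param scheme a [cv_scheme()].
#' @param max_size largest nested model evaluated (default 30).
#' @param tolerance absolute accuracy slack defining "as accurate as the
#'   best" (default 0.01).
#' @return an object of class `forward_model`: `comparison`, `method`,
#'   `features` (ordered names of the chosen model), `feature_indices`,
#'   `size_curve` (accuracy at each nested size), `chosen_size` and
#'   `average_accuracy` (`= size_curve[chosen_size]`).
#' @export
forward_select <- function(rank, data, spec = classifier_spec("knn"),
                           scheme = cv_scheme(), max_size = 30L,
                           tolerance = 0.01) {
  if (length(rank) == 0L) stop_config("empty gene rank")
  xy <- as_xy(data)
  if (is.character(rank)) {
    idx <- match(rank, colnames(xy$x))
    if (anyNA(idx))
      stop_config("unknown feature in rank: \"%s\"", rank[which(is.na(idx))[1L]])
  } else {
    idx <- as.integer(rank)
    if (any(idx < 1L | idx > ncol(xy$x)))
      stop_config("rank index out of range")
  }
  if (anyDuplicated(idx)) stop_config("rank contains duplicate features")
  max_size <- min(max_size, length(idx))
  ctx <- cv_context(data, spec, scheme)
  curve <- vapply(seq_len(max_size), function(s)
    mean(ctx_accuracy(ctx, idx[seq_len(s)])), numeric(1))
  chosen <- which(curve >= max(curve) - tolerance)[1L]
  structure(list(comparison = if (inherits(data, "comparison_dataset"))
                   data$name else NA_character_,
                 method = spec$method,
                 features = colnames(xy$x)[idx[seq_len(chosen)]],
                 feature_indices = idx[seq_len(chosen)],
                 size_curve = curve,
                 chosen_size = chosen,
                 average_accuracy = curve[chosen],
                 tolerance = tolerance),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %s / %s: %d features, average accuracy %.4f\n",
              x$comparison, x$method, x$chosen_size, x$average_accuracy))
  invisible(x)
}

#' Plot a forward-selection accuracy curve
#' @param x a `forward_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.forward_model <- function(x, ...) {
  graphics::plot(seq_along(x$size_curve), x$size_curve, type = "b",
                 xlab = "model size (features)",
                 ylab = "average accuracy", ...)
  graphics::abline(v = x$chosen_size, lty = 2)
  invisible(x)
}

#' Summarize models per comparison and flag the best
#'
#' Builds the comparison x method accuracy summary and flags, per
#' comparison, the method(s) with the maximal average accuracy (ties are all
#' flagged).
#'
#' @param models either a list of `forward_model` objects or a data frame
#'   with columns `comparison`, `method` and `average_accuracy`.
#' @return data frame `comparison`, `method`, `average_accuracy`, `best`
#'   (logical), comparisons in order of first appearance.
#' @export
best_models_table <- function(models) {
  if (is.data.frame(models)) {
    df <- models[c("comparison", "method", "average_accuracy")]
  } else {
    stopifnot(length(models) >= 1L,
              all(vapply(models, inherits, logical(1), "forward_model")))
    df <- data.frame(
      comparison = vapply(models, `[[`, character(1), "comparison"),
      method = vapply(models, `[[`, character(1), "method"),
      average_accuracy = vapply(models, `[[`, numeric(1),
                                "average_accuracy"))
  }
  df$comparison <- factor(df$comparison, levels = unique(df$comparison))
  best <- unlist(lapply(split(df$average_accuracy, df$comparison),
                        function(a) a == max(a)), use.names = FALSE)
  df <- df[order(df$comparison), ]
  df$best <- best
  df$comparison <- as.character(df$comparison)
  rownames(df) <- NULL
  df
}
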