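#' Labeled metabolomics feature table
#'
#' The central data container: a samples x metabolites matrix of positive
#' intensities with one disease-stage label per sample. Rows are samples,
#' columns are metabolite features (e.g. `"Cer(d18:1/24:1) i2"`). The table
#' must be complete: missing intensities are an error here and are handled
#' upstream by [apply_inclusion()].
#'
#' @param intensities numeric matrix (or data frame) of intensities, rows =
#'   samples, columns = metabolites; must be complete and non-negative with
#'   unique column names.
#' @param stages character vector of per-sample stage labels, one per row.
#' @param sample_ids sample identifiers; defaults to the matrix row names or
#'   `"S1"..."Sn"`.
#' @return an object of class `feature_table` with fields `sample_ids`,
#'   `stages` and `intensities`.
#' @seealso [read_feature_table()], [write_feature_table()],
#'   [generate_dataset()]
#' @export
feature_table <- function(intensities, stages, sample_ids = NULL) {
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_format("intensities must be a numeric matrix")
  n <- nrow(intensities)
  if (length(stages) != n)
    stop_format("got %d stage labels for %d samples", length(stages), n)
  if (anyNA(intensities)) {
    bad <- which(is.na(intensities), arr.ind = TRUE)[1L, ]
    stop_format("intensity table must be complete; missing value at sample %s, feature %s",
                bad[["row"]], bad[["col"]])
  }
  if (any(intensities < 0))
    stop_format("intensities must be non-negative")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("F", seq_len(ncol(intensities)))
  if (anyDuplicated(colnames(intensities))) {
    dup <- colnames(intensities)[duplicated(colnames(intensities))][1L]
    stop_format("duplicate metabolite name: \"%s\"", dup)
  }
  sample_ids <- sample_ids %||% rownames(intensities) %||%
    paste0("S", seq_len(n))
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop_format("sample_ids must be unique, one per sample")
  rownames(intensities) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids),
                 stages = as.character(stages),
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d metabolites\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$stages)
  cat("  stages:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, stage = x$stages,
             as.data.frame(x$intensities, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}

#' Feature names of a table
#' @param table a [feature_table()].
#' @return character vector of metabolite names.
#' @export
feature_names <- function(table) colnames(table$intensities)

#' Write a feature table to CSV
#'
#' Layout: first column `sample_id`, second `stage`, remaining columns one per
#' metabolite. All fields are quoted because metabolite names routinely
#' contain commas, colons and parentheses.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' With `strict = TRUE` (default) the file must be a complete, fully numeric
#' table in the layout written by [write_feature_table()]; any empty or
#' non-numeric intensity cell is a format error naming the offending sample
#' and column. With `strict = FALSE` the raw data frame is returned with such
#' cells as `NA`, suitable for [apply_inclusion()].
#'
#' @param path CSV file path.
#' @param strict reject incomplete tables? (default `TRUE`)
#' @return a [feature_table()] (`strict = TRUE`) or a data frame.
#' @export
read_feature_table <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("NA", ""))
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("sample_id", "stage")))
    stop_format("expected columns sample_id, stage, <metabolites...> in %s", path)
  feats <- names(df)[-(1:2)]
  if (anyDuplicated(feats))
    stop_format("duplicate metabolite name: \"%s\"",
                feats[duplicated(feats)][1L])
  vals <- df[-(1:2)]
  num <- vapply(vals, function(v) suppressWarnings(as.numeric(v)),
                numeric(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  colnames(num) <- feats
  if (strict) {
    bad <- which(is.na(num) & !vapply(vals, is.na, logical(nrow(df))),
                 arr.ind = TRUE)
    if (length(bad))
      stop_format("non-numeric intensity for sample \"%s\", feature \"%s\"",
                  df$sample_id[bad[1L, 1L]], feats[bad[1L, 2L]])
    if (anyNA(num)) {
      miss <- which(is.na(num), arr.ind = TRUE)
      stop_format("missing intensity for sample \"%s\", feature \"%s\"",
                  df$sample_id[miss[1L, 1L]], feats[miss[1L, 2L]])
    }
    return(feature_table(num, df$stage, df$sample_id))
  }
  data.frame(sample_id = df$sample_id, stage = df$stage,
             as.data.frame(num, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}
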