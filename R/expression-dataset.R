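#' Labeled two-class expression dataset
#'
#' Container for a samples x features continuous expression matrix (RPPA-style
#' protein expression or similar) with a binary stage label per sample. The
#' positive class (conventionally "early" stage) is encoded `+1` and the
#' negative class ("advanced" stage) `-1`; every downstream operation relies on
#' this sign convention, e.g. the MCC's true positives count positive-class
#' hits.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param labels vector coercible to `+1`/`-1` (integer) or a character/factor
#'   vector together with `positive_label`.
#' @param feature_names unique feature names; defaults to `colnames(x)`.
#' @param sample_ids unique sample identifiers; defaults to `rownames(x)`.
#' @param positive_label the label value mapped to `+1` when `labels` is not
#'   already numeric.
#' @param load_report optional list describing how the dataset was loaded
#'   (rows dropped, class counts); attached as-is.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `labels` (integer `+1`/`-1`), `feature_names`, `sample_ids`,
#'   `positive_label`, `negative_label`, `load_report`.
#' @export
expression_dataset <- function(x, labels, feature_names = colnames(x),
                               sample_ids = rownames(x),
                               positive_label = "early",
                               load_report = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  feature_names <- as.character(feature_names)
  sample_ids <- as.character(sample_ids)

  negative_label <- NULL
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    lab <- as.integer(labels)
  } else {
    labels <- as.character(labels)
    if (!positive_label %in% labels) {
      stop("positive_label '", positive_label, "' not present in labels",
           call. = FALSE)
    }
    other <- setdiff(unique(labels), positive_label)
    if (length(other) != 1L) {
      stop("labels must contain exactly two classes; found: ",
           paste(sort(unique(labels)), collapse = ", "), call. = FALSE)
    }
    negative_label <- other
    lab <- ifelse(labels == positive_label, 1L, -1L)
  }
  if (is.null(negative_label)) negative_label <- "advanced"

  if (length(lab) != n) {
    stop("labels length (", length(lab), ") != number of samples (", n, ")",
         call. = FALSE)
  }
  if (length(feature_names) != p) {
    stop("feature_names length != number of features", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature_names must be unique", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  counts <- c(sum(lab == 1L), sum(lab == -1L))
  if (any(counts < 2L)) {
    stop("each class needs >= 2 samples; got ", counts[1], " positive / ",
         counts[2], " negative", call. = FALSE)
  }
  dimnames(x) <- list(sample_ids, feature_names)
  structure(
    list(matrix = x, labels = lab, feature_names = feature_names,
         sample_ids = sample_ids,
         positive_label = positive_label, negative_label = negative_label,
         load_report = load_report),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$matrix), "samples x", ncol(x$matrix),
      "features\n")
  cat("  classes: ", x$positive_label, " (+1): ", sum(x$labels == 1),
      ", ", x$negative_label, " (-1): ", sum(x$labels == -1), "\n", sep = "")
  if (!is.null(x$load_report)) {
    cat("  load report:", x$load_report$n_dropped, "row(s) dropped\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

# subset samples, keeping all features; used by CV fold splitting
subset_samples <- function(data, idx) {
  expression_dataset(
    data$matrix[idx, , drop = FALSE],
    data$labels[idx],
    feature_names = data$feature_names,
    sample_ids = data$sample_ids[idx],
    positive_label = data$positive_label
  )
}

#' Load a labeled expression table from delimited text
#'
#' Reads a CSV or TSV file (dialect sniffed from the extension; anything not
#' ending in `.tsv`/`.txt` is treated as comma-separated) with one header row,
#' a label column, and numeric expression columns. Rows containing missing
#' values in any expression column are dropped and counted in the load report.
#'
#' @param path path to the delimited file.
#' @param label_column name of the column holding class labels.
#' @param positive_label label value mapped to the positive class (`+1`).
#' @return An [expression_dataset()] whose `load_report` records the number of
#'   dropped rows and the per-class sample counts.
#' @export
load_expression_dataset <- function(path, label_column = "stage",
                                    positive_label = "early") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path,
         call. = FALSE)
  }
  labels <- as.character(df[[label_column]])
  expr_cols <- setdiff(names(df), label_column)
  id_col <- NULL
  if ("sample_id" %in% expr_cols) {
    id_col <- as.character(df[["sample_id"]])
    expr_cols <- setdiff(expr_cols, "sample_id")
  }
  expr <- df[expr_cols]
  for (j in seq_along(expr)) {
    col <- expr[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad) > 0) {
        stop("non-numeric expression value in column '", expr_cols[j],
             "', row ", bad[1], call. = FALSE)
      }
      num[!is.na(col) & col == ""] <- NA_real_
      expr[[j]] <- num
    }
  }
  m <- as.matrix(expr)
  keep <- stats::complete.cases(m) & !is.na(labels)
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- if (is.null(id_col)) paste0("S", which(keep)) else id_col[keep]
  report <- list(
    n_dropped = n_dropped,
    n_retained = nrow(m),
    class_counts = table(labels)
  )
  expression_dataset(m, labels, feature_names = expr_cols, sample_ids = ids,
                     positive_label = positive_label, load_report = report)
}

#' Write an expression dataset back to delimited text
#'
#' Inverse of [load_expression_dataset()]: writes `sample_id`, the label
#' column (original string labels) and one numeric column per feature.
#'
#' @param data an `ExpressionDataset`.
#' @param path output path; extension selects comma vs tab separation.
#' @param label_column name for the label column.
#' @export
write_expression_dataset <- function(data, path, label_column = "stage") {
  stopifnot(inherits(data, "ExpressionDataset"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lab <- ifelse(data$labels == 1L, data$positive_label, data$negative_label)
  df <- data.frame(sample_id = data$sample_ids, stage = lab,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2] <- label_column
  df <- cbind(df, as.data.frame(data$matrix, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
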