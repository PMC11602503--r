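#' Construct an omics view
#'
#' An omics view is one data modality (mRNA expression, DNA methylation,
#' miRNA expression, ...) measured on a common set of samples. It is stored
#' as a numeric samples x features matrix with sample IDs as row names and
#' feature IDs as column names. All views of a dataset must share the same
#' ordered sample set before model training.
#'
#' @param X numeric matrix, samples in rows, features in columns. Row and
#'   column names are required (sample IDs / feature IDs).
#' @param name short label for the view (e.g. `"mrna"`).
#' @return an object of class `OmicsView`: a list with elements `name`,
#'   `samples`, `features` and the matrix `X`.
#' @export
omics_view <- function(X, name = "view") {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("X must carry sample IDs as rownames and feature IDs as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(X)) || anyDuplicated(colnames(X)))
    stop("duplicated sample or feature IDs in view '", name, "'", call. = FALSE)
  structure(
    list(name = as.character(name)[1],
         samples = rownames(X),
         features = colnames(X),
         X = X),
    class = "OmicsView"
  )
}

#' @export
print.OmicsView <- function(x, ...) {
  cat(sprintf("OmicsView '%s': %d samples x %d features (%d missing entries)\n",
              x$name, nrow(x$X), ncol(x$X), sum(is.na(x$X))))
  invisible(x)
}

#' @export
dim.OmicsView <- function(x) dim(x$X)

#' Read an omics view from a delimited text file
#'
#' Expects a header row of feature IDs and a first column of sample IDs.
#' Tab- or comma-separated is inferred from the file extension (`.csv` =>
#' comma, anything else => tab). Empty fields and `NA` are read as missing.
#'
#' @param path file path.
#' @param name view label; defaults to the file name without extension.
#' @return an [omics_view()].
#' @export
read_omics_view <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("NA", ""),
                          comment.char = "", quote = "\"")
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  omics_view(X, name = name)
}

#' Write an omics view to a delimited text file
#'
#' Inverse of [read_omics_view()]: header row of feature IDs, first column
#' of sample IDs. Missing entries are written as empty fields.
#'
#' @param view an [omics_view()].
#' @param path output path; `.csv` extension selects comma separation.
#' @export
write_omics_view <- function(view, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = view$samples, view$X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write a sample label table
#'
#' Two-column delimited file: sample ID and integer cluster label.
#'
#' @param path file path.
#' @return named integer vector of labels.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  labs <- as.integer(df[[2]])
  names(labs) <- as.character(df[[1]])
  labs
}

#' @rdname read_labels
#' @param labels named integer vector (names are sample IDs).
#' @export
write_labels <- function(labels, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = names(labels), cluster = as.integer(labels))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
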