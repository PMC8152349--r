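#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric features-by-samples matrix with unique
#' feature and sample identifiers. Missing measurements are stored as `NA`.
#' All preprocessing steps ([filter_samples()], [filter_features()],
#' [knn_impute()], [log_transform()], [standardize()]) take and return this
#' class.
#'
#' @param values numeric matrix, `p` features in rows, `N` samples in columns.
#' @param feature_ids character vector of length `p`; defaults to existing
#'   rownames or `feature1..p`.
#' @param sample_ids character vector of length `N`; defaults to existing
#'   colnames or `sample1..N`.
#' @return a numeric matrix of class `omics_matrix` with dimnames set.
#' @export
omics_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(nrow(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  }
  if (length(feature_ids) != nrow(values)) stop("feature_ids length != nrow(values)")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length != ncol(values)")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("omics_matrix", class(matrix()))
  values
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

as_omics <- function(x) {
  if (inherits(x, "omics_matrix")) x else omics_matrix(as.matrix(x))
}

#' Read an omics matrix from a delimited text file
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Empty cells, `NA` and `NaN` are treated as missing.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) for TSV, `","` for CSV.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          na.strings = c("", "NA", "NaN"), check.names = FALSE,
                          comment.char = "")
  omics_matrix(as.matrix(df))
}

#' Write an omics matrix to a delimited text file
#'
#' @param x an [omics_matrix()] (or plain matrix).
#' @param path output file path.
#' @param sep field separator.
#' @export
write_omics_matrix <- function(x, path, sep = "\t") {
  x <- as_omics(x)
  df <- data.frame(feature_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
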