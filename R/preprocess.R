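#' Remove samples with too much missing data in any view
#'
#' A sample is dropped from every view if its fraction of missing features
#' strictly exceeds `max_missing_frac` in at least one view ("exceeds" is
#' strict: a sample missing exactly the threshold fraction is kept).
#'
#' @param matrices list of [omics_matrix()] sharing the same sample set, in
#'   the same order.
#' @param max_missing_frac maximum tolerated missing fraction per sample
#'   (default 0.2).
#' @return list of omics matrices with the offending samples removed from all
#'   views; sample order preserved.
#' @export
filter_samples <- function(matrices, max_missing_frac = 0.2) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  matrices <- lapply(matrices, as_omics)
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("`max_missing_frac` must be in [0, 1]")
  }
  ids <- colnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(colnames(m), ids)) {
      stop("all views must share the same sample_ids in the same order")
    }
  }
  drop <- Reduce(`|`, lapply(matrices, function(m) colMeans(is.na(m)) > max_missing_frac))
  if (all(drop)) stop("no samples left after sample filtering")
  lapply(matrices, function(m) omics_matrix(m[, !drop, drop = FALSE]))
}

#' Remove features with too much missing data
#'
#' Features whose missing fraction across samples strictly exceeds
#' `max_missing_frac` are removed; feature order is preserved.
#'
#' @param matrix an [omics_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction per feature
#'   (default 0.2).
#' @return the filtered omics matrix.
#' @export
filter_features <- function(matrix, max_missing_frac = 0.2) {
  matrix <- as_omics(matrix)
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("`max_missing_frac` must be in [0, 1]")
  }
  drop <- rowMeans(is.na(matrix)) > max_missing_frac
  if (all(drop)) stop("no features left after feature filtering")
  omics_matrix(matrix[!drop, , drop = FALSE])
}

#' K-nearest-neighbour imputation of missing values
#'
#' Each missing cell is replaced by the mean of that feature over the `k`
#' samples nearest to the sample with the gap. Distances between two samples
#' use only features observed in both, as the root mean squared difference
#' (so that pairs sharing few features are comparable to pairs sharing many);
#' neighbours missing the feature being imputed are skipped in favour of the
#' next nearest. Ties in distance are broken by sample index.
#'
#' @param matrix an [omics_matrix()].
#' @param k number of neighbours (default 20). If `k >= N` it is clamped to
#'   `N - 1` with a warning.
#' @return the completed omics matrix; observed cells are untouched.
#' @export
knn_impute <- function(matrix, k = 20) {
  x <- as_omics(matrix)
  if (k < 1) stop("`k` must be >= 1")
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples to impute")
  if (k >= n) {
    warning(sprintf("k = %d >= number of samples %d; clamping to %d", k, n, n - 1))
    k <- n - 1
  }
  miss <- is.na(x)
  if (!any(miss)) return(x)
  obs_per_sample <- colSums(!miss)
  if (any(obs_per_sample == 0)) {
    stop(sprintf("sample(s) with no observed features: %s",
                 paste(colnames(x)[obs_per_sample == 0], collapse = ", ")))
  }
  # pairwise mean squared difference over mutually observed features
  d2 <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !miss[, i] & !miss[, j]
      if (any(shared)) {
        d2[i, j] <- d2[j, i] <- mean((x[shared, i] - x[shared, j])^2)
      }
    }
  }
  out <- unclass(x)
  for (s in which(colSums(miss) > 0)) {
    ds <- d2[, s]
    ds[s] <- NA
    if (all(is.na(ds))) {
      stop(sprintf("sample '%s' shares no observed features with any other sample",
                   colnames(x)[s]))
    }
    nbr <- order(ds, seq_len(n), na.last = NA) # drops non-comparable samples
    for (f in which(miss[, s])) {
      donors <- nbr[!miss[f, nbr]]
      if (length(donors) == 0) {
        stop(sprintf("feature '%s' unobserved in all neighbours of sample '%s'",
                     rownames(x)[f], colnames(x)[s]))
      }
      out[f, s] <- mean(x[f, donors[seq_len(min(k, length(donors)))]])
    }
  }
  omics_matrix(out)
}

#' Elementwise log transform
#'
#' Applies `log(value + offset)` to stabilise heavy-tailed omics intensities.
#'
#' @param matrix an [omics_matrix()].
#' @param offset added before taking logs (default 1 so that zeros map to 0).
#' @return the transformed omics matrix (missing cells stay missing).
#' @export
log_transform <- function(matrix, offset = 1) {
  x <- as_omics(matrix)
  bad <- which(x + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("log transform undefined (value + offset <= 0) for feature '%s', sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  out <- log(unclass(x) + offset)
  omics_matrix(out)
}

#' Standardize each feature to mean 0, variance 1
#'
#' Each feature row is centred and scaled to unit variance across samples.
#' Constant features carry no information for sample similarity and are
#' dropped with a warning instead of producing NaN.
#'
#' @param matrix a complete (no missing values) [omics_matrix()].
#' @param unbiased if `FALSE` (default) the variance uses the population
#'   denominator `N`; if `TRUE`, `N - 1`.
#' @return the standardized omics matrix.
#' @export
standardize <- function(matrix, unbiased = FALSE) {
  x <- as_omics(matrix)
  if (anyNA(x)) stop("standardize() requires a complete matrix; impute first")
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples to standardize")
  mu <- rowMeans(x)
  centred <- unclass(x) - mu
  v <- rowSums(centred^2) / (if (unbiased) n - 1 else n)
  keep <- v > 0
  if (!any(keep)) stop("all features have zero variance")
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s", sum(!keep),
                    paste(utils::head(rownames(x)[!keep], 5), collapse = ", ")))
  }
  omics_matrix(centred[keep, , drop = FALSE] / sqrt(v[keep]))
}

#' Full preprocessing chain for multi-omics matrices
#'
#' Runs, in order: sample filtering across views, per-view feature filtering,
#' KNN imputation, log transform (optional) and feature standardization.
#'
#' @param matrices list of [omics_matrix()] sharing a sample set.
#' @param max_missing_frac missing-fraction threshold for samples and
#'   features (default 0.2).
#' @param impute_k neighbours for imputation (default 20).
#' @param log apply the log transform (default `TRUE`).
#' @param offset log offset (default 1).
#' @param unbiased variance denominator flag, see [standardize()].
#' @return list of complete standardized omics matrices.
#' @export
preprocess_views <- function(matrices, max_missing_frac = 0.2, impute_k = 20,
                             log = TRUE, offset = 1, unbiased = FALSE) {
  matrices <- filter_samples(matrices, max_missing_frac)
  matrices <- lapply(matrices, filter_features, max_missing_frac = max_missing_frac)
  matrices <- lapply(matrices, knn_impute, k = impute_k)
  if (log) matrices <- lapply(matrices, log_transform, offset = offset)
  lapply(matrices, standardize, unbiased = unbiased)
}
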