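#' Per-view cluster labels
#'
#' Container for the `M` per-view k-means labellings of a multi-view
#' embedding. Labels are integers in `1..K`. `aligned` records whether
#' cross-view label correspondence has been resolved ([align_labels()]).
#'
#' @param labels list of `M` integer vectors of equal length with values in
#'   `1..K`.
#' @param K number of clusters.
#' @param aligned logical.
#' @return object of class `view_labels`.
#' @export
view_labels <- function(labels, K, aligned = FALSE) {
  stopifnot(is.list(labels), length(labels) >= 1)
  n <- length(labels[[1]])
  labels <- lapply(labels, function(l) {
    l <- as.integer(l)
    if (length(l) != n) stop("all label vectors must have the same length")
    if (any(l < 1 | l > K)) stop("labels must lie in 1..K")
    l
  })
  structure(list(labels = labels, K = as.integer(K), M = length(labels),
                 n = n, aligned = isTRUE(aligned)),
            class = "view_labels")
}

#' @export
print.view_labels <- function(x, ...) {
  cat(sprintf("view_labels: M = %d views, N = %d samples, K = %d, aligned: %s\n",
              x$M, x$n, x$K, x$aligned))
  invisible(x)
}

row_normalize <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  x / pmax(nrm, .Machine$double.eps)
}

# evaluate expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' K-means clustering of each view's embedding block
#'
#' Runs k-means (k-means++-like behaviour via many random restarts) on each
#' `U_m`. Rows are normalized to unit length first (standard practice for
#' spectral embeddings, where cluster information lives in direction rather
#' than magnitude); disable with `row_norm = FALSE`.
#'
#' @param U a [stacked_embedding()].
#' @param K number of clusters, `2 <= K <= N`.
#' @param seed integer seed; view `m` uses `seed + m` so runs are
#'   reproducible and views independent.
#' @param row_norm normalize rows before clustering (default `TRUE`).
#' @param nstart random restarts per view (default 50).
#' @return a [view_labels()] (not yet aligned).
#' @export
kmeans_per_view <- function(U, K, seed = 1L, row_norm = TRUE, nstart = 50) {
  stopifnot(inherits(U, "stacked_embedding"))
  if (K < 2) stop("`K` must be >= 2")
  if (K > U$n) stop("`K` cannot exceed the number of samples")
  labels <- lapply(seq_len(U$M), function(m) {
    x <- emb_block(U, m)
    if (row_norm) x <- row_normalize(x)
    with_seed(seed + m,
              stats::kmeans(x, centers = K, nstart = nstart, iter.max = 100)$cluster)
  })
  view_labels(labels, K = K, aligned = U$M == 1)
}

#' Calinski-Harabasz score of a labelling
#'
#' Ratio of between- to within-cluster dispersion,
#' `(SSB / (k - 1)) / (SSW / (n - k))`; larger is better.
#'
#' @param x numeric matrix of observations in rows.
#' @param labels integer cluster labels.
#' @return the score (Inf when `SSW = 0`).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  cl <- unique(labels)
  k <- length(cl)
  if (k < 2 || k >= n) stop("need 2 <= number of clusters < n")
  centre <- colMeans(x)
  ssw <- 0
  ssb <- 0
  for (c in cl) {
    xc <- x[labels == c, , drop = FALSE]
    mu <- colMeans(xc)
    ssw <- ssw + sum(sweep(xc, 2, mu)^2)
    ssb <- ssb + nrow(xc) * sum((mu - centre)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz score
#'
#' Scans `K = k_min..k_max`, clustering the row-concatenated embedding
#' `[U_1 | ... | U_M]` with k-means at each candidate, and returns the `K`
#' with the highest score (ties broken towards the smallest `K`).
#'
#' @param U a [stacked_embedding()].
#' @param k_min,k_max scan range (defaults 2 and 10), `k_max < N`.
#' @param seed integer seed for the k-means restarts.
#' @param row_norm normalize block rows before concatenation.
#' @return list of class `k_selection` with `K` (the chosen count) and
#'   `ch_scores` (named vector over the scanned range).
#' @export
select_k <- function(U, k_min = 2, k_max = 10, seed = 1L, row_norm = TRUE) {
  stopifnot(inherits(U, "stacked_embedding"))
  if (k_min < 2 || k_min > k_max) stop("need 2 <= k_min <= k_max")
  if (k_max >= U$n) stop("`k_max` must be < N")
  X <- do.call(cbind, lapply(seq_len(U$M), function(m) {
    b <- emb_block(U, m)
    if (row_norm) row_normalize(b) else b
  }))
  if (nrow(unique(X)) < 2) stop("degenerate embedding: all samples identical")
  ks <- k_min:k_max
  scores <- vapply(ks, function(k) {
    lab <- with_seed(seed + 1000 * k,
                     stats::kmeans(X, centers = k, nstart = 50, iter.max = 100)$cluster)
    calinski_harabasz(X, lab)
  }, numeric(1))
  names(scores) <- ks
  structure(list(K = ks[which.max(scores)], ch_scores = scores),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: K = %d (CH scores over %s..%s)\n", x$K,
              names(x$ch_scores)[1], names(x$ch_scores)[length(x$ch_scores)]))
  invisible(x)
}

# Minimum-cost assignment (Hungarian / shortest augmenting path, O(n^3)).
# Returns an integer vector `rows`: rows[j] is the row assigned to column j.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials, index 1 = virtual column
  p <- integer(n + 1)    # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  p[-1]
}

#' Align cluster labels across views
#'
#' K-means labels are arbitrary per view; any cross-view vote needs a
#' correspondence. Views `2..M` are relabelled by maximum-overlap matching
#' (Hungarian assignment on the contingency table) against view 1.
#'
#' @param vl a [view_labels()].
#' @return the aligned [view_labels()] (`aligned = TRUE`).
#' @export
align_labels <- function(vl) {
  stopifnot(inherits(vl, "view_labels"))
  if (vl$M == 1 || vl$aligned) {
    vl$aligned <- TRUE
    return(vl)
  }
  K <- vl$K
  ref <- factor(vl$labels[[1]], levels = seq_len(K))
  labels <- vl$labels
  for (m in 2:vl$M) {
    tab <- table(ref, factor(labels[[m]], levels = seq_len(K)))
    newlab <- solve_assignment(max(tab) - unclass(tab))
    labels[[m]] <- newlab[labels[[m]]]
  }
  view_labels(labels, K = K, aligned = TRUE)
}

#' Integrate per-view labels by a k-nearest-neighbour majority vote
#'
#' Integration adjudicates cross-view disagreement: a sample on which all
#' views already agree keeps that label (so unanimous labellings pass
#' through unchanged whatever the neighbourhood size). For a disputed
#' sample, the final label is the majority over the `M * (k + 1)` aligned
#' labels of itself and its `k_integrate` nearest neighbours in the
#' row-concatenated embedding `[U_1 | ... | U_M]`. Ties are broken by the
#' sample's own majority view label, then by the smallest label index.
#' Neighbour ties in distance are broken by sample index.
#'
#' @param U a [stacked_embedding()].
#' @param vl an aligned [view_labels()].
#' @param k_integrate number of neighbours; default `max(10, round(N/10))`
#'   as for the similarity graphs. Values `>= N` are clamped to `N - 1`
#'   with a warning.
#' @param row_norm normalize block rows before concatenation.
#' @return object of class `integrated_clustering`: list with
#'   `final_labels`, `per_view` (the aligned [view_labels()]), `K` and
#'   `k_integrate`.
#' @export
integrate_knn <- function(U, vl, k_integrate = NULL, row_norm = TRUE) {
  stopifnot(inherits(U, "stacked_embedding"), inherits(vl, "view_labels"))
  if (U$n != vl$n || U$M != vl$M) stop("embedding and labels disagree on M or N")
  if (!vl$aligned) stop("labels must be aligned first; call align_labels()")
  n <- U$n
  if (is.null(k_integrate)) k_integrate <- default_knn(n)
  if (k_integrate < 1) stop("`k_integrate` must be >= 1")
  if (k_integrate >= n) {
    warning(sprintf("k_integrate = %d >= N; clamping to %d", k_integrate, n - 1))
    k_integrate <- n - 1
  }
  X <- do.call(cbind, lapply(seq_len(U$M), function(m) {
    b <- emb_block(U, m)
    if (row_norm) row_normalize(b) else b
  }))
  D <- as.matrix(stats::dist(X))
  lab_mat <- do.call(cbind, vl$labels)   # n x M
  K <- vl$K
  unanimous <- apply(lab_mat, 1, function(l) length(unique(l)) == 1)
  final <- integer(n)
  for (i in seq_len(n)) {
    if (unanimous[i]) {
      final[i] <- lab_mat[i, 1]
      next
    }
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    voters <- c(i, ord[seq_len(k_integrate)])
    counts <- tabulate(as.vector(lab_mat[voters, ]), nbins = K)
    winners <- which(counts == max(counts))
    if (length(winners) > 1) {
      own <- tabulate(lab_mat[i, ], nbins = K)[winners]
      winners <- winners[own == max(own)]
    }
    final[i] <- min(winners)
  }
  structure(list(final_labels = final, per_view = vl, K = K,
                 k_integrate = as.integer(k_integrate)),
            class = "integrated_clustering")
}

#' @export
print.integrated_clustering <- function(x, ...) {
  cat(sprintf("integrated_clustering: N = %d samples, K = %d, cluster sizes: %s\n",
              length(x$final_labels), x$K,
              paste(tabulate(x$final_labels, x$K), collapse = ", ")))
  invisible(x)
}
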