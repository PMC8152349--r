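# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Rand index by explicit enumeration of all unordered pairs.
ri_brute <- function(a, b) {
  n <- length(a)
  agree <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
    }
  }
  agree / total
}

# NMI from the joint distribution with explicit loops (natural log).
nmi_ref <- function(a, b) {
  n <- length(a)
  ua <- unique(a)
  ub <- unique(b)
  pa <- vapply(ua, function(x) sum(a == x) / n, 0)
  pb <- vapply(ub, function(x) sum(b == x) / n, 0)
  mi <- 0
  for (i in seq_along(ua)) {
    for (j in seq_along(ub)) {
      pij <- sum(a == ua[i] & b == ub[j]) / n
      if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
    }
  }
  h <- function(p) -sum(p * log(p))
  denom <- h(pa) + h(pb)
  if (denom == 0) 1 else 2 * mi / denom
}

# Minimum assignment cost by exhaustive permutation enumeration.
assignment_brute <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    best <- min(best, sum(cost[cbind(p, seq_len(n))]))
  }
  best
}

# Blockwise Stiefel tangent projection written out independently.
tangent_project_stacked_oracle <- function(U, Zmat) {
  out <- Zmat
  for (m in seq_len(U$M)) {
    idx <- ((m - 1) * U$n + 1):(m * U$n)
    Um <- U$mat[idx, , drop = FALSE]
    Zm <- Zmat[idx, , drop = FALSE]
    B <- t(Um) %*% Zm
    out[idx, ] <- Zm - Um %*% ((B + t(B)) / 2)
  }
  out
}

# Random orthonormal N x K matrix.
rand_stiefel <- function(n, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

# Small connected 3-block SBM adjacency (dense regime) for optimizer tests.
toy_sbm <- function(sizes = c(10, 10, 10), p_in = 0.55, p_out = 0.05, seed = 1) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (labels[i] == labels[j]) p_in else p_out
      A[i, j] <- A[j, i] <- as.numeric(runif(1) < p)
    }
  }
  list(A = A, labels = labels)
}

# Complete omics fixture: three separated sample groups over p features.
toy_omics <- function(p = 12, sizes = c(7, 7, 6), shift = 6, seed = 1, noise = 1) {
  set.seed(seed)
  n <- sum(sizes)
  groups <- rep(seq_along(sizes), sizes)
  centres <- matrix(rnorm(p * length(sizes), sd = shift), p, length(sizes))
  vals <- centres[, groups] + matrix(rnorm(p * n, sd = noise), p, n)
  list(x = omics_matrix(vals), groups = groups)
}
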