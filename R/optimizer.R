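#' Optimizer parameters
#'
#' Settings for the projected-gradient / backtracking scheme of
#' [mcsm_optimize()].
#'
#' The sufficient-decrease test accepts a step `alpha` when
#' `f(retract(U + alpha * eta)) <= f(U) - alpha * c_eff * <eta, Z>`, with
#' `c_eff = min(c, c_max)`. A coefficient of 1 or more demands more decrease
#' than the first-order model predicts and can never be met as `alpha -> 0`,
#' so the conventional control value `c = 6` is clamped to the classical
#' Armijo constant `c_max = 1e-4`; the slope `<eta, Z>` is the trace inner
#' product of the search direction with the negative gradient.
#'
#' @param alpha0 initial step size (default 0.01). Later iterations
#'   warm-start the line search from the previously accepted step times
#'   `growth`, so `alpha0` only sets the scale of the very first step.
#' @param growth factor by which the accepted step seeds the next
#'   iteration's line search (default 2; set to 1 to restart every search
#'   at `alpha0`).
#' @param c line-search control parameter (default 6); effectively clamped to
#'   `c_max`, see Details.
#' @param c_max upper bound for the effective Armijo coefficient (default
#'   1e-4).
#' @param tau step-shrink factor in (0, 1) (default 0.1).
#' @param max_iter maximum outer iterations (default 20).
#' @param tol relative objective-change tolerance for early stopping
#'   (default 1e-6).
#' @param max_backtracks maximum step shrinkages per iteration (default 30).
#' @param seed integer seed for any randomized fallback initialization.
#' @return a list of class `opt_params`.
#' @export
opt_params <- function(alpha0 = 0.01, c = 6, c_max = 1e-4, tau = 0.1,
                       max_iter = 20, tol = 1e-6, max_backtracks = 30,
                       growth = 2, seed = 1L) {
  if (alpha0 <= 0) stop("`alpha0` must be positive")
  if (tau <= 0 || tau >= 1) stop("`tau` must be in (0, 1)")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (c <= 0 || c_max <= 0) stop("`c` and `c_max` must be positive")
  if (growth < 1) stop("`growth` must be >= 1")
  structure(list(alpha0 = alpha0, c = c, c_max = c_max, tau = tau,
                 max_iter = as.integer(max_iter), tol = tol,
                 max_backtracks = as.integer(max_backtracks),
                 growth = growth, seed = as.integer(seed)),
            class = "opt_params")
}

#' Stacked multi-view embedding
#'
#' The optimization variable: `M` blocks `U_m`, each an `N x K` matrix with
#' orthonormal columns, stacked vertically into an `MN x K` matrix in view
#' order.
#'
#' @param x MN x K numeric matrix, or a list of M conforming N x K blocks.
#' @param M number of views (not needed when `x` is a list of blocks).
#' @return object of class `stacked_embedding` with elements `mat` (MN x K),
#'   `M`, `n`, `K`.
#' @export
stacked_embedding <- function(x, M = NULL) {
  if (is.list(x)) {
    M <- length(x)
    dims <- vapply(x, dim, integer(2))
    if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
      stop("all blocks must share the same dimensions")
    }
    x <- do.call(rbind, x)
  }
  if (is.null(M)) stop("`M` required when `x` is a single stacked matrix")
  x <- as.matrix(x)
  if (nrow(x) %% M != 0) stop("nrow(x) must be a multiple of M")
  structure(list(mat = x, M = as.integer(M), n = nrow(x) %/% M, K = ncol(x)),
            class = "stacked_embedding")
}

#' Extract one view's block from a stacked embedding
#'
#' @param U a [stacked_embedding()].
#' @param m view index in `1..M`.
#' @return the N x K matrix `U_m`.
#' @export
emb_block <- function(U, m) {
  stopifnot(inherits(U, "stacked_embedding"), m >= 1, m <= U$M)
  U$mat[((m - 1) * U$n + 1):(m * U$n), , drop = FALSE]
}

#' @export
print.stacked_embedding <- function(x, ...) {
  cat(sprintf("stacked_embedding: M = %d blocks of %d x %d\n", x$M, x$n, x$K))
  invisible(x)
}

as_stacked_mat <- function(U, L = NULL) {
  if (inherits(U, "stacked_embedding")) U$mat
  else if (is.matrix(U)) U
  else stop("`U` must be a stacked_embedding or matrix")
}

joint_L_matrix <- function(L) {
  if (inherits(L, "joint_laplacian")) L$L else L
}

#' Joint spectral objective trace(U' L U)
#'
#' Equals `sum_m trace(U_m' L_m U_m) - beta * sum_{l != m} trace(U_m' U_l)`
#' for the block Laplacian of [joint_laplacian()].
#'
#' @param U a [stacked_embedding()] (or MN x K matrix).
#' @param L a [joint_laplacian()] (or MN x MN symmetric matrix).
#' @return scalar objective value.
#' @export
mcsm_objective <- function(U, L) {
  Um <- as_stacked_mat(U)
  Lm <- joint_L_matrix(L)
  if (nrow(Um) != nrow(Lm)) stop("dimension mismatch between U and L")
  sum(Um * as.matrix(Lm %*% Um))
}

#' Negative Euclidean gradient of the joint objective
#'
#' For symmetric `L`, the gradient of `trace(U' L U)` is `2 L U`; the search
#' uses its negative `Z = -2 L U`, split into per-view blocks.
#'
#' @inheritParams mcsm_objective
#' @return MN x K matrix `Z`.
#' @export
negative_gradient <- function(U, L) {
  Um <- as_stacked_mat(U)
  Lm <- joint_L_matrix(L)
  if (nrow(Um) != nrow(Lm)) stop("dimension mismatch between U and L")
  -2 * as.matrix(Lm %*% Um)
}

#' Project a direction onto the Stiefel tangent space
#'
#' Returns `eta = Z - U sym(U' Z)` with `sym(A) = (A + A')/2`, the orthogonal
#' projection of `Z` onto the tangent space at `U` of the Stiefel manifold
#' `{U : U'U = I_K}`, i.e. `U' eta` is skew-symmetric.
#'
#' @param U_m N x K matrix with orthonormal columns.
#' @param Z_m N x K direction to project.
#' @return the tangent direction `eta_m`.
#' @export
tangent_project <- function(U_m, Z_m) {
  if (max(abs(crossprod(U_m) - diag(ncol(U_m)))) > 1e-6) {
    stop("`U_m` must have orthonormal columns")
  }
  A <- crossprod(U_m, Z_m)
  Z_m - U_m %*% ((A + t(A)) / 2)
}

tangent_project_stacked <- function(Umat, Zmat, M) {
  n <- nrow(Umat) %/% M
  eta <- Zmat
  for (m in seq_len(M)) {
    idx <- ((m - 1) * n + 1):(m * n)
    A <- crossprod(Umat[idx, , drop = FALSE], Zmat[idx, , drop = FALSE])
    eta[idx, ] <- Zmat[idx, , drop = FALSE] -
      Umat[idx, , drop = FALSE] %*% ((A + t(A)) / 2)
  }
  eta
}

#' SVD (polar) retraction onto the Stiefel manifold
#'
#' For `Y = W Sigma V'` (thin SVD) returns `W V'`, the orthonormal matrix
#' closest to `Y` in Frobenius norm.
#'
#' @param Y N x K matrix of full column rank.
#' @return N x K matrix with orthonormal columns.
#' @export
svd_retract <- function(Y) {
  s <- svd(Y)
  if (min(s$d) <= max(s$d) * 1e-12) stop("`Y` is (numerically) rank deficient")
  s$u %*% t(s$v)
}

retract_stacked <- function(Ymat, M) {
  n <- nrow(Ymat) %/% M
  for (m in seq_len(M)) {
    idx <- ((m - 1) * n + 1):(m * n)
    Ymat[idx, ] <- svd_retract(Ymat[idx, , drop = FALSE])
  }
  Ymat
}

#' One backtracking line-search step
#'
#' Tries `alpha in {alpha0, tau*alpha0, ...}` and accepts the first step for
#' which the blockwise-retracted candidate satisfies the sufficient-decrease
#' condition (see [opt_params()]). The Armijo test is evaluated at the
#' retracted point, since `U + alpha*eta` leaves the manifold. If the
#' direction is not a descent direction or all backtracks fail, `U` is
#' returned unchanged with `alpha = 0`.
#'
#' @param U a [stacked_embedding()].
#' @param eta MN x K tangent direction.
#' @param Z MN x K negative gradient.
#' @param L a [joint_laplacian()].
#' @param params an [opt_params()].
#' @param alpha_start first step size to try (default `params$alpha0`);
#'   [mcsm_optimize()] passes the previously accepted step times
#'   `params$growth`.
#' @return list with `alpha`, `U_next` ([stacked_embedding()]), `f_next` and
#'   logical `accepted`.
#' @export
backtracking_step <- function(U, eta, Z, L, params = opt_params(),
                              alpha_start = params$alpha0) {
  Umat <- as_stacked_mat(U)
  M <- U$M
  f0 <- mcsm_objective(Umat, L)
  if (!is.finite(f0)) stop("objective is not finite at the current point")
  slope <- sum(eta * Z)
  c_eff <- min(params$c, params$c_max)
  thr <- 1e-13 * max(1, abs(f0))
  if (slope < -thr) {   # ascent direction: refuse to move
    return(list(alpha = 0, U_next = U, f_next = f0, accepted = FALSE))
  }
  if (slope <= thr) {   # stationary to numerical precision: accept in place
    return(list(alpha = alpha_start, U_next = U, f_next = f0, accepted = TRUE))
  }
  alpha <- alpha_start
  for (bt in 0:params$max_backtracks) {
    cand <- retract_stacked(Umat + alpha * eta, M)
    f_cand <- mcsm_objective(cand, L)
    if (!is.finite(f_cand)) stop("objective is not finite at a candidate point")
    if (f_cand <= f0 - alpha * c_eff * slope) {
      return(list(alpha = alpha, U_next = stacked_embedding(cand, M = M),
                  f_next = f_cand, accepted = TRUE, backtracks = bt))
    }
    alpha <- params$tau * alpha
  }
  list(alpha = 0, U_next = U, f_next = f0, accepted = FALSE)
}

# K eigenvectors of smallest eigenvalue of a symmetric matrix, with a
# deterministic sign convention (largest-magnitude entry of each column made
# positive; first occurrence on ties).
bottom_eigvecs <- function(L, K) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (K > n) stop("K cannot exceed the matrix dimension")
  e <- eigen(L, symmetric = TRUE)   # eigenvalues in decreasing order
  V <- e$vectors[, n - seq_len(K) + 1, drop = FALSE]
  for (j in seq_len(K)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Minimize trace(U' L U) over a product of Stiefel manifolds
#'
#' Projected gradient descent with Armijo backtracking and SVD retraction.
#' Each iteration computes the negative gradient `Z = -2 L U`, projects it
#' blockwise onto the tangent spaces, finds a step by backtracking line
#' search and retracts every block back to the manifold. The loop stops
#' after `max_iter` iterations, when the relative objective change drops
#' below `tol`, or when no descent step can be found.
#'
#' Initialization (`init = "pooled"`, the default) takes the `K`
#' bottom-eigenvalue eigenvectors of the pooled Laplacian `sum_m L_m` and
#' replicates them across views; for a single view this is exactly the
#' spectral-relaxation optimum. `init = "random"` draws a seeded random
#' orthonormal block per view; a matrix or block list may also be supplied
#' via `U0`.
#'
#' @param L a [joint_laplacian()].
#' @param K embedding dimension (number of clusters sought).
#' @param params an [opt_params()].
#' @param init `"pooled"` or `"random"` (ignored when `U0` given).
#' @param U0 optional explicit start: a [stacked_embedding()], an MN x K
#'   matrix, or a list of M blocks.
#' @return list with `U` (the final [stacked_embedding()]) and `trace`, a
#'   list of class `opt_trace` carrying `objective` (value per accepted
#'   iterate, starting at the initial point), `step_sizes`, `converged` and
#'   `n_iter`.
#' @export
mcsm_optimize <- function(L, K, params = opt_params(),
                          init = c("pooled", "random"), U0 = NULL) {
  stopifnot(inherits(L, "joint_laplacian"), K >= 1)
  init <- match.arg(init)
  M <- L$M
  n <- L$n
  if (K > n) stop("K cannot exceed the number of nodes")
  if (is.null(U0)) {
    if (init == "pooled") {
      U0mat <- bottom_eigvecs(Reduce(`+`, L$blocks), K)
      Umat <- do.call(rbind, rep(list(U0mat), M))
    } else {
      rng <- get0(".Random.seed", envir = globalenv())
      set.seed(params$seed)
      Umat <- retract_stacked(matrix(stats::rnorm(M * n * K), M * n, K), M)
      if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
    }
  } else {
    Umat <- if (inherits(U0, "stacked_embedding")) U0$mat
            else if (is.list(U0)) do.call(rbind, U0)
            else as.matrix(U0)
    if (nrow(Umat) != M * n || ncol(Umat) != K) stop("`U0` has wrong dimensions")
    Umat <- retract_stacked(Umat, M)
  }
  U <- stacked_embedding(Umat, M = M)
  f <- mcsm_objective(U, L)
  objective <- f
  step_sizes <- numeric(0)
  converged <- FALSE
  alpha_next <- params$alpha0
  for (it in seq_len(params$max_iter)) {
    Z <- negative_gradient(U, L)
    eta <- tangent_project_stacked(U$mat, Z, M)
    step <- backtracking_step(U, eta, Z, L, params, alpha_start = alpha_next)
    if (!step$accepted) {
      converged <- TRUE   # no admissible descent step: stationary to tolerance
      break
    }
    rel_change <- abs(f - step$f_next) / max(abs(f), .Machine$double.eps)
    alpha_next <- step$alpha * params$growth
    U <- step$U_next
    f <- step$f_next
    objective <- c(objective, f)
    step_sizes <- c(step_sizes, step$alpha)
    if (rel_change < params$tol) {
      converged <- TRUE
      break
    }
  }
  trace <- structure(list(objective = objective, step_sizes = step_sizes,
                          converged = converged,
                          n_iter = length(objective) - 1L),
                     class = "opt_trace")
  list(U = U, trace = trace)
}

#' @export
print.opt_trace <- function(x, ...) {
  cat(sprintf("opt_trace: %d iterations, objective %.6g -> %.6g, converged: %s\n",
              x$n_iter, x$objective[1], x$objective[length(x$objective)],
              x$converged))
  invisible(x)
}

#' Principal angles between two column spans
#'
#' @param A,B matrices with the same number of rows; angles are computed
#'   between their (orthonormalized) column spans.
#' @return vector of principal angles in radians, non-decreasing.
#' @export
principal_angles <- function(A, B) {
  Qa <- qr.Q(qr(A))
  Qb <- qr.Q(qr(B))
  s <- svd(crossprod(Qa, Qb))$d
  acos(pmin(pmax(s, -1), 1))
}
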