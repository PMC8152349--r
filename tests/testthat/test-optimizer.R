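toy_joint <- function(M = 2, seed = 1, n = 12, beta = 1) {
  graphs <- lapply(seq_len(M), function(m) {
    view_graph(toy_sbm(sizes = rep(n / 3, 3), p_in = 0.7, p_out = 0.1,
                       seed = seed + m)$A)
  })
  joint_laplacian(graphs, beta = beta)
}

test_that("objective equals the elementwise trace formula", {
  L <- toy_joint(M = 2, seed = 10)
  U <- stacked_embedding(list(rand_stiefel(12, 2, 1), rand_stiefel(12, 2, 2)))
  # elementwise oracle: trace(U'LU) = sum_ij L_ij (U U')_ij
  Lm <- as.matrix(L$L)
  Um <- U$mat
  expect_equal(mcsm_objective(U, L), sum(Lm * tcrossprod(Um)), tolerance = 1e-10)

  # zero operator -> 0 for any U
  z <- view_graph(matrix(0, 12, 12))
  L0 <- joint_laplacian(list(z, z), beta = 0)
  expect_equal(mcsm_objective(U, L0), 0)

  # constant vector lies in the kernel of a connected Laplacian (K3)
  LK3 <- joint_laplacian(list(view_graph(matrix(1, 3, 3) - diag(3))))
  U1 <- stacked_embedding(matrix(1 / sqrt(3), 3, 1), M = 1)
  expect_equal(mcsm_objective(U1, LK3), 0, tolerance = 1e-12)

  expect_error(mcsm_objective(stacked_embedding(rand_stiefel(6, 2, 3), M = 1), L),
               "mismatch")
})

test_that("negative gradient matches finite differences and the coupling structure", {
  # finite-difference directional derivative along a tangent direction
  for (seed in 1:4) {
    L <- toy_joint(M = 2, seed = seed, beta = 0.7)
    U <- stacked_embedding(list(rand_stiefel(12, 2, seed + 50),
                                rand_stiefel(12, 2, seed + 90)))
    Z <- negative_gradient(U, L)
    set.seed(seed)
    H <- tangent_project_stacked_oracle(U, matrix(rnorm(24 * 2), 24, 2))
    eps <- 1e-6
    fd <- (mcsm_objective(U$mat + eps * H, L) -
           mcsm_objective(U$mat - eps * H, L)) / (2 * eps)
    expect_equal(fd, -sum(Z * H), tolerance = 1e-5)
  }

  # pure coupling (L_m = 0, beta = 1): Z_1 = 2 U_2, Z_2 = 2 U_1
  z <- view_graph(matrix(0, 8, 8))
  Lc <- joint_laplacian(list(z, z), beta = 1)
  U <- stacked_embedding(list(rand_stiefel(8, 2, 7), rand_stiefel(8, 2, 8)))
  Z <- negative_gradient(U, Lc)
  expect_equal(Z[1:8, ], 2 * emb_block(U, 2), tolerance = 1e-12)
  expect_equal(Z[9:16, ], 2 * emb_block(U, 1), tolerance = 1e-12)

  # zero operator -> zero gradient
  L0 <- joint_laplacian(list(z, z), beta = 0)
  expect_equal(negative_gradient(U, L0), matrix(0, 16, 2))
})

test_that("tangent projection lands in the tangent space and fixes tangent vectors", {
  U <- rand_stiefel(6, 2, 21)
  # normal direction is annihilated
  expect_equal(tangent_project(U, U), matrix(0, 6, 2), tolerance = 1e-12)

  # projection output satisfies the tangency condition (U'eta skew)
  set.seed(22)
  Z <- matrix(rnorm(12), 6, 2)
  eta <- tangent_project(U, Z)
  S <- crossprod(U, eta)
  expect_lt(max(abs(S + t(S))), 1e-10)

  # idempotence: an already-tangent direction is unchanged
  expect_equal(tangent_project(U, eta), eta, tolerance = 1e-10)

  expect_error(tangent_project(matrix(1, 6, 2), Z), "orthonormal")
})

test_that("SVD retraction returns the nearest orthonormal matrix", {
  U <- rand_stiefel(5, 2, 31)
  expect_equal(svd_retract(U), U, tolerance = 1e-10)
  expect_equal(svd_retract(2 * diag(2)), diag(2))

  # polar-factor optimality: no orthonormal Q (random or near the answer)
  # is closer to Y in Frobenius norm
  set.seed(32)
  Y <- matrix(rnorm(10), 5, 2)
  R <- svd_retract(Y)
  dR <- norm(R - Y, "F")
  for (i in 1:100) {
    Q <- rand_stiefel(5, 2, 1000 + i)
    expect_gte(norm(Q - Y, "F"), dR - 1e-12)
  }
  for (i in 1:50) {   # local perturbations of the answer, retracted back
    Q <- svd_retract(R + 0.05 * matrix(rnorm(10), 5, 2))
    expect_gte(norm(Q - Y, "F"), dR - 1e-10)
  }
  expect_error(svd_retract(cbind(c(1, 0, 0), c(2, 0, 0))), "rank")
})

test_that("backtracking accepts descent steps and guards against ascent", {
  L <- toy_joint(M = 2, seed = 40)
  U <- stacked_embedding(list(rand_stiefel(12, 2, 41), rand_stiefel(12, 2, 42)))
  Z <- negative_gradient(U, L)
  eta <- tangent_project_stacked_oracle(U, Z)
  f0 <- mcsm_objective(U, L)
  step <- backtracking_step(U, eta, Z, L, opt_params())
  expect_true(step$accepted)
  expect_lt(step$f_next, f0)
  # orthonormal after retraction
  for (m in 1:2) {
    expect_lt(max(abs(crossprod(emb_block(step$U_next, m)) - diag(2))), 1e-8)
  }

  # zero direction: alpha0 accepted immediately, U unchanged
  step0 <- backtracking_step(U, 0 * eta, Z, L, opt_params())
  expect_equal(step0$alpha, opt_params()$alpha0)
  expect_equal(step0$U_next$mat, U$mat, tolerance = 1e-10)

  # ascent direction: rejected with alpha = 0
  stepa <- backtracking_step(U, -eta, Z, L, opt_params())
  expect_false(stepa$accepted)
  expect_equal(stepa$alpha, 0)
  expect_identical(stepa$U_next$mat, U$mat)
})

test_that("a line-search step strictly descends on the unit circle", {
  # 2 x 1 Stiefel manifold = unit circle; minimising x' L x for
  # L = diag(1, -1) has optimum at (0, +-1), objective -1
  Lg <- structure(list(L = Matrix::Matrix(diag(c(1, -1)), sparse = TRUE),
                       blocks = list(diag(c(1, -1))), beta = 0, M = 1L, n = 2L),
                  class = "joint_laplacian")
  theta <- 0.4   # non-optimal point on the circle
  U <- stacked_embedding(matrix(c(cos(theta), sin(theta)), 2, 1), M = 1)
  # circle-parametrization oracle: f(theta) = cos(2 theta)... check descent
  f0 <- mcsm_objective(U, Lg)
  expect_equal(f0, cos(theta)^2 - sin(theta)^2, tolerance = 1e-12)
  Z <- negative_gradient(U, Lg)
  eta <- tangent_project(U$mat, Z)
  step <- backtracking_step(U, eta, Z, Lg, opt_params())
  expect_true(step$accepted)
  expect_lt(step$f_next, f0)
  expect_equal(sum(step$U_next$mat^2), 1, tolerance = 1e-10)
})

test_that("single-view optimization recovers the bottom-K eigenspace", {
  sbm <- toy_sbm(sizes = c(10, 10, 10), p_in = 0.55, p_out = 0.05, seed = 51)
  g <- view_graph(sbm$A)
  L <- joint_laplacian(list(g))
  out <- mcsm_optimize(L, K = 3)
  e <- eigen(as.matrix(g$L), symmetric = TRUE)
  V <- e$vectors[, 30:28]
  ang <- principal_angles(out$U$mat, V)
  expect_lt(max(ang), 1e-3)
  expect_lt(max(abs(crossprod(out$U$mat) - diag(3))), 1e-8)
})

test_that("two identical views converge to matching subspaces", {
  sbm <- toy_sbm(sizes = c(10, 10, 10), p_in = 0.55, p_out = 0.05, seed = 61)
  g <- view_graph(sbm$A)
  L <- joint_laplacian(list(g, g), beta = 1)
  out <- mcsm_optimize(L, K = 3)
  ang <- principal_angles(emb_block(out$U, 1), emb_block(out$U, 2))
  expect_lt(max(ang), 1e-2)
})

test_that("the objective trace is monotone and blocks stay orthonormal", {
  for (seed in 1:5) {
    L <- toy_joint(M = 3, seed = 70 + seed, beta = 1)
    out <- mcsm_optimize(L, K = 2, params = opt_params(seed = seed),
                         init = if (seed %% 2) "pooled" else "random")
    expect_true(all(diff(out$trace$objective) <= 1e-12))
    for (m in 1:3) {
      expect_lt(max(abs(crossprod(emb_block(out$U, m)) - diag(2))), 1e-8)
    }
  }
})

test_that("optimizer accepts an explicit start and validates dimensions", {
  L <- toy_joint(M = 2, seed = 81)
  U0 <- list(rand_stiefel(12, 2, 82), rand_stiefel(12, 2, 83))
  out <- mcsm_optimize(L, K = 2, U0 = U0)
  expect_true(all(diff(out$trace$objective) <= 1e-12))
  expect_error(mcsm_optimize(L, K = 2, U0 = rand_stiefel(12, 2, 84)),
               "dimensions")
  expect_error(mcsm_optimize(L, K = 40), "exceed")
})
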