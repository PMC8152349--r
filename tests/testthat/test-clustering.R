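embed_from_points <- function(...) {
  # stack per-view coordinate matrices (rows = samples) into an embedding
  stacked_embedding(lapply(list(...), as.matrix))
}

test_that("per-view k-means separates well-separated clouds and is deterministic", {
  set.seed(101)
  pts <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), 10, 2),
               matrix(rnorm(20, mean = 5, sd = 0.1), 10, 2))
  U <- embed_from_points(pts, pts)
  vl <- kmeans_per_view(U, K = 2, seed = 9, row_norm = FALSE)
  truth <- rep(1:2, each = 10)
  expect_equal(rand_index(vl$labels[[1]], truth), 1)
  # identical blocks + same per-view seeds would differ only via RNG; rerun
  vl2 <- kmeans_per_view(U, K = 2, seed = 9, row_norm = FALSE)
  expect_identical(vl$labels, vl2$labels)
  expect_error(kmeans_per_view(U, K = 30, seed = 1), "exceed")
})

test_that("Calinski-Harabasz score matches an independent decomposition", {
  set.seed(102)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  lab <- rep(1:2, each = 20)
  # independent route: SSB = SST - SSW
  sst <- sum(sweep(x, 2, colMeans(x))^2)
  ssw <- sum(unlist(lapply(split.data.frame(x, lab), function(g) {
    sum(sweep(g, 2, colMeans(g))^2)
  })))
  expected <- ((sst - ssw) / (2 - 1)) / (ssw / (40 - 2))
  expect_equal(calinski_harabasz(x, lab), expected, tolerance = 1e-10)
})

test_that("select_k recovers the planted number of clusters", {
  set.seed(103)
  centres <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  pts <- centres[rep(1:3, each = 12), ] + matrix(rnorm(72, sd = 0.3), 36, 2)
  U <- embed_from_points(pts)
  sel <- select_k(U, k_min = 2, k_max = 7, seed = 5, row_norm = FALSE)
  expect_equal(sel$K, 3)
  expect_named(sel$ch_scores, as.character(2:7))
  # degenerate scan range: no alternatives scored
  sel2 <- select_k(U, k_min = 2, k_max = 2, seed = 5, row_norm = FALSE)
  expect_equal(sel2$K, 2)
  expect_length(sel2$ch_scores, 1)
})

test_that("the assignment solver matches brute-force enumeration", {
  for (seed in 1:12) {
    set.seed(200 + seed)
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    rows <- mcsm:::solve_assignment(cost)
    expect_equal(sort(rows), 1:n)   # a permutation
    achieved <- sum(cost[cbind(rows, 1:n)])
    expect_equal(achieved, assignment_brute(cost), tolerance = 1e-10)
  }
})

test_that("label alignment restores cross-view correspondence", {
  base <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  # view 2 = view 1 with labels renamed
  renamed <- c(3, 1, 2)[base]
  vl <- view_labels(list(base, renamed), K = 3)
  out <- align_labels(vl)
  expect_true(out$aligned)
  expect_identical(out$labels[[2]], out$labels[[1]])

  # single view: unchanged
  v1 <- align_labels(view_labels(list(base), K = 3))
  expect_identical(v1$labels[[1]], as.integer(base))

  # random 3-view fixture: alignment achieves the best relabelling of each
  # view against view 1 (exhaustive permutation oracle at K = 3)
  set.seed(104)
  labs <- lapply(1:3, function(m) sample(1:3, 30, replace = TRUE))
  out2 <- align_labels(view_labels(labs, K = 3))
  agree <- function(a, b) sum(a == b)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (m in 2:3) {
    best <- max(vapply(perms, function(p) agree(labs[[1]], p[labs[[m]]]), 0))
    expect_equal(agree(out2$labels[[1]], out2$labels[[m]]), best)
  }
})

test_that("KNN integration votes over neighbourhoods with documented tie-breaks", {
  # unanimity: all views agree -> final equals the common labelling
  set.seed(105)
  pts <- rbind(matrix(rnorm(16, 0, 0.1), 8, 2), matrix(rnorm(16, 4, 0.1), 8, 2))
  lab <- rep(1:2, each = 8)
  U <- embed_from_points(pts, pts)
  vl <- align_labels(view_labels(list(lab, lab), K = 2))
  out <- integrate_knn(U, vl, k_integrate = 3)
  expect_equal(out$final_labels, lab)

  # single view: final labels equal the view's labels
  U1 <- embed_from_points(pts)
  out1 <- integrate_knn(U1, align_labels(view_labels(list(lab), K = 2)),
                        k_integrate = 3)
  expect_equal(out1$final_labels, lab)

  # hand-built 8-sample fixture: the two views disagree on exactly one
  # boundary sample whose 3 nearest neighbours are unanimous
  coords <- matrix(c(0, 0.1, 0.2, 0.3, 5, 5.1, 5.2, 5.3), 8, 1)
  labA <- c(1, 1, 1, 1, 2, 2, 2, 2)
  labB <- c(1, 1, 1, 2, 2, 2, 2, 2)   # sample 4 disputed
  Ud <- embed_from_points(coords, coords)
  vld <- view_labels(list(labA, labB), K = 2, aligned = TRUE)
  outd <- integrate_knn(Ud, vld, k_integrate = 3, row_norm = FALSE)
  # sample 4's neighbours are 3, 2, 1, all labelled 1 in both views:
  # votes 7 x label 1 vs 1 x label 2 (its own view-B label)
  expect_equal(outd$final_labels[4], 1L)
  expect_equal(outd$final_labels[-4], labA[-4])

  # integration never invents labels
  expect_true(all(outd$final_labels %in% unlist(vld$labels)))

  # permutation equivariance
  perm <- sample(8)
  Up <- embed_from_points(coords[perm, , drop = FALSE], coords[perm, , drop = FALSE])
  vlp <- view_labels(list(labA[perm], labB[perm]), K = 2, aligned = TRUE)
  outp <- integrate_knn(Up, vlp, k_integrate = 3, row_norm = FALSE)
  expect_equal(outp$final_labels, outd$final_labels[perm])

  # k clamping and alignment precondition
  expect_warning(integrate_knn(Ud, vld, k_integrate = 20, row_norm = FALSE),
                 "clamping")
  expect_error(integrate_knn(Ud, view_labels(list(labA, labB), K = 2)),
               "align")
})
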