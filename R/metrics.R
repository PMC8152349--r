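#' Rand index between two partitions
#'
#' Fraction of unordered sample pairs on which the two partitions agree
#' (both together or both apart): `(TP + TN) / choose(n, 2)`. Invariant to
#' label permutation; equals 1 iff the partitions are identical up to
#' relabelling.
#'
#' @param pred,truth label vectors of equal length `>= 2` (any atomic type).
#' @return the Rand index in `[0, 1]`.
#' @export
rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must have equal length")
  n <- length(pred)
  if (n < 2) stop("need at least 2 samples")
  tab <- table(pred, truth)
  same_both <- sum(choose(tab, 2))
  same_pred <- sum(choose(rowSums(tab), 2))
  same_truth <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = pairs together in both + pairs apart in both
  (total + 2 * same_both - same_pred - same_truth) / total
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' `NMI(U, V) = 2 MI(U, V) / (H(U) + H(V))` with natural-log entropies and
#' the convention `0 log 0 = 0`. When both partitions are single clusters
#' (`H(U) + H(V) = 0`) the partitions are identical and 1 is returned.
#'
#' @param pred,truth label vectors of equal length.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors must have equal length")
  joint <- table(pred, truth) / length(pred)
  pi <- rowSums(joint)
  pj <- colSums(joint)
  denom <- entropy_nats(pi) + entropy_nats(pj)
  if (denom == 0) return(1)
  expected <- outer(pi, pj)
  pos <- joint > 0
  mi <- sum(joint[pos] * log(joint[pos] / expected[pos]))
  max(0, min(1, 2 * mi / denom))
}

#' Evaluate the clustering pipeline over replicate simulations
#'
#' For each run a fresh multi-view network is drawn from `spec` (with seed
#' `seed + 1000 * (run - 1)` added to the spec's base seed), the pipeline is
#' executed, and per-view Rand index / NMI are computed against each view's
#' own planted labels (the views have different truths by design). Values
#' are averaged over runs per view and overall.
#'
#' @param spec an [sbm_spec()].
#' @param pipeline function `(sim, K, seed) -> view_labels` (or a plain list
#'   of per-view label vectors). Defaults to the full fit of [mcsm_fit()].
#' @param n_runs number of replicate simulations (default 50).
#' @param seed integer base seed.
#' @param K number of clusters passed to the pipeline (default: the spec's).
#' @return object of class `eval_report`: per-view mean `ri_per_view` /
#'   `nmi_per_view`, overall `mean_ri` / `mean_nmi`, per-run matrices
#'   `ri_runs` / `nmi_runs` (runs x views), `n_runs` and `n_failed`.
#' @export
evaluate_runs <- function(spec, pipeline = NULL, n_runs = 50, seed = 1L,
                          K = spec$K) {
  stopifnot(inherits(spec, "sbm_spec"), n_runs >= 1)
  if (is.null(pipeline)) {
    pipeline <- function(sim, K, seed) {
      mcsm_fit(sim$adjacencies, K = K, seed = seed)$per_view
    }
  }
  M <- spec$M
  ri_runs <- matrix(NA_real_, n_runs, M)
  nmi_runs <- matrix(NA_real_, n_runs, M)
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    run_seed <- spec$seed + seed + 1000L * (r - 1L)
    spec_r <- spec
    spec_r$seed <- run_seed
    res <- tryCatch({
      sim <- simulate_multiview(spec_r)
      vl <- pipeline(sim, K, run_seed)
      labels <- if (inherits(vl, "view_labels")) vl$labels else vl
      list(ri = vapply(seq_len(M), function(m) rand_index(labels[[m]], sim$truth[[m]]), 0),
           nmi = vapply(seq_len(M), function(m) nmi(labels[[m]], sim$truth[[m]]), 0))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
    } else {
      ri_runs[r, ] <- res$ri
      nmi_runs[r, ] <- res$nmi
    }
  }
  ok <- !is.na(ri_runs[, 1])
  if (!any(ok)) stop("every run failed; first error: ", failures[1])
  structure(list(ri_per_view = colMeans(ri_runs[ok, , drop = FALSE]),
                 nmi_per_view = colMeans(nmi_runs[ok, , drop = FALSE]),
                 mean_ri = mean(ri_runs[ok, ]),
                 mean_nmi = mean(nmi_runs[ok, ]),
                 ri_runs = ri_runs, nmi_runs = nmi_runs,
                 n_runs = as.integer(n_runs), n_failed = sum(!ok),
                 failures = failures),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d runs (%d failed)\n", x$n_runs, x$n_failed))
  cat(sprintf("  mean RI  %.4f  per view: %s\n", x$mean_ri,
              paste(sprintf("%.3f", x$ri_per_view), collapse = " ")))
  cat(sprintf("  mean NMI %.4f  per view: %s\n", x$mean_nmi,
              paste(sprintf("%.3f", x$nmi_per_view), collapse = " ")))
  invisible(x)
}
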