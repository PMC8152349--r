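#' Fit the multi-view clustering model to a set of graphs
#'
#' End-to-end model fit from per-view networks: assemble the joint block
#' Laplacian, minimise `trace(U' L U)` over the product of Stiefel manifolds
#' ([mcsm_optimize()]), run per-view k-means on the embedding blocks, align
#' labels across views and integrate them by the k-nearest-neighbour
#' majority vote.
#'
#' @param graphs list of `view_graph` objects or adjacency matrices (all
#'   views over the same samples).
#' @param K number of clusters; `NULL` to choose by [select_k()] over
#'   `k_range`.
#' @param beta coupling weight of the joint Laplacian (default 1).
#' @param params an [opt_params()].
#' @param seed integer seed driving k-means and integration.
#' @param k_integrate neighbours for label integration (default
#'   `max(10, round(N/10))`).
#' @param k_range scan range for `K` when `K = NULL` (default `2:10`).
#' @return object of class `mcsm_fit`: list with `clustering` (an
#'   `integrated_clustering`), `per_view` (aligned [view_labels()]), `U`
#'   (the [stacked_embedding()]), `trace` (optimizer `opt_trace`), `K`,
#'   `k_selection` (when `K` was selected) and the call parameters.
#' @export
mcsm_fit <- function(graphs, K = NULL, beta = 1, params = opt_params(),
                     seed = 1L, k_integrate = NULL, k_range = 2:10) {
  L <- joint_laplacian(graphs, beta = beta)
  ksel <- NULL
  if (is.null(K)) {
    # scan with the largest candidate dimension, then refit at the chosen K
    opt0 <- mcsm_optimize(L, K = max(k_range), params = params)
    ksel <- select_k(opt0$U, k_min = min(k_range), k_max = max(k_range),
                     seed = seed)
    K <- ksel$K
  }
  opt <- mcsm_optimize(L, K = K, params = params)
  vl <- align_labels(kmeans_per_view(opt$U, K = K, seed = seed))
  cl <- integrate_knn(opt$U, vl, k_integrate = k_integrate)
  structure(list(clustering = cl, per_view = vl, final_labels = cl$final_labels,
                 U = opt$U, trace = opt$trace, K = K, beta = beta,
                 k_selection = ksel, params = params, seed = as.integer(seed)),
            class = "mcsm_fit")
}

#' @export
print.mcsm_fit <- function(x, ...) {
  cat(sprintf("mcsm_fit: M = %d views, N = %d samples, K = %d\n",
              x$U$M, x$U$n, x$K))
  print(x$trace)
  print(x$clustering)
  invisible(x)
}

#' Cluster real multi-omics matrices
#'
#' Real-data pipeline: [preprocess_views()] (missing-data filters, KNN
#' imputation, log transform, standardization), per-view heat-kernel KNN
#' similarity graphs, then [mcsm_fit()].
#'
#' @param matrices list of [omics_matrix()] sharing a sample set.
#' @param K number of clusters (`NULL` to select automatically).
#' @param t heat-kernel bandwidth (`NULL`: per-view median distance).
#' @param k_neighbors graph neighbourhood size (`NULL`:
#'   `max(10, round(N/10))`).
#' @param preprocess run the preprocessing chain first (default `TRUE`; set
#'   to `FALSE` if the matrices are already complete and standardized).
#' @param max_missing_frac,impute_k,log,offset preprocessing settings, see
#'   [preprocess_views()].
#' @param ... passed to [mcsm_fit()] (`beta`, `params`, `seed`,
#'   `k_integrate`, `k_range`).
#' @return an `mcsm_fit` with an extra `sample_ids` element.
#' @export
mcsm_from_omics <- function(matrices, K = NULL, t = NULL, k_neighbors = NULL,
                            preprocess = TRUE, max_missing_frac = 0.2,
                            impute_k = 20, log = TRUE, offset = 1, ...) {
  if (preprocess) {
    matrices <- preprocess_views(matrices, max_missing_frac = max_missing_frac,
                                 impute_k = impute_k, log = log, offset = offset)
  } else {
    matrices <- lapply(matrices, as_omics)
  }
  graphs <- lapply(matrices, function(x) knn_graph(heat_kernel(x, t = t), k_neighbors))
  fit <- mcsm_fit(graphs, K = K, ...)
  fit$sample_ids <- colnames(matrices[[1]])
  fit
}

#' Run a configured pipeline and write its artifacts
#'
#' Orchestrates either the simulation pipeline (simulate, fit, evaluate
#' against planted labels) or the real-data pipeline (read matrices,
#' preprocess, build graphs, fit), writing labels, the objective trace, an
#' evaluation report (simulation mode) and a manifest with all parameters
#' to `out_dir`.
#'
#' @param config list. Common fields: `mode` (`"simulate"` or `"real"`),
#'   `K` (or `NULL` for automatic selection), `beta`, `seed`, `k_integrate`,
#'   `opt` (list passed to [opt_params()]). Simulation mode: either `spec`
#'   (an [sbm_spec()]) or `setting`/`pmatrix` for the presets, plus optional
#'   `n_runs` (default 1; the first run's labels are written). Real mode:
#'   `paths` (vector of matrix files), `sep`, `t`, `k_neighbors`, and the
#'   preprocessing fields of [mcsm_from_omics()].
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @return list with `fit` (an `mcsm_fit`) and, in simulation mode,
#'   `report` (an `eval_report`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), config$mode %in% c("simulate", "real"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- do.call(opt_params, c(config$opt, if (is.null(config$opt$seed)) list(seed = seed)))
  beta <- if (is.null(config$beta)) 1 else config$beta
  if (config$mode == "simulate") {
    spec <- if (!is.null(config$spec)) config$spec
            else sbm_setting(config$setting,
                             pmatrix = if (is.null(config$pmatrix)) 1 else config$pmatrix,
                             seed = seed)
    n_runs <- if (is.null(config$n_runs)) 1L else as.integer(config$n_runs)
    K <- if (is.null(config$K)) spec$K else config$K
    sim <- simulate_multiview(spec)
    fit <- mcsm_fit(sim$adjacencies, K = K, beta = beta, params = params,
                    seed = seed, k_integrate = config$k_integrate)
    report <- evaluate_runs(spec, n_runs = n_runs, seed = seed, K = K,
                            pipeline = function(sim, K, s) {
                              mcsm_fit(sim$adjacencies, K = K, beta = beta,
                                       params = params, seed = s)$per_view
                            })
    out <- list(fit = fit, report = report)
    ids <- paste0("node", seq_len(spec$N))
  } else {
    if (is.null(config$paths)) stop("real mode requires `paths`")
    missing_files <- config$paths[!file.exists(config$paths)]
    if (length(missing_files) > 0) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    }
    sep <- if (is.null(config$sep)) "\t" else config$sep
    mats <- lapply(config$paths, read_omics_matrix, sep = sep)
    pp <- list(max_missing_frac = config$max_missing_frac,
               impute_k = config$impute_k, log = config$log,
               offset = config$offset, preprocess = config$preprocess)
    pp <- pp[!vapply(pp, is.null, TRUE)]
    fit <- do.call(mcsm_from_omics,
                   c(list(mats, K = config$K, t = config$t,
                          k_neighbors = config$k_neighbors, beta = beta,
                          params = params, seed = seed,
                          k_integrate = config$k_integrate), pp))
    out <- list(fit = fit)
    ids <- fit$sample_ids
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    labels_df <- data.frame(sample_id = ids,
                            final_label = out$fit$final_labels,
                            do.call(cbind, stats::setNames(
                              out$fit$per_view$labels,
                              paste0("view", seq_along(out$fit$per_view$labels), "_label"))))
    utils::write.table(labels_df, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(iteration = seq_along(out$fit$trace$objective) - 1L,
                 objective = out$fit$trace$objective),
      file.path(out_dir, "objective_trace.csv"), sep = ",", quote = FALSE,
      row.names = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("mcsm")),
                     mode = config$mode, seed = seed, K = out$fit$K, beta = beta,
                     opt_params = unclass(out$fit$params),
                     config = config[setdiff(names(config), c("spec", "opt"))])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    if (!is.null(out$report)) {
      jsonlite::write_json(
        list(mean_ri = out$report$mean_ri, mean_nmi = out$report$mean_nmi,
             ri_per_view = out$report$ri_per_view,
             nmi_per_view = out$report$nmi_per_view,
             ri_runs = out$report$ri_runs, nmi_runs = out$report$nmi_runs,
             n_runs = out$report$n_runs, n_failed = out$report$n_failed),
        file.path(out_dir, "report.json"), pretty = TRUE, auto_unbox = TRUE,
        digits = NA)
    }
  }
  invisible(out)
}
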