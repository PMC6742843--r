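#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run:
#' simulate (or load) -> denoise -> connectivity -> graph topology ->
#' group inference.
#'
#' @param spec A [cohort_spec()] used when simulating; ignored when
#'   `manifest` is given.
#' @param manifest Optional path to a cohort manifest CSV to load instead of
#'   simulating.
#' @param denoise A [denoise_config()].
#' @param graph A [graph_config()].
#' @param restriction A [seed_restriction()] or NULL (test all pairs).
#' @param kinds Connectivity kinds to run, subset of `c("FUN", "EFF")`.
#' @param q FDR level in (0, 1). Default 0.05.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes matrices, metric tables, stats tables and the run log there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = example_cohort_spec(), manifest = NULL,
                            denoise = denoise_config(), graph = graph_config(),
                            restriction = NULL, kinds = c("FUN", "EFF"),
                            q = 0.05, out_dir = NULL) {
  stopifnot(q > 0 || q == 0, q < 1)
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (!is.null(manifest) && !file.exists(manifest))
    abort(paste0("Manifest not found: ", manifest))
  structure(list(spec = spec, manifest = manifest, denoise = denoise,
                 graph = graph, restriction = restriction, kinds = kinds,
                 q = q, out_dir = out_dir),
            class = "pipeline_config")
}

#' Serialize / restore a cohort spec as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$planted_effects <- as.list(spec$planted_effects)
  x$nuisance <- unclass(spec$nuisance)
  x$seeds <- attr(spec, "seeds")
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  pe <- if (length(x$planted_effects$seed) > 0)
    tibble::as_tibble(x$planted_effects) else NULL
  spec <- cohort_spec(
    n_per_group = x$n_per_group, n_timepoints = x$n_timepoints, tr = x$tr,
    roi_labels = x$roi_labels, blocks = x$blocks, within_cor = x$within_cor,
    between_cor = x$between_cor, planted_effects = pe, ar_coef = x$ar_coef,
    roi_sd = x$roi_sd, nuisance = do.call(nuisance_spec, x$nuisance),
    master_seed = x$master_seed)
  if (!is.null(x$seeds)) attr(spec, "seeds") <- x$seeds
  spec
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a two-group cohort, denoises every subject, computes
#' the requested connectivity kinds with Fisher z-transformation, builds
#' thresholded binary graphs and the seven node metrics, and performs
#' edge-wise and node-wise group comparisons with BH-FDR. Deterministic
#' given the spec's master seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `cohort` (denoised, with
#'   list-columns `z`, `graph`, `metrics` per kind), `edgewise` and
#'   `nodewise` (`group_stats` tables per kind / metric), and `log`
#'   (config hash, seeds, stage order, warnings such as Fisher clips).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  log <- list(config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
              kinds = cfg$kinds, q = cfg$q, stages = character(),
              warnings = character())
  if (!is.null(cfg$manifest)) {
    cohort <- read_cohort(cfg$manifest)
    log$source <- cfg$manifest
  } else {
    cohort <- simulate_cohort(cfg$spec)
    log$source <- "simulated"
    log$master_seed <- cfg$spec$master_seed
  }
  log$n_subjects <- nrow(cohort)
  log$stages <- c(log$stages, "simulate_or_load")

  cohort <- denoise_cohort(cohort, cfg$denoise)
  log$n_outliers <- vapply(cohort$denoise_report, function(r) r$n_outliers,
                           numeric(1))
  log$stages <- c(log$stages, "denoise")

  labels <- colnames(cohort$series[[1]])
  restriction <- cfg$restriction %||% seed_restriction(labels, labels)

  results <- list()
  skipped <- setdiff(c("FUN", "EFF"), cfg$kinds)
  if (length(skipped) > 0)
    log$skipped_kinds <- skipped
  n_clip_total <- 0
  for (kind in cfg$kinds) {
    fc <- if (kind == "FUN") functional_connectivity else effective_connectivity
    z <- purrr::map(cohort$series, function(s)
      withCallingHandlers(fisher_z(fc(s)),
                          message = function(m) invokeRestart("muffleMessage")))
    n_clip_total <- n_clip_total +
      sum(vapply(z, function(m) attr(m, "n_clipped") %||% 0L, numeric(1)))
    graphs <- purrr::map(z, threshold_binarize, cfg = cfg$graph)
    metrics <- purrr::map(graphs, node_metrics, cfg = cfg$graph)
    dat <- tibble::tibble(subject_id = cohort$subject_id,
                          group = cohort$group, z = z)
    edge <- edgewise_group_comparison(dat, restriction, q = cfg$q)
    mdat <- tibble::tibble(subject_id = cohort$subject_id,
                           group = cohort$group, metrics = metrics)
    node <- purrr::map(setNames(.metric_names, .metric_names), function(m)
      nodewise_metric_comparison(mdat, m, q = cfg$q))
    results[[kind]] <- list(z = z, graphs = graphs, metrics = metrics,
                            edgewise = edge, nodewise = node)
  }
  log$n_fisher_clips <- n_clip_total
  log$stages <- c(log$stages, "connectivity", "graph_topology",
                  "group_inference")

  out <- structure(list(cohort = cohort, results = results, log = log,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d subjects; kinds: %s; q = %g\n", nrow(x$cohort),
              paste(names(x$results), collapse = ", "), x$log$q))
  for (k in names(x$results)) {
    g <- glance(x$results[[k]]$edgewise)
    cat(sprintf("  %s edgewise: %d tested, %d significant (%d+, %d-)\n",
                k, g$n_tested, g$n_significant, g$n_sig_positive,
                g$n_sig_negative))
  }
  invisible(x)
}

#' Write a pipeline result bundle to a directory
#'
#' Per subject and kind: z-matrix CSVs and node-metric TSVs; per kind:
#' edgewise and nodewise group-stats TSVs; plus `run_log.json`.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in names(result$results)) {
    res <- result$results[[kind]]
    kd <- file.path(dir, tolower(kind))
    dir.create(kd, showWarnings = FALSE)
    purrr::walk2(res$z, result$cohort$subject_id, function(m, id)
      write_conn_matrix(m, file.path(kd, paste0(id, "_z.csv"))))
    purrr::walk2(res$metrics, result$cohort$subject_id, function(m, id)
      write_node_metrics(m, file.path(kd, paste0(id, "_metrics.tsv"))))
    write_group_stats(res$edgewise, file.path(kd, "edgewise_stats.tsv"))
    nodewise <- dplyr::bind_rows(purrr::map(res$nodewise, tidy))
    readr::write_tsv(nodewise, file.path(kd, "nodewise_stats.tsv"))
  }
  jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replicate study: edge-wise FDR behaviour over simulated cohorts
#'
#' Repeats the full FUN pipeline (simulate -> denoise -> correlate ->
#' Fisher z -> edge-wise pooled t + BH-FDR) over independent replicate
#' cohorts drawn from the same spec with per-replicate seeds, and scores
#' each replicate against the spec's planted ground truth: how many retained
#' connections are true planted edges, the false-discovery proportion among
#' retained connections (0 when none are retained), and whether all planted
#' edges were recovered with the planted sign.
#'
#' @param spec A [cohort_spec()] with planted effects (see
#'   [example_cohort_spec()]).
#' @param n_replicates Number of replicate cohorts.
#' @param seed Integer seed governing all replicate master seeds.
#' @param seeds Seed ROI labels for the restriction; defaults to attribute
#'   `seeds` of the spec, else all ROIs.
#' @param q FDR level. Default 0.05.
#' @param denoise A [denoise_config()].
#' @return Tibble with one row per replicate: `replicate`, `n_tested`,
#'   `n_significant`, `n_true_positive`, `n_false_positive`, `fdp`,
#'   `recovered_all` (all planted edges significant with the planted sign).
#' @export
replicate_edgewise_study <- function(spec, n_replicates = 200, seed = 1,
                                     seeds = NULL, q = 0.05,
                                     denoise = denoise_config()) {
  seeds_roi <- seeds %||% attr(spec, "seeds") %||% spec$roi_labels
  restriction <- seed_restriction(spec$roi_labels, seeds_roi)
  planted <- spec$planted_effects
  rep_seeds <- derive_seeds(seed, n_replicates)
  pairs <- tested_pairs(restriction, "FUN")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted_key <- key(planted$seed, planted$target)
  stopifnot(all(planted_key %in% key(pairs$seed, pairs$target)))
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    sp <- spec
    sp$master_seed <- rep_seeds[r]
    cohort <- simulate_cohort(sp)
    cohort <- denoise_cohort(cohort, denoise)
    z <- purrr::map(cohort$series, function(s)
      suppressMessages(fisher_z(functional_connectivity(s))))
    dat <- tibble::tibble(subject_id = cohort$subject_id,
                          group = cohort$group, z = z)
    st <- edgewise_group_comparison(dat, restriction, q = q)
    sig <- st[st$significant, ]
    sig_key <- key(sig$seed, sig$target)
    truth <- match(sig_key, planted_key)
    tp_sign_ok <- !is.na(truth) & sign(sig$t) == sign(planted$delta[truth])
    n_tp <- sum(!is.na(truth))
    n_fp <- sum(is.na(truth))
    tibble::tibble(
      replicate = r,
      n_tested = nrow(st),
      n_significant = nrow(sig),
      n_true_positive = n_tp,
      n_false_positive = n_fp,
      fdp = if (nrow(sig) > 0) n_fp / nrow(sig) else 0,
      recovered_all = sum(tp_sign_ok) == nrow(planted)
    )
  })
}
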