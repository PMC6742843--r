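#' Specify a synthetic two-group resting-state cohort
#'
#' Builds a validated specification for the synthetic cohort generator. The
#' generator emulates a two-group resting-state study design: `n_per_group`
#' subjects per group, `n_timepoints` volumes at repetition time `tr`,
#' ROI signals drawn as multivariate Gaussian innovations with a
#' block-structured correlation matrix, combined through a common AR(1)
#' temporal filter, and contaminated with linear drift, a slow sinusoid,
#' scheduled motion/signal spikes and injected nuisance components.
#' Group differences are planted on designated seed-target edges
#' (`planted_effects`), present in the patient group only.
#'
#' @param n_per_group Subjects per group (>= 2). Default 28.
#' @param n_timepoints Volumes per subject (>= 20). Default 220.
#' @param tr Repetition time in seconds. Default 3.2.
#' @param roi_labels Character vector of ROI labels; defaults to
#'   `sprintf("roi_%02d", 1:n_rois)`.
#' @param n_rois Number of ROIs when `roi_labels` is NULL. Default 40.
#' @param blocks Integer community id per ROI (block covariance structure).
#'   Default: 4 equal-size blocks.
#' @param within_cor Base correlation inside a block, in (-1, 1). Default 0.3.
#' @param between_cor Base correlation across blocks. Default 0.05.
#' @param planted_effects Data frame with columns `seed`, `target`, `delta`:
#'   correlation deltas added in the patient group only. Default none.
#' @param ar_coef Lag-1 autoregressive coefficient in [0, 1). Default 0.3.
#' @param roi_sd Per-ROI innovation standard deviation (length 1 or N). Default 1.
#' @param nuisance Nuisance/artifact settings from [nuisance_spec()].
#' @param master_seed Integer master seed; the whole cohort is a pure function
#'   of the spec including this seed.
#' @return A validated object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [build_group_covariance()]
#' @export
cohort_spec <- function(n_per_group = 28, n_timepoints = 220, tr = 3.2,
                        roi_labels = NULL, n_rois = 40, blocks = NULL,
                        within_cor = 0.3, between_cor = 0.05,
                        planted_effects = NULL, ar_coef = 0.3, roi_sd = 1,
                        nuisance = nuisance_spec(), master_seed = 1L) {
  if (is.null(roi_labels)) roi_labels <- sprintf("roi_%02d", seq_len(n_rois))
  n_rois <- length(roi_labels)
  if (anyDuplicated(roi_labels)) abort("ROI labels must be unique.")
  if (n_per_group < 2) abort("n_per_group must be >= 2.")
  if (n_timepoints < 20) abort("n_timepoints must be >= 20.")
  if (tr <= 0) abort("tr must be positive.")
  if (ar_coef < 0 || ar_coef >= 1) abort("ar_coef must lie in [0, 1).")
  if (is.null(blocks)) {
    blocks <- rep(seq_len(4), length.out = n_rois)
    blocks <- sort(blocks)
  }
  if (length(blocks) != n_rois) abort("blocks must have one entry per ROI.")
  if (abs(within_cor) >= 1 || abs(between_cor) >= 1)
    abort("Base correlations must lie in (-1, 1).", class = "roinet_invalid_spec")
  if (length(roi_sd) == 1) roi_sd <- rep(roi_sd, n_rois)
  if (length(roi_sd) != n_rois || any(roi_sd <= 0))
    abort("roi_sd must be positive, length 1 or one per ROI.")
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(seed = character(), target = character(),
                                      delta = numeric())
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  stopifnot(all(c("seed", "target", "delta") %in% names(planted_effects)))
  bad <- setdiff(c(planted_effects$seed, planted_effects$target), roi_labels)
  if (length(bad) > 0)
    abort(paste0("Planted-effect ROI not in roi_labels: ",
                 paste(bad, collapse = ", ")), class = "roinet_invalid_spec")
  if (any(planted_effects$seed == planted_effects$target))
    abort("Planted effects must connect two distinct ROIs.",
          class = "roinet_invalid_spec")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_timepoints = as.integer(n_timepoints), tr = tr,
         roi_labels = roi_labels, blocks = as.integer(blocks),
         within_cor = within_cor, between_cor = between_cor,
         planted_effects = planted_effects, ar_coef = ar_coef,
         roi_sd = roi_sd, nuisance = nuisance,
         master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

#' Nuisance and artifact settings for the cohort generator
#'
#' @param drift_amplitude Total linear-drift rise over the scan, in units of
#'   ROI innovation SD. Default 1.
#' @param sin_amplitude,sin_freq Amplitude (SD units) and frequency (Hz) of an
#'   additive slow sinusoid. Defaults 0.5 and 0.003 Hz (below the retained
#'   pass-band, so denoising removes it).
#' @param spike_times Volume indices at which a motion step and a one-volume
#'   global signal artifact occur. Default `c(55L, 145L)`.
#' @param spike_amp Step size of the motion spike (mm) and amplitude of the
#'   coincident signal artifact (SD units). Default 2.
#' @param motion_scale Innovation SD of the smooth motion-parameter noise, in
#'   mm (rotations use `motion_scale / 50` rad). Default 0.02.
#' @param n_components Number of injected nuisance component series. Default 10.
#' @param loading_sd SD of the per-ROI loadings with which nuisance components
#'   are injected into the ROI signals. Default 0.3.
#' @return A list of class `nuisance_spec`.
#' @export
nuisance_spec <- function(drift_amplitude = 1, sin_amplitude = 0.5,
                          sin_freq = 0.003, spike_times = c(55L, 145L),
                          spike_amp = 2, motion_scale = 0.02,
                          n_components = 10, loading_sd = 0.3) {
  structure(list(drift_amplitude = drift_amplitude,
                 sin_amplitude = sin_amplitude, sin_freq = sin_freq,
                 spike_times = as.integer(spike_times), spike_amp = spike_amp,
                 motion_scale = motion_scale,
                 n_components = as.integer(n_components),
                 loading_sd = loading_sd),
            class = "nuisance_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects/group, %d volumes, TR %.2f s, %d ROIs\n",
              x$n_per_group, x$n_timepoints, x$tr, length(x$roi_labels)))
  cat(sprintf("  blocks: %d; within r = %.2f, between r = %.2f; AR(1) = %.2f\n",
              length(unique(x$blocks)), x$within_cor, x$between_cor, x$ar_coef))
  cat(sprintf("  planted effects: %d; master seed %d\n",
              nrow(x$planted_effects), x$master_seed))
  invisible(x)
}

# Deterministic per-purpose sub-seeds derived from a base seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Build the group covariance matrix implied by a cohort spec
#'
#' Constructs the N x N covariance whose implied correlations follow the block
#' structure of the spec, with the planted seed-target deltas applied for the
#' patient group only. If the raw construction is not positive definite it is
#' repaired by the smallest uniform eigenvalue shift on the correlation scale
#' (`R <- (R + sI) / (1 + s)`), which preserves the unit diagonal; the shift
#' is recorded in attribute `pd_repair_shift`. A repair that would move any
#' correlation by more than 0.05 is an error.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @return Covariance matrix with dimnames = ROI labels.
#' @export
build_group_covariance <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  n <- length(spec$roi_labels)
  same_block <- outer(spec$blocks, spec$blocks, "==")
  R <- ifelse(same_block, spec$within_cor, spec$between_cor)
  diag(R) <- 1
  if (group == "patient" && nrow(spec$planted_effects) > 0) {
    i <- match(spec$planted_effects$seed, spec$roi_labels)
    j <- match(spec$planted_effects$target, spec$roi_labels)
    for (k in seq_along(i)) {
      R[i[k], j[k]] <- R[i[k], j[k]] + spec$planted_effects$delta[k]
      R[j[k], i[k]] <- R[i[k], j[k]]
    }
  }
  off <- R[upper.tri(R)]
  if (any(abs(off) >= 1))
    abort("Implied correlation outside (-1, 1); check block structure and deltas.",
          class = "roinet_invalid_spec")
  shift <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  eps <- 1e-8
  if (min(ev) < eps) {
    shift <- (eps - min(ev)) / (1 - eps)
    distortion <- max(abs(off)) * shift / (1 + shift)
    if (distortion > 0.05)
      abort(sprintf(
        "Positive-definiteness repair would distort correlations by %.3f (> 0.05).",
        distortion), class = "roinet_pd_repair_error")
    R <- (R + diag(shift, n)) / (1 + shift)
  }
  S <- R * tcrossprod(spec$roi_sd)
  dimnames(S) <- list(spec$roi_labels, spec$roi_labels)
  structure(S, pd_repair_shift = shift)
}

#' Simulate one subject's ROI time series
#'
#' Draws T multivariate Gaussian innovation vectors with covariance `cov`,
#' passes them through a common AR(1) recursion with coefficient
#' `spec$ar_coef` (20-volume burn-in, so the kept series is effectively
#' stationary), then adds the nuisance contamination of the spec: linear
#' drift, slow sinusoid, one-volume global signal artifacts at the scheduled
#' spike times, and — when `confounds` is supplied — the subject's nuisance
#' component series injected with deterministic per-ROI loadings (see
#' [nuisance_loadings()]), so that confound regression has a known ground
#' truth. Output is bit-reproducible given `subject_seed`.
#'
#' @param cov Positive-definite covariance matrix (N x N).
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed for this subject.
#' @param confounds Optional [simulate_confounds()] output whose nuisance
#'   components should be injected into the signals.
#' @return A T x N tibble, one column per ROI label.
#' @export
simulate_subject <- function(cov, spec, subject_seed, confounds = NULL) {
  n <- length(spec$roi_labels)
  stopifnot(nrow(cov) == n, ncol(cov) == n)
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("Covariance must be positive definite.")
  tt <- spec$n_timepoints
  burn <- 20L
  seeds <- derive_seeds(subject_seed, 3)
  L <- chol(cov)
  x <- withr::with_seed(seeds[1], {
    innov <- matrix(rnorm((tt + burn) * n), tt + burn, n) %*% L
    if (spec$ar_coef > 0) {
      innov <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, spec$ar_coef, method = "recursive")))
    }
    innov[(burn + 1):(burn + tt), , drop = FALSE]
  })
  nu <- spec$nuisance
  time_idx <- seq_len(tt)
  shared <- nu$drift_amplitude * (time_idx - 1) / (tt - 1) +
    nu$sin_amplitude * sin(2 * pi * nu$sin_freq * spec$tr * (time_idx - 1))
  spikes <- numeric(tt)
  st <- nu$spike_times[nu$spike_times >= 1 & nu$spike_times <= tt]
  spikes[st] <- nu$spike_amp
  x <- x + outer(shared + spikes, spec$roi_sd)
  if (!is.null(confounds)) {
    comps <- as.matrix(confounds$nuisance)
    if (nrow(comps) != tt) abort("Confound series length must match n_timepoints.")
    load <- nuisance_loadings(spec, subject_seed)
    x <- x + (comps %*% t(load)) * rep(spec$roi_sd, each = tt)
  }
  colnames(x) <- spec$roi_labels
  tibble::as_tibble(x)
}

#' Ground-truth loadings used to inject nuisance components into ROI signals
#'
#' @inheritParams simulate_subject
#' @return N x K loading matrix (rows = ROIs, cols = components).
#' @export
nuisance_loadings <- function(spec, subject_seed) {
  seeds <- derive_seeds(subject_seed, 3)
  n <- length(spec$roi_labels)
  k <- spec$nuisance$n_components
  withr::with_seed(seeds[3],
                   matrix(rnorm(n * k, sd = spec$nuisance$loading_sd), n, k,
                          dimnames = list(spec$roi_labels, NULL)))
}

#' Simulate one subject's confound set
#'
#' Produces 6 motion-parameter series (3 translations in mm, 3 rotations in
#' rad) as smooth AR(1) noise with scheduled step changes on translation-x,
#' and `n_components` smooth nuisance component series (stand-ins for
#' principal components of white-matter and CSF signals).
#'
#' @inheritParams simulate_subject
#' @return A list of class `confound_set` with tibbles `motion`
#'   (columns trans_x..rot_z) and `nuisance` (columns comp_01..).
#' @export
simulate_confounds <- function(spec, subject_seed) {
  tt <- spec$n_timepoints
  nu <- spec$nuisance
  seeds <- derive_seeds(subject_seed, 3)
  smooth_noise <- function(scale, phi, m) {
    if (scale == 0) return(matrix(0, tt, m))
    innov <- matrix(rnorm(tt * m, sd = scale), tt, m)
    apply(innov, 2, function(e)
      as.numeric(stats::filter(e, phi, method = "recursive")))
  }
  out <- withr::with_seed(seeds[2], {
    trans <- smooth_noise(nu$motion_scale, 0.95, 3)
    rot <- smooth_noise(nu$motion_scale / 50, 0.95, 3)
    comps <- smooth_noise(sqrt(1 - 0.9^2), 0.9, nu$n_components)
    list(trans = trans, rot = rot, comps = comps)
  })
  st <- nu$spike_times[nu$spike_times >= 1 & nu$spike_times <= tt]
  for (t0 in st) out$trans[t0:tt, 1] <- out$trans[t0:tt, 1] + nu$spike_amp
  motion <- cbind(out$trans, out$rot)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  comps <- out$comps
  colnames(comps) <- sprintf("comp_%02d", seq_len(ncol(comps)))
  structure(list(motion = tibble::as_tibble(motion),
                 nuisance = tibble::as_tibble(comps)),
            class = "confound_set")
}

#' Simulate a full two-group cohort
#'
#' Generates `2 * n_per_group` subjects (groups `control` and `patient`),
#' each with a confound set and an ROI time series carrying the group's
#' covariance structure plus all nuisance contamination. Per-subject seeds
#' are derived deterministically from `spec$master_seed`, so the cohort is a
#' pure function of its spec.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `roi_cohort` with columns `subject_id`, `group`,
#'   `tr`, `seed`, and list-columns `series` (T x N tibbles) and `confounds`
#'   ([simulate_confounds()] outputs). The spec is attached as attribute
#'   `spec`.
#' @examples
#' spec <- cohort_spec(n_per_group = 2, n_timepoints = 40, n_rois = 6,
#'                     master_seed = 7)
#' cohort <- simulate_cohort(spec)
#' nrow(cohort) # 4
#' @export
simulate_cohort <- function(spec) {
  n_sub <- 2L * spec$n_per_group
  seeds <- derive_seeds(spec$master_seed, n_sub)
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("%s_%02d", ifelse(groups == "control", "ctrl", "pat"),
                 c(seq_len(spec$n_per_group), seq_len(spec$n_per_group)))
  covs <- list(control = build_group_covariance(spec, "control"),
               patient = build_group_covariance(spec, "patient"))
  confounds <- purrr::map(seeds, ~ simulate_confounds(spec, .x))
  series <- purrr::pmap(list(groups, seeds, confounds), function(g, s, cf)
    simulate_subject(covs[[g]], spec, s, confounds = cf))
  out <- tibble::tibble(subject_id = ids, group = groups, tr = spec$tr,
                        seed = seeds, series = series, confounds = confounds)
  attr(out, "spec") <- spec
  class(out) <- c("roi_cohort", class(out))
  out
}

#' A ready-made study-scale cohort spec with planted seed-target effects
#'
#' Convenience constructor mirroring the package's reference simulation
#' design: `n_rois` regions in four equal covariance blocks, the first
#' `n_seeds` ROIs designated as seed regions, and `n_planted` planted
#' correlation increases of size `delta` between seed i and a target in the
#' second block (pairwise-disjoint edges), present in the patient group only.
#'
#' @param n_rois Number of ROIs (default 40).
#' @param n_seeds Number of seed ROIs (default 10; the first block).
#' @param n_planted Number of planted seed-target edges (default 10).
#' @param delta Planted correlation increase (default 0.3).
#' @param master_seed Master seed.
#' @inheritParams cohort_spec
#' @return A [cohort_spec()] with attribute `seeds` (the seed ROI labels).
#' @export
example_cohort_spec <- function(n_rois = 40, n_seeds = 10, n_planted = 10,
                                delta = 0.3, n_per_group = 28,
                                n_timepoints = 220, master_seed = 1L, ...) {
  stopifnot(n_planted <= n_seeds, n_rois >= 2 * n_seeds)
  labels <- sprintf("roi_%02d", seq_len(n_rois))
  planted <- tibble::tibble(seed = labels[seq_len(n_planted)],
                            target = labels[n_seeds + seq_len(n_planted)],
                            delta = delta)
  spec <- cohort_spec(n_per_group = n_per_group, n_timepoints = n_timepoints,
                      roi_labels = labels, planted_effects = planted,
                      master_seed = master_seed, ...)
  attr(spec, "seeds") <- labels[seq_len(n_seeds)]
  spec
}
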