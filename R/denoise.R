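#' Denoising configuration
#'
#' Settings for the temporal denoising chain: motion/global-signal outlier
#' detection, nuisance regression with scrubbing regressors, then linear
#' detrending and ideal band-pass filtering.
#'
#' @param band Pass-band in Hz, `c(low, high)`. Default `c(0.008, 0.09)`.
#' @param fd_threshold Framewise-displacement threshold in mm for flagging a
#'   volume. Default 0.9.
#' @param global_z_threshold Threshold on the z-scored mean-signal change for
#'   flagging a volume. Default 5.
#' @param rotation_radius Radius in mm converting rotation changes to a
#'   displacement on the head surface (small-angle approximation). Default 50.
#' @param include_motion_derivatives Add first differences of the 6 motion
#'   parameters to the design. Default TRUE.
#' @param n_nuisance_components Number of nuisance component regressors used.
#'   Default 10.
#' @return A list of class `denoise_config`.
#' @export
denoise_config <- function(band = c(0.008, 0.09), fd_threshold = 0.9,
                           global_z_threshold = 5, rotation_radius = 50,
                           include_motion_derivatives = TRUE,
                           n_nuisance_components = 10) {
  stopifnot(length(band) == 2, band[1] >= 0, band[1] < band[2],
            fd_threshold > 0, global_z_threshold > 0, rotation_radius > 0)
  structure(list(band = band, fd_threshold = fd_threshold,
                 global_z_threshold = global_z_threshold,
                 rotation_radius = rotation_radius,
                 include_motion_derivatives = include_motion_derivatives,
                 n_nuisance_components = as.integer(n_nuisance_components)),
            class = "denoise_config")
}

#' Framewise displacement from 6 motion parameters
#'
#' FD(t) = sum of absolute frame-to-frame changes of the three translations
#' (mm) plus `rotation_radius` times the sum of absolute changes of the three
#' rotations (rad), i.e. rotations are converted to arc displacement on a
#' sphere of the given radius. FD(1) = 0 by convention.
#'
#' @param motion T x 6 table or matrix, columns in
#'   (trans_x, trans_y, trans_z, rot_x, rot_y, rot_z) order.
#' @param rotation_radius Radius in mm. Default 50.
#' @return Numeric vector of length T, in mm.
#' @export
framewise_displacement <- function(motion, rotation_radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6)
    abort("Motion table must have exactly 6 columns (3 translations, 3 rotations).",
          class = "roinet_format_error")
  d <- abs(apply(m, 2, function(col) c(0, diff(col))))
  rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Flag motion/global-signal outlier volumes
#'
#' A volume is flagged when its framewise displacement exceeds
#' `cfg$fd_threshold` or when the absolute z-score of its mean-over-ROIs
#' signal change exceeds `cfg$global_z_threshold` (an ROI-level analogue of
#' artifact-detection outlier scanning).
#'
#' @param ts T x N ROI time-series table.
#' @param motion T x 6 motion-parameter table.
#' @param cfg A [denoise_config()].
#' @return Logical vector of length T with attribute `n_outliers`.
#' @export
detect_outliers <- function(ts, motion, cfg = denoise_config()) {
  x <- as.matrix(ts)
  if (nrow(x) != nrow(as.matrix(motion)))
    abort("Time series and motion table must have the same number of rows.")
  fd <- framewise_displacement(motion, cfg$rotation_radius)
  g <- rowMeans(x)
  dg <- c(0, diff(g))
  s <- sd(dg)
  z <- if (s > 0) (dg - mean(dg)) / s else dg * 0
  flags <- fd > cfg$fd_threshold | abs(z) > cfg$global_z_threshold
  structure(flags, n_outliers = sum(flags))
}

#' Regress nuisance signals out of ROI time series
#'
#' Replaces every ROI series by its least-squares residual against a design
#' holding an intercept, the 6 motion parameters, their first differences
#' (optional), the first `n_nuisance_components` nuisance component series,
#' and one indicator column per flagged volume (scrubbing without deletion,
#' which keeps the series length intact for spectral filtering). Residuals
#' are orthogonal to every retained design column; flagged volumes have
#' residual exactly zero.
#'
#' @param ts T x N ROI time-series table.
#' @param confounds A `confound_set` (tibbles `motion`, `nuisance`).
#' @param cfg A [denoise_config()].
#' @param outlier_flags Logical vector of flagged volumes; default none.
#' @return T x N tibble of residuals, with attribute `dropped_columns`.
#' @export
regress_confounds <- function(ts, confounds, cfg = denoise_config(),
                              outlier_flags = NULL) {
  y <- as.matrix(ts)
  tt <- nrow(y)
  motion <- as.matrix(confounds$motion)
  comps <- as.matrix(confounds$nuisance)
  k <- min(cfg$n_nuisance_components, ncol(comps))
  comps <- comps[, seq_len(k), drop = FALSE]
  X <- cbind(intercept = 1, motion)
  if (isTRUE(cfg$include_motion_derivatives)) {
    dmot <- apply(motion, 2, function(col) c(0, diff(col)))
    colnames(dmot) <- paste0("d_", colnames(motion))
    X <- cbind(X, dmot)
  }
  X <- cbind(X, comps)
  if (!is.null(outlier_flags) && any(outlier_flags)) {
    idx <- which(outlier_flags)
    scrub <- matrix(0, tt, length(idx),
                    dimnames = list(NULL, paste0("scrub_", idx)))
    scrub[cbind(idx, seq_along(idx))] <- 1
    X <- cbind(X, scrub)
  }
  if (tt <= ncol(X))
    abort(sprintf("Design has %d columns but only %d timepoints.", ncol(X), tt))
  qrx <- qr(X)
  dropped <- character()
  if (qrx$rank < ncol(X)) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warn(sprintf("Design is rank deficient; dropping dependent column(s): %s",
                 paste(dropped, collapse = ", ")))
    qrx <- qr(X[, keep, drop = FALSE])
  }
  res <- qr.resid(qrx, y)
  out <- tibble::as_tibble(res)
  attr(out, "dropped_columns") <- dropped
  out
}

#' Linear detrending plus ideal band-pass filtering
#'
#' Per ROI: subtracts the least-squares linear trend, then applies a
#' rectangular frequency-domain band-pass that retains exactly the discrete
#' frequency bins f with `low <= f <= high` (inclusive at both edges) and
#' zeroes all others, including the DC bin when `low > 0`. The spectral mask
#' is linear and idempotent (applying it twice equals applying it once);
#' `detrend = FALSE` applies the mask alone.
#'
#' @param ts T x N ROI time-series table.
#' @param tr Repetition time in seconds.
#' @param cfg A [denoise_config()] (its `band` is used).
#' @param detrend Remove the linear trend before filtering. Default TRUE.
#' @return T x N tibble of filtered series.
#' @export
bandpass_detrend <- function(ts, tr, cfg = denoise_config(), detrend = TRUE) {
  y <- as.matrix(ts)
  tt <- nrow(y)
  nyquist <- 1 / (2 * tr)
  band <- cfg$band
  if (band[2] > nyquist)
    abort(sprintf("Band upper edge %.4f Hz exceeds Nyquist %.4f Hz at TR %.2f s.",
                  band[2], nyquist, tr))
  if (isTRUE(detrend)) {
    t_idx <- seq_len(tt)
    y <- qr.resid(qr(cbind(1, t_idx)), y)
  }
  # rectangular spectral mask, symmetric over positive/negative frequencies
  freq <- (seq_len(tt) - 1) / (tt * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  yf <- mvfft(y)
  yf[!keep, ] <- 0
  out <- Re(mvfft(yf, inverse = TRUE)) / tt
  colnames(out) <- colnames(ts)
  tibble::as_tibble(out)
}

#' Denoise one subject's ROI time series
#'
#' Runs the full temporal denoising chain in a fixed order: outlier
#' detection, nuisance regression (motion + derivatives + nuisance
#' components + scrubbing regressors), then linear detrending and band-pass
#' filtering.
#'
#' @inheritParams regress_confounds
#' @param tr Repetition time in seconds.
#' @return A list with `ts` (the denoised T x N tibble) and `report`
#'   (stages run, outlier indices and count, dropped design columns, band).
#' @export
denoise_subject <- function(ts, confounds, tr, cfg = denoise_config()) {
  flags <- detect_outliers(ts, confounds$motion, cfg)
  res <- regress_confounds(ts, confounds, cfg, outlier_flags = flags)
  out <- bandpass_detrend(res, tr, cfg)
  list(ts = out,
       report = list(
         stages = c("detect_outliers", "regress_confounds", "bandpass_detrend"),
         n_outliers = attr(flags, "n_outliers"),
         outlier_index = which(flags),
         dropped_columns = attr(res, "dropped_columns"),
         band = cfg$band))
}

#' Denoise every subject of a cohort
#'
#' @param cohort A `roi_cohort` tibble (see [simulate_cohort()]) or any tibble
#'   with list-columns `series`, `confounds` and a `tr` column.
#' @param cfg A [denoise_config()].
#' @return The cohort tibble with `series` replaced by denoised series and a
#'   new list-column `denoise_report`.
#' @export
denoise_cohort <- function(cohort, cfg = denoise_config()) {
  den <- purrr::pmap(list(cohort$series, cohort$confounds, cohort$tr),
                     function(s, cf, tr) denoise_subject(s, cf, tr, cfg))
  cohort$series <- purrr::map(den, "ts")
  cohort$denoise_report <- purrr::map(den, "report")
  cohort
}
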