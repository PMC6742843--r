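new_conn_matrix <- function(values, kind, scale, roi_labels) {
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, kind = kind, scale = scale,
                 roi_labels = roi_labels),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> kind = %s, scale = %s, %d ROIs\n",
              x$kind, x$scale, length(x$roi_labels)))
  nc <- attr(x, "n_clipped")
  if (!is.null(nc) && nc > 0) cat(sprintf("  %d value(s) clipped before arctanh\n", nc))
  invisible(x)
}

#' Functional connectivity (ROI-ROI Pearson correlation)
#'
#' Entry (i, j) is the Pearson correlation between the series of ROI i and
#' ROI j; the matrix is symmetric and the diagonal is masked as `NA`.
#' Constant-valued ROIs yield undefined entries (`NA`, with a warning) which
#' downstream steps exclude.
#'
#' @param ts T x N ROI time-series table (T >= 3).
#' @return A `conn_matrix` with `kind = "FUN"`, `scale = "r"`.
#' @export
functional_connectivity <- function(ts) {
  x <- as.matrix(ts)
  if (nrow(x) < 3) abort("At least 3 timepoints are required.")
  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    warn(paste0("Constant ROI series; correlations set to NA: ",
                paste(colnames(x)[const], collapse = ", ")))
    x[, const] <- NA_real_
  }
  r <- suppressWarnings(cor(x))
  diag(r) <- NA_real_
  new_conn_matrix(r, "FUN", "r", colnames(x))
}

#' Effective-like connectivity (ROI-ROI bivariate regression slope)
#'
#' Entry (i, j) is the least-squares slope of regressing the target ROI j's
#' series on the seed ROI i's series (with intercept):
#' `b(i -> j) = cov(i, j) / var(i)`. Rows index the seed/predictor, columns
#' the target, so the matrix is asymmetric in general. Series are
#' deliberately not variance-normalised first — otherwise the slope
#' degenerates to the correlation and the asymmetry vanishes. A zero-variance
#' seed yields an undefined (`NA`) row.
#'
#' @param ts T x N ROI time-series table (T >= 3).
#' @return A `conn_matrix` with `kind = "EFF"`, `scale = "b"`.
#' @export
effective_connectivity <- function(ts) {
  x <- as.matrix(ts)
  if (nrow(x) < 3) abort("At least 3 timepoints are required.")
  C <- cov(x)
  v <- diag(C)
  if (any(v == 0)) {
    warn(paste0("Zero-variance seed ROI; slopes set to NA: ",
                paste(colnames(x)[v == 0], collapse = ", ")))
    v[v == 0] <- NA_real_
  }
  b <- C / v  # row i divided by var(i): b[i, j] = cov(i, j) / var(i)
  diag(b) <- NA_real_
  new_conn_matrix(b, "EFF", "b", colnames(x))
}

#' Fisher z-transformation of a connectivity matrix
#'
#' Applies `atanh` after clipping values into `[-clip, clip]`; the transform
#' is monotone and sign-preserving with z(0) = 0. Clipping makes the
#' transform well-defined for regression slopes with |b| >= 1; the number of
#' clipped entries is recorded in attribute `n_clipped` (and reported when
#' positive).
#'
#' @param cm A `conn_matrix` on the r/b scale.
#' @param clip Clipping bound, default `1 - 1e-6`.
#' @return A `conn_matrix` with `scale = "z"`.
#' @export
fisher_z <- function(cm, clip = 1 - 1e-6) {
  stopifnot(inherits(cm, "conn_matrix"))
  v <- cm$values
  clipped <- sum(abs(v) > clip, na.rm = TRUE)
  z <- atanh(pmin(pmax(v, -clip), clip))
  out <- new_conn_matrix(z, cm$kind, "z", cm$roi_labels)
  attr(out, "n_clipped") <- clipped
  if (clipped > 0)
    inform(sprintf("fisher_z: clipped %d value(s) with |v| > %g before arctanh.",
                   clipped, clip))
  out
}

#' @exportS3Method generics::tidy
tidy.conn_matrix <- function(x, ...) {
  v <- x$values
  ij <- which(row(v) != col(v), arr.ind = TRUE)
  if (x$kind == "FUN") ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tibble::tibble(
    seed = x$roi_labels[ij[, 1]],
    target = x$roi_labels[ij[, 2]],
    value = v[ij],
    kind = x$kind,
    scale = x$scale
  )
}

#' Heat-map of a connectivity matrix
#'
#' @param object A `conn_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conn_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(seed = object$roi_labels, target = object$roi_labels)
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$target, levels = object$roi_labels),
    y = factor(.data$seed, levels = rev(object$roi_labels)),
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = "target ROI", y = "seed ROI",
                  fill = paste0(object$kind, " (", object$scale, ")")) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
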