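# Vectorized pooled two-sample t over the columns of two matrices
# (rows = subjects). Degenerate rules: zero pooled variance with equal means
# -> t = 0, p = 1; with unequal means -> t = +/-Inf, p = 0.
pooled_t_cols <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(sweep(X1, 2, m1)^2)
  ss2 <- colSums(sweep(X2, 2, m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se,
              ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  list(t = t, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Pooled-variance two-sample t-test
#'
#' Classical pooled two-sample t (equivalent to the [1, -1] contrast of a
#' two-group general linear model), with sign convention group1 minus group2.
#' Non-finite observations are dropped (with a note of the count). Zero
#' pooled variance with equal means gives t = 0, p = 1; with unequal means
#' an infinite-t row with p at its 0 limit.
#'
#' @param x,y Numeric vectors for group 1 and group 2 (each >= 2 finite
#'   values).
#' @return One-row tibble: `t`, `df`, `p`, `mean1`, `mean2`, `n1`, `n2`,
#'   `n_dropped`.
#' @export
two_sample_t <- function(x, y) {
  x0 <- x[is.finite(x)]; y0 <- y[is.finite(y)]
  dropped <- (length(x) - length(x0)) + (length(y) - length(y0))
  if (length(x0) < 2 || length(y0) < 2)
    abort("Each group needs at least 2 finite values.")
  r <- pooled_t_cols(matrix(x0, ncol = 1), matrix(y0, ncol = 1))
  tibble::tibble(t = r$t, df = r$df, p = r$p, mean1 = r$mean1, mean2 = r$mean2,
                 n1 = length(x0), n2 = length(y0), n_dropped = dropped)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `adj(i) = min_{j >= i} (p_(j) * m / j)` on the sorted p-values, capped at
#' 1 and mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Seed restriction for edge-wise testing
#'
#' Restricts edge-wise comparisons to connections between a set of seed ROIs
#' and all other ROIs (no self-pairs; a seed-seed pair is tested once). With
#' no arguments the default is the reference 132-label set with the
#' basal-ganglia + thalamus + cerebellum seeds (8 + 2 + 26 ROIs).
#'
#' @param roi_labels All ROI labels. Default: the 132-label reference set.
#' @param seeds Seed ROI labels (subset of `roi_labels`). Default: the 36
#'   subcortical/cerebellar seed ROIs of the reference set.
#' @param fdr_scope `"all_tested_pairs"` (BH across every tested connection
#'   jointly, default) or `"per_seed"` (BH within each seed's connections).
#' @return A list of class `seed_restriction`.
#' @export
seed_restriction <- function(roi_labels = NULL, seeds = NULL,
                             fdr_scope = c("all_tested_pairs", "per_seed")) {
  fdr_scope <- match.arg(fdr_scope)
  if (is.null(roi_labels)) {
    ls <- roi_label_set()
    roi_labels <- ls$all
    if (is.null(seeds)) seeds <- unique(unlist(ls$seed_subsets))
  }
  if (is.null(seeds)) seeds <- roi_labels
  if (!all(seeds %in% roi_labels))
    abort("All seeds must appear in roi_labels.")
  structure(list(roi_labels = roi_labels, seeds = seeds,
                 fdr_scope = fdr_scope),
            class = "seed_restriction")
}

#' Enumerate the connections tested under a seed restriction
#'
#' For symmetric (FUN) matrices each unordered seed-other pair is tested
#' once (seed-seed pairs are not double counted); for asymmetric (EFF)
#' matrices both directions of every such pair are tested.
#'
#' @param restriction A [seed_restriction()].
#' @param kind `"FUN"` or `"EFF"`.
#' @return Tibble with columns `seed`, `target`.
#' @export
tested_pairs <- function(restriction, kind = c("FUN", "EFF")) {
  kind <- match.arg(kind)
  labels <- restriction$roi_labels
  seeds <- restriction$seeds
  df <- tidyr::expand_grid(seed = seeds, target = labels) |>
    dplyr::filter(.data$seed != .data$target)
  if (kind == "FUN") {
    # drop the duplicate orientation of seed-seed pairs
    i <- match(df$seed, labels); j <- match(df$target, labels)
    dup <- df$target %in% seeds & i > j
    df <- df[!dup, ]
  } else {
    # both directions of every seed-other pair; seed-seed pairs already
    # appear in both orientations
    rev_df <- df |> dplyr::filter(!(.data$target %in% seeds))
    rev_df <- tibble::tibble(seed = rev_df$target, target = rev_df$seed)
    df <- dplyr::bind_rows(df, rev_df)
  }
  df
}

new_group_stats <- function(df, level = "edge", kind = NULL, q = 0.05,
                            scope = "all_tested_pairs", metric = NULL,
                            n_excluded = 0L) {
  structure(df, class = c("group_stats", class(df)), level = level,
            kind = kind, q = q, fdr_scope = scope, metric = metric,
            n_excluded = n_excluded)
}

#' Edge-wise two-group comparison of connectivity
#'
#' For every tested connection, runs a pooled two-sample t-test on the
#' subjects' Fisher-z values (sign convention: patients minus controls, i.e.
#' a [1, -1] group contrast) and applies Benjamini-Hochberg FDR correction
#' over the scope given by the restriction; a connection is significant when
#' its adjusted p-value is below `q`.
#'
#' @param data Tibble with columns `subject_id`, `group` and a list-column
#'   `z` of `conn_matrix` objects on the z scale (all sharing labels and
#'   kind).
#' @param restriction A [seed_restriction()]; default tests every pair among
#'   the matrices' labels.
#' @param q FDR level, default 0.05.
#' @param group_levels Length-2 character: which group is "group 1" (first)
#'   and "group 2". Default `c("patient", "control")` when present.
#' @return A `group_stats` tibble: `seed`, `target`, `mean_patient`,
#'   `mean_control` (named after the group levels), `t`, `df`, `p`, `p_fdr`,
#'   `significant`.
#' @export
edgewise_group_comparison <- function(data, restriction = NULL, q = 0.05,
                                      group_levels = NULL) {
  stopifnot(all(c("group", "z") %in% names(data)))
  mats <- data$z
  kind <- mats[[1]]$kind
  labels <- mats[[1]]$roi_labels
  ok <- vapply(mats, function(m) identical(m$roi_labels, labels) &&
                 identical(m$kind, kind), logical(1))
  if (!all(ok)) abort("All subjects must share ROI labels and matrix kind.")
  if (is.null(group_levels)) {
    gl <- unique(data$group)
    if (length(gl) != 2) abort("Exactly two groups are required.")
    group_levels <- if (all(c("patient", "control") %in% gl))
      c("patient", "control") else sort(gl)
  }
  if (is.null(restriction)) restriction <- seed_restriction(labels, labels)
  if (!all(restriction$roi_labels == labels))
    abort("Restriction labels do not match the matrices' ROI labels.")
  pairs <- tested_pairs(restriction, kind)
  i <- match(pairs$seed, labels); j <- match(pairs$target, labels)
  idx <- cbind(i, j)
  V <- t(vapply(mats, function(m) m$values[idx], numeric(nrow(idx))))
  g1 <- data$group == group_levels[1]
  g2 <- data$group == group_levels[2]
  r <- pooled_t_cols(V[g1, , drop = FALSE], V[g2, , drop = FALSE])
  out <- tibble::tibble(seed = pairs$seed, target = pairs$target,
                        mean1 = r$mean1, mean2 = r$mean2,
                        t = r$t, df = r$df, p = r$p)
  names(out)[names(out) == "mean1"] <- paste0("mean_", group_levels[1])
  names(out)[names(out) == "mean2"] <- paste0("mean_", group_levels[2])
  if (restriction$fdr_scope == "per_seed") {
    out$p_fdr <- stats::ave(out$p, out$seed, FUN = bh_fdr)
  } else {
    out$p_fdr <- bh_fdr(out$p)
  }
  out$significant <- out$p_fdr < q
  new_group_stats(out, level = "edge", kind = kind, q = q,
                  scope = restriction$fdr_scope)
}

#' Node-wise two-group comparison of a topology metric
#'
#' Per node, a pooled two-sample t-test between groups on one of the seven
#' node metrics, BH-corrected across the nodes within that metric.
#' Undefined values (e.g. average path length of an isolated node) are
#' excluded per node; a node with fewer than 2 defined values in either
#' group is excluded from testing entirely (count recorded in attribute
#' `n_excluded`).
#'
#' @param data Tibble with columns `subject_id`, `group` and a list-column
#'   `metrics` of [node_metrics()] tibbles.
#' @param metric One of `"degree"`, `"cost"`, `"betweenness"`,
#'   `"path_length"`, `"global_efficiency"`, `"local_efficiency"`,
#'   `"clustering"`.
#' @inheritParams edgewise_group_comparison
#' @return A `group_stats` tibble with one row per tested node.
#' @export
nodewise_metric_comparison <- function(data, metric, q = 0.05,
                                       group_levels = NULL) {
  stopifnot(all(c("group", "metrics") %in% names(data)))
  metric <- match.arg(metric, .metric_names)
  labels <- data$metrics[[1]]$roi
  if (is.null(group_levels)) {
    gl <- unique(data$group)
    if (length(gl) != 2) abort("Exactly two groups are required.")
    group_levels <- if (all(c("patient", "control") %in% gl))
      c("patient", "control") else sort(gl)
  }
  M <- t(vapply(data$metrics, function(m) {
    if (!identical(m$roi, labels)) abort("All subjects must share ROI labels.")
    as.numeric(m[[metric]])
  }, numeric(length(labels))))
  g1 <- data$group == group_levels[1]
  g2 <- data$group == group_levels[2]
  rows <- lapply(seq_along(labels), function(jj) {
    x <- M[g1, jj]; y <- M[g2, jj]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    r <- pooled_t_cols(matrix(x, ncol = 1), matrix(y, ncol = 1))
    tibble::tibble(node = labels[jj], mean1 = r$mean1, mean2 = r$mean2,
                   t = r$t, df = r$df, p = r$p)
  })
  n_excluded <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    names(out)[names(out) == "mean1"] <- paste0("mean_", group_levels[1])
    names(out)[names(out) == "mean2"] <- paste0("mean_", group_levels[2])
    out$metric <- metric
    out$p_fdr <- bh_fdr(out$p)
    out$significant <- out$p_fdr < q
  }
  new_group_stats(out, level = "node", q = q, metric = metric,
                  n_excluded = n_excluded)
}

#' @exportS3Method generics::tidy
tidy.group_stats <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "group_stats")
  tibble::as_tibble(out)
}

#' @exportS3Method generics::glance
glance.group_stats <- function(x, ...) {
  tibble::tibble(
    level = attr(x, "level"),
    kind = attr(x, "kind") %||% NA_character_,
    metric = attr(x, "metric") %||% NA_character_,
    q = attr(x, "q"),
    n_tested = nrow(x),
    n_significant = sum(x$significant),
    n_sig_positive = sum(x$significant & x$t > 0),
    n_sig_negative = sum(x$significant & x$t < 0),
    n_excluded = attr(x, "n_excluded") %||% 0L
  )
}

#' Volcano-style plot of a group comparison
#'
#' @param object A `group_stats` table.
#' @param ... Unused.
#' @return A ggplot object: t statistic vs -log10 adjusted p, significant
#'   rows highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.group_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = -log10(.data$p_fdr),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "t (group 1 - group 2)",
                  y = expression(-log[10] ~ "p-FDR"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}
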