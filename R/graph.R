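#' Graph construction configuration
#'
#' @param threshold Absolute Fisher-z threshold tau; an edge requires
#'   `|z| > tau` (strict inequality, so a value exactly at tau gives no
#'   edge). Default 0.4 — strong connections only.
#' @param eff_symmetrization How a directed (EFF) pass pattern is collapsed
#'   to an undirected graph: `"OR"` (edge if either direction passes,
#'   default), `"AND"`, or `"mean"` (threshold the mean of |z| in both
#'   directions).
#' @param betweenness_normalization `"normalized"` (divide by
#'   (N-1)(N-2)/2, default) or `"raw"`.
#' @return A list of class `graph_config`.
#' @export
graph_config <- function(threshold = 0.4,
                         eff_symmetrization = c("OR", "AND", "mean"),
                         betweenness_normalization = c("normalized", "raw")) {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold,
                 eff_symmetrization = match.arg(eff_symmetrization),
                 betweenness_normalization = match.arg(betweenness_normalization)),
            class = "graph_config")
}

new_subject_graph <- function(A, roi_labels) {
  dimnames(A) <- list(roi_labels, roi_labels)
  structure(list(adjacency = A, roi_labels = roi_labels),
            class = "subject_graph")
}

#' @export
print.subject_graph <- function(x, ...) {
  cat(sprintf("<subject_graph> %d nodes, %d edges\n",
              length(x$roi_labels), sum(x$adjacency) / 2))
  invisible(x)
}

#' Threshold and binarize a Fisher-z connectivity matrix
#'
#' Builds an undirected binary graph keeping only strong connections:
#' an edge between i and j requires `|z| > tau`, so strong anticorrelations
#' count the same as strong correlations. For asymmetric (EFF) matrices the
#' directed pass pattern is first computed per direction and then symmetrized
#' per `cfg$eff_symmetrization`. Undefined (`NA`) entries never produce an
#' edge; the diagonal is always zero.
#'
#' @param cm A `conn_matrix` (z scale recommended).
#' @param cfg A [graph_config()].
#' @return A `subject_graph` with binary symmetric adjacency.
#' @export
threshold_binarize <- function(cm, cfg = graph_config()) {
  stopifnot(inherits(cm, "conn_matrix"))
  z <- cm$values
  z[is.na(z)] <- 0
  tau <- cfg$threshold
  if (cm$kind == "EFF") {
    p <- abs(z) > tau
    A <- switch(cfg$eff_symmetrization,
                OR = p | t(p),
                AND = p & t(p),
                mean = (abs(z) + t(abs(z))) / 2 > tau)
  } else {
    A <- abs(z) > tau
  }
  # every symmetrization rule yields a symmetric pattern already; coerce 0/1
  A <- matrix(as.integer(A), nrow(A), ncol(A))
  diag(A) <- 0L
  new_subject_graph(A, cm$roi_labels)
}

#' Shortest-path lengths and geodesic counts of a binary graph
#'
#' Breadth-first search from every node. `d[i, j]` is the unweighted
#' shortest-path length (0 on the diagonal, `Inf` for disconnected pairs);
#' `sigma[i, j]` counts the distinct shortest paths (0 when disconnected).
#'
#' @param graph A `subject_graph`.
#' @return List with matrices `d` and `sigma`.
#' @export
shortest_path_stats <- function(graph) {
  A <- graph$adjacency
  n <- nrow(A)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    cnt <- numeric(n); cnt[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nb[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
            cnt[w] <- cnt[w] + cnt[v]
          } else if (dist[w] == dist[v] + 1) {
            cnt[w] <- cnt[w] + cnt[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
    sigma[s, ] <- cnt
  }
  diag(sigma) <- 1
  list(d = d, sigma = sigma)
}

# Brandes dependency accumulation for betweenness centrality.
brandes_betweenness <- function(A) {
  n <- nrow(A)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier) > 0) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nb[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # each unordered pair (s, t) counted from both endpoints
}

#' Node centrality measures: degree, cost, betweenness
#'
#' Degree is the number of direct neighbours; cost is the proportion of
#' possible neighbours, degree / (N - 1); betweenness centrality is the sum
#' over node pairs (s, t) of the fraction of s-t geodesics passing through
#' the node (Brandes accumulation), divided by (N-1)(N-2)/2 when normalized.
#' With fewer than 3 nodes betweenness is 0.
#'
#' @param graph A `subject_graph`.
#' @param cfg A [graph_config()].
#' @return Tibble with columns `roi`, `degree`, `cost`, `betweenness`.
#' @export
node_centralities <- function(graph, cfg = graph_config()) {
  A <- graph$adjacency
  n <- nrow(A)
  k <- unname(rowSums(A))
  cost <- if (n > 1) k / (n - 1) else rep(0, n)
  if (n < 3) {
    bc <- rep(0, n)
  } else {
    bc <- brandes_betweenness(A)
    if (cfg$betweenness_normalization == "normalized")
      bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  tibble::tibble(roi = graph$roi_labels, degree = as.integer(k),
                 cost = cost, betweenness = bc)
}

#' Node integration measures: average path length and global efficiency
#'
#' `path_length(i)` is the mean geodesic distance from i to the nodes
#' reachable from i (`NA` for an isolated node, which downstream statistics
#' exclude); `global_efficiency(i)` is the mean over all other nodes j of
#' `1 / d(i, j)`, with unreachable pairs contributing 0.
#'
#' @param graph A `subject_graph`.
#' @return Tibble with columns `roi`, `path_length`, `global_efficiency`.
#' @export
node_integration <- function(graph) {
  sp <- shortest_path_stats(graph)
  d <- sp$d
  n <- nrow(d)
  L <- rep(NA_real_, n)
  eglob <- numeric(n)
  for (i in seq_len(n)) {
    dij <- d[i, -i]
    reach <- is.finite(dij)
    if (any(reach)) L[i] <- mean(dij[reach])
    if (n > 1) eglob[i] <- mean(ifelse(is.finite(dij), 1 / dij, 0))
  }
  tibble::tibble(roi = graph$roi_labels, path_length = L,
                 global_efficiency = eglob)
}

#' Node segregation measures: clustering coefficient and local efficiency
#'
#' `clustering(i)` is the proportion of pairs of i's neighbours that are
#' themselves connected; `local_efficiency(i)` is the global efficiency of
#' the subgraph induced by i's neighbours (i itself excluded): the mean over
#' ordered neighbour pairs of the inverse within-subgraph distance. Both are
#' 0 for nodes with fewer than 2 neighbours.
#'
#' @param graph A `subject_graph`.
#' @return Tibble with columns `roi`, `clustering`, `local_efficiency`.
#' @export
node_segregation <- function(graph) {
  A <- graph$adjacency
  n <- nrow(A)
  C <- numeric(n)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    e <- sum(sub) / 2
    C[i] <- 2 * e / (k * (k - 1))
    subg <- new_subject_graph(sub, as.character(nb))
    dsub <- shortest_path_stats(subg)$d
    inv <- 1 / dsub[row(dsub) != col(dsub)]
    eloc[i] <- mean(ifelse(is.finite(inv), inv, 0))
  }
  tibble::tibble(roi = graph$roi_labels, clustering = C,
                 local_efficiency = eloc)
}

#' All seven node-level topology metrics of a binary graph
#'
#' Joins [node_centralities()], [node_integration()] and
#' [node_segregation()]: degree, cost, betweenness, average path length,
#' global efficiency, local efficiency and clustering coefficient per node.
#'
#' @param graph A `subject_graph`.
#' @param cfg A [graph_config()].
#' @return Tibble with one row per ROI and the 7 metric columns.
#' @export
node_metrics <- function(graph, cfg = graph_config()) {
  node_centralities(graph, cfg) |>
    dplyr::left_join(node_integration(graph), by = "roi") |>
    dplyr::left_join(node_segregation(graph), by = "roi")
}

.metric_names <- c("degree", "cost", "betweenness", "path_length",
                   "global_efficiency", "local_efficiency", "clustering")
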