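# Brute-force graph oracle, deliberately independent of the package's
# BFS/Brandes implementation: Floyd-Warshall distances plus explicit
# enumeration of every geodesic by depth-first search.

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# all simple paths from s to t with length exactly d[s, t]
oracle_geodesics <- function(A, s, t, len) {
  if (!is.finite(len)) return(list())
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      if (length(path) - 1 == len) out[[length(out) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= len) return(invisible())
    for (w in which(A[v, ] == 1)) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  out
}

oracle_sigma_bc <- function(A, normalized = TRUE) {
  n <- nrow(A)
  d <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  bc <- numeric(n)
  if (n >= 2) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      paths <- oracle_geodesics(A, s, t, d[s, t])
      sigma[s, t] <- sigma[t, s] <- length(paths)
      if (length(paths) > 0 && n >= 3) {
        inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
        if (length(inner) > 0) {
          tab <- table(inner)
          idx <- as.integer(names(tab))
          bc[idx] <- bc[idx] + as.numeric(tab) / length(paths)
        }
      }
    }
  }
  if (normalized && n >= 3) bc <- bc / ((n - 1) * (n - 2) / 2)
  list(d = d, sigma = sigma, bc = bc)
}

oracle_node_metrics <- function(A, normalized = TRUE) {
  n <- nrow(A)
  ob <- oracle_sigma_bc(A, normalized)
  d <- ob$d
  k <- rowSums(A)
  cost <- if (n > 1) k / (n - 1) else rep(0, n)
  L <- rep(NA_real_, n)
  eglob <- numeric(n)
  C <- numeric(n)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    if (n > 1) {
      dij <- d[i, -i]
      if (any(is.finite(dij))) L[i] <- mean(dij[is.finite(dij)])
      eglob[i] <- mean(ifelse(is.finite(dij), 1 / dij, 0))
    }
    nb <- which(A[i, ] == 1)
    if (length(nb) >= 2) {
      sub <- A[nb, nb, drop = FALSE]
      C[i] <- sum(sub) / (length(nb) * (length(nb) - 1))
      dsub <- oracle_distances(sub)
      off <- dsub[row(dsub) != col(dsub)]
      eloc[i] <- mean(ifelse(is.finite(off), 1 / off, 0))
    }
  }
  list(degree = k, cost = cost, betweenness = ob$bc, path_length = L,
       global_efficiency = eglob, local_efficiency = eloc, clustering = C,
       d = d, sigma = ob$sigma)
}

# adjacency from an integer bitmask over the upper triangle
graph_from_mask <- function(n, mask) {
  A <- matrix(0L, n, n)
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(mask))[seq_len(m)]
  A[upper.tri(A)] <- bits
  A + t(A)
}

all_labeled_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(0:(2^m - 1), function(mask) graph_from_mask(n, mask))
}

random_graph <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

as_graph <- function(A) {
  roinet:::new_subject_graph(A, sprintf("n%02d", seq_len(nrow(A))))
}

expect_metrics_match_oracle <- function(A, tol = 1e-10) {
  g <- as_graph(A)
  o <- oracle_node_metrics(A)
  sp <- shortest_path_stats(g)
  expect_equal(sp$d, o$d, tolerance = tol, ignore_attr = TRUE)
  expect_equal(sp$sigma, o$sigma, tolerance = tol, ignore_attr = TRUE)
  m <- node_metrics(g)
  expect_equal(as.numeric(m$degree), as.numeric(o$degree), tolerance = tol)
  expect_equal(m$cost, o$cost, tolerance = tol)
  expect_equal(m$betweenness, o$betweenness, tolerance = tol)
  expect_equal(m$path_length, o$path_length, tolerance = tol)
  expect_equal(m$global_efficiency, o$global_efficiency, tolerance = tol)
  expect_equal(m$local_efficiency, o$local_efficiency, tolerance = tol)
  expect_equal(m$clustering, o$clustering, tolerance = tol)
}
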