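# Shared fixture builders for the test suite.

# a spec with every nuisance source switched off (pure covariance signal)
clean_spec <- function(n_rois = 8, n_timepoints = 220, n_per_group = 2,
                       ar_coef = 0, within_cor = 0.3, between_cor = 0.05,
                       master_seed = 1L, ...) {
  cohort_spec(
    n_per_group = n_per_group, n_timepoints = n_timepoints,
    n_rois = n_rois, ar_coef = ar_coef, within_cor = within_cor,
    between_cor = between_cor, master_seed = master_seed,
    nuisance = nuisance_spec(drift_amplitude = 0, sin_amplitude = 0,
                             spike_times = integer(), motion_scale = 0,
                             loading_sd = 0), ...)
}

# canonical small graphs used across graph tests
graph_k4 <- function() as_graph(matrix(1L, 4, 4) - diag(1L, 4))
graph_star4 <- function() {
  A <- matrix(0L, 4, 4); A[1, 2:4] <- 1L; A[2:4, 1] <- 1L
  as_graph(A)  # node 1 is the hub
}
graph_cycle <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- 1L
  }
  as_graph(A)
}
graph_path3 <- function() {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  as_graph(A)
}

# conn_matrix straight from numbers (z scale unless stated)
zmat <- function(values, kind = "FUN", labels = NULL) {
  n <- nrow(values)
  labels <- labels %||% sprintf("r%02d", seq_len(n))
  m <- roinet:::new_conn_matrix(values, kind, "z", labels)
  m
}
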