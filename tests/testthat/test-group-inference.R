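test_that("pooled two-sample t matches its closed form and t.test", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # pooled: s2p = (2 + 2) / 4 = 1, se = sqrt(1 * (1/3 + 1/3)), t = -3 / se
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)

  # independent cross-check against the classical implementation
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rnorm(7); y <- rnorm(9, mean = 0.5)
      ours <- two_sample_t(x, y)
      ref <- stats::t.test(x, y, var.equal = TRUE)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$df, unname(ref$parameter))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  })

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- two_sample_t(c(0, 0), c(0, 0))
  expect_equal(degen$t, 0)
  expect_equal(degen$p, 1)

  degen2 <- two_sample_t(c(1, 1), c(0, 0))
  expect_true(is.infinite(degen2$t) && degen2$t > 0)
  expect_equal(degen2$p, 0)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order invariance
  p <- withr::with_seed(3, runif(50))
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # monotone in p
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("seed restriction enumerates the right connection count", {
  ls <- roi_label_set()
  restr <- seed_restriction()  # default: 132 labels, 36 seeds
  s <- length(unique(unlist(ls$seed_subsets)))
  expect_equal(s, 36)
  pairs <- tested_pairs(restr, "FUN")
  expect_equal(nrow(pairs), s * (132 - s) + choose(s, 2))
  key <- paste(pmin(pairs$seed, pairs$target), pmax(pairs$seed, pairs$target))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(pairs$seed != pairs$target))
  # EFF: both directions of every pair
  pairs_eff <- tested_pairs(restr, "EFF")
  expect_equal(nrow(pairs_eff), 2 * nrow(pairs))
})

make_z_cohort <- function(n_per_group, labels, mu = NULL, sd_z = 0.1,
                          seed = 1) {
  # subject z-matrices drawn directly around a group-level mean matrix
  n <- length(labels)
  base <- matrix(0, n, n)
  withr::with_seed(seed, {
    subjects <- purrr::map(seq_len(2 * n_per_group), function(s) {
      m <- base
      if (!is.null(mu) && s > n_per_group) m <- m + mu
      noise <- matrix(rnorm(n * n, sd = sd_z), n, n)
      noise <- (noise + t(noise)) / 2
      v <- m + noise
      diag(v) <- NA
      roinet:::new_conn_matrix(v, "FUN", "z", labels)
    })
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
      group = rep(c("control", "patient"), each = n_per_group),
      z = subjects)
  })
}

test_that("edgewise comparison flags planted shifts and respects q", {
  labels <- sprintf("r%02d", 1:8)
  mu <- matrix(0, 8, 8)
  mu[1, 5] <- mu[5, 1] <- 0.4  # strong shift on one edge
  dat <- make_z_cohort(15, labels, mu, seed = 10)
  st <- edgewise_group_comparison(dat, q = 0.05)
  expect_s3_class(st, "group_stats")
  expect_equal(nrow(st), choose(8, 2))
  hit <- st[st$seed == "r01" & st$target == "r05", ]
  expect_true(hit$significant)
  expect_gt(hit$t, 0)  # patients minus controls
  expect_true(all(st$p_fdr >= st$p - 1e-15))
  expect_true(all(st$significant == (st$p_fdr < 0.05)))

  # q = 0 retains nothing
  st0 <- edgewise_group_comparison(dat, q = 0)
  expect_equal(sum(st0$significant), 0)

  # swapping group labels negates every t exactly
  dat_swapped <- dat
  dat_swapped$group <- ifelse(dat$group == "control", "patient", "control")
  st_sw <- edgewise_group_comparison(dat_swapped, q = 0.05)
  expect_equal(st_sw$t, -st$t, tolerance = 1e-12)

  # label mismatch is a hard error
  bad <- dat
  bad$z[[3]] <- roinet:::new_conn_matrix(bad$z[[3]]$values, "FUN", "z",
                                         sprintf("x%02d", 1:8))
  expect_error(edgewise_group_comparison(bad), "share ROI labels")

  g <- glance(st)
  expect_equal(g$n_tested, choose(8, 2))
  expect_equal(g$n_significant, sum(st$significant))
})

test_that("BH keeps the false-discovery proportion controlled across replicates", {
  labels <- sprintf("r%02d", 1:10)
  # global null: mean FDP (= any-rejection rate here) stays near or below q
  fdp <- vapply(1:200, function(r) {
    dat <- make_z_cohort(10, labels, mu = NULL, seed = 100 + r)
    st <- edgewise_group_comparison(dat, q = 0.05)
    if (sum(st$significant) == 0) 0 else 1  # every rejection is false
  }, numeric(1))
  mc_se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * mc_se)

  # mean significant-edge count under the null is consistent with BH control
  counts <- vapply(1:20, function(r) {
    dat <- make_z_cohort(10, labels, mu = NULL, seed = 300 + r)
    sum(edgewise_group_comparison(dat, q = 0.05)$significant)
  }, numeric(1))
  expect_lte(mean(counts), 0.05 * choose(10, 2) * 1.5)
})

test_that("nodewise comparison detects a strengthened hub", {
  # planted hub: all edges of seed node gain delta -> degree/cost/Eglob rise
  hits <- vapply(1:20, function(r) {
    sp <- example_cohort_spec(n_rois = 16, n_seeds = 4, n_planted = 0,
                              delta = 0, n_per_group = 10, n_timepoints = 120,
                              master_seed = 700 + r)
    hub <- sp$roi_labels[1]
    sp$planted_effects <- tibble::tibble(
      seed = hub, target = setdiff(sp$roi_labels, hub), delta = 0.3)
    cohort <- simulate_cohort(sp)
    cohort <- denoise_cohort(cohort)
    mdat <- dplyr::mutate(
      cohort,
      metrics = purrr::map(series, function(s)
        node_metrics(threshold_binarize(suppressMessages(
          fisher_z(functional_connectivity(s)))))))
    res <- vapply(c("degree", "cost", "global_efficiency"), function(m) {
      st <- nodewise_metric_comparison(mdat, m)
      st$t[st$node == hub] > 0
    }, logical(1))
    all(res)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate nodewise inputs are handled per the conventions", {
  # identical groups (copied subjects) -> all t exactly 0
  m1 <- node_metrics(graph_star4())
  m2 <- node_metrics(graph_cycle(4))
  dat <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                        group = rep(c("control", "patient"), each = 3),
                        metrics = rep(list(m1, m2, m1), 2))
  st <- nodewise_metric_comparison(dat, "degree")
  expect_true(all(st$t == 0))
  expect_true(all(st$p == 1))

  # a node with undefined path length in one group is excluded
  iso <- matrix(0L, 4, 4)
  iso[1, 2] <- iso[2, 1] <- 1L   # nodes 3, 4 isolated -> path_length NA
  m_iso <- node_metrics(as_graph(iso))
  dat2 <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                         group = rep(c("control", "patient"), each = 3),
                         metrics = rep(list(m_iso), 6))
  st2 <- nodewise_metric_comparison(dat2, "path_length")
  expect_equal(nrow(st2), 2)  # only the connected nodes are testable
  expect_equal(attr(st2, "n_excluded"), 2)
})
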