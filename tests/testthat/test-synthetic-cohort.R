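test_that("ROI label set has the reference structure", {
  ls <- roi_label_set()
  expect_length(ls$cortical, 91)
  expect_length(ls$subcortical, 15)
  expect_length(ls$cerebellar, 26)
  expect_length(ls$all, 132)
  expect_false(anyDuplicated(ls$all) > 0)
  expect_length(ls$seed_subsets$basal_ganglia, 8)
  expect_length(ls$seed_subsets$thalamus, 2)
  expect_length(ls$seed_subsets$cerebellum, 26)
  expect_true(all(unlist(ls$seed_subsets) %in%
                    c(ls$subcortical, ls$cerebellar)))
  td <- tidy(ls)
  expect_equal(nrow(td), 132)
  expect_equal(sum(td$basal_ganglia), 8)
})

test_that("group covariance reproduces the requested structure", {
  # independence: zero base correlations, unit sd -> identity
  sp <- cohort_spec(n_rois = 5, within_cor = 0, between_cor = 0,
                    n_timepoints = 20, n_per_group = 2)
  expect_equal(unname(build_group_covariance(sp, "control")), diag(5),
               ignore_attr = TRUE)

  # 2-ROI block, r = 0.6: off-diagonals 0.6, eigenvalues 1 +/- 0.6
  sp2 <- cohort_spec(n_rois = 2, blocks = c(1, 1), within_cor = 0.6,
                     n_timepoints = 20, n_per_group = 2)
  S <- build_group_covariance(sp2, "control")
  expect_equal(S[1, 2], 0.6)
  expect_equal(sort(eigen(S)$values), c(0.4, 1.6))

  # planted delta touches exactly the 2 symmetric entries, patient only
  labels <- sprintf("roi_%02d", 1:6)
  sp3 <- cohort_spec(roi_labels = labels, within_cor = 0.2, between_cor = 0.2,
                     n_timepoints = 20, n_per_group = 2,
                     planted_effects = data.frame(seed = "roi_01",
                                                  target = "roi_04",
                                                  delta = 0.2))
  Sc <- build_group_covariance(sp3, "control")
  Sp <- build_group_covariance(sp3, "patient")
  diffs <- which(Sc != Sp, arr.ind = TRUE)
  expect_equal(nrow(diffs), 2)
  expect_equal(Sp[1, 4], 0.4)
  expect_equal(Sp[4, 1], 0.4)
})

test_that("invalid covariance requests are rejected", {
  expect_error(cohort_spec(n_rois = 4, within_cor = 1.2, n_timepoints = 20,
                           n_per_group = 2),
               class = "roinet_invalid_spec")
  # planted delta pushing a correlation out of (-1, 1)
  sp <- cohort_spec(n_rois = 4, within_cor = 0.9, between_cor = 0.9,
                    n_timepoints = 20, n_per_group = 2,
                    planted_effects = data.frame(seed = "roi_01",
                                                 target = "roi_02",
                                                 delta = 0.2))
  expect_error(build_group_covariance(sp, "patient"),
               class = "roinet_invalid_spec")
  # indefinite construction whose repair would distort correlations > 0.05
  sp2 <- cohort_spec(n_rois = 3, blocks = c(1, 1, 1), within_cor = 0.9,
                     n_timepoints = 20, n_per_group = 2,
                     planted_effects = data.frame(seed = "roi_02",
                                                  target = "roi_03",
                                                  delta = -1.8))
  expect_error(build_group_covariance(sp2, "patient"),
               class = "roinet_pd_repair_error")
  # planted ROI not in the label set
  expect_error(cohort_spec(n_rois = 3, n_timepoints = 20, n_per_group = 2,
                           planted_effects = data.frame(seed = "roi_01",
                                                        target = "nope",
                                                        delta = 0.1)),
               class = "roinet_invalid_spec")
})

test_that("simulated series recover the target correlation structure", {
  # iid case: every off-diagonal correlation within 3/sqrt(T) of zero
  sp <- clean_spec(n_rois = 6, n_timepoints = 10000, within_cor = 0,
                   between_cor = 0)
  S <- build_group_covariance(sp, "control")
  x <- as.matrix(simulate_subject(S, sp, 11))
  r <- cor(x)
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(10000))

  # planted 2-ROI correlation 0.5 recovered within 3/sqrt(T) on the z scale
  sp2 <- clean_spec(n_rois = 2, n_timepoints = 10000, within_cor = 0.5)
  sp2$blocks <- c(1L, 1L)
  S2 <- build_group_covariance(sp2, "control")
  x2 <- as.matrix(simulate_subject(S2, sp2, 12))
  expect_lt(abs(atanh(cor(x2)[1, 2]) - atanh(0.5)), 3 / sqrt(10000))

  # AR(1) coefficient shows up as the lag-1 autocorrelation
  sp3 <- clean_spec(n_rois = 1, n_timepoints = 10000, ar_coef = 0.3,
                    within_cor = 0, between_cor = 0)
  sp3$blocks <- 1L
  x3 <- as.matrix(simulate_subject(diag(1), sp3, 13))[, 1]
  ac1 <- cor(x3[-1], x3[-length(x3)])
  expect_lt(abs(ac1 - 0.3), 0.03)
})

test_that("covariance fidelity holds across replicates on the z scale", {
  sp <- clean_spec(n_rois = 8, n_timepoints = 10000, within_cor = 0.3,
                   between_cor = 0.05)
  S <- build_group_covariance(sp, "control")
  target_z <- atanh(stats::cov2cor(S)[upper.tri(S)])
  bound <- 3 / sqrt(10000 - 3)
  hits <- vapply(1:20, function(i) {
    x <- as.matrix(simulate_subject(S, sp, 1000 + i))
    z <- atanh(cor(x)[upper.tri(S)])
    mean(abs(z - target_z) <= bound)
  }, numeric(1))
  expect_gte(mean(hits), 0.99)
})

test_that("confound simulation is deterministic and respects its schedule", {
  sp <- cohort_spec(n_rois = 4, n_timepoints = 120, n_per_group = 2,
                    nuisance = nuisance_spec(motion_scale = 0,
                                             spike_times = integer()))
  cf <- simulate_confounds(sp, 5)
  expect_true(all(as.matrix(cf$motion) == 0))

  sp2 <- cohort_spec(n_rois = 4, n_timepoints = 120, n_per_group = 2,
                     nuisance = nuisance_spec(motion_scale = 0,
                                              spike_times = 100L,
                                              spike_amp = 2))
  cf2 <- simulate_confounds(sp2, 5)
  tx <- cf2$motion$trans_x
  expect_equal(tx[100] - tx[99], 2)
  expect_true(all(diff(tx)[-99] == 0))

  expect_identical(simulate_confounds(sp2, 5), simulate_confounds(sp2, 5))
  expect_false(identical(simulate_confounds(sp2, 5)$nuisance,
                         simulate_confounds(sp2, 6)$nuisance))
})

test_that("cohort generation is balanced, sized and fully reproducible", {
  sp <- cohort_spec(n_per_group = 2, n_timepoints = 30, n_rois = 5,
                    master_seed = 42)
  co <- simulate_cohort(sp)
  expect_equal(nrow(co), 4)
  expect_equal(sum(co$group == "control"), 2)
  expect_equal(dim(co$series[[1]]), c(30L, 5L))

  co2 <- simulate_cohort(sp)
  expect_identical(co$series, co2$series)
  expect_identical(co$confounds, co2$confounds)

  # byte-identical files on disk from the same master seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  sp3 <- cohort_spec(n_per_group = 3, n_timepoints = 30, n_rois = 5,
                     master_seed = 43)
  expect_equal(nrow(simulate_cohort(sp3)), 6)
})

test_that("planted group contrast has the planted sign at study scale", {
  n_rep <- 100
  sgn <- vapply(seq_len(n_rep), function(r) {
    sp <- example_cohort_spec(n_rois = 20, n_seeds = 5, n_planted = 5,
                              delta = 0.2, n_per_group = 28,
                              n_timepoints = 220, master_seed = 5000 + r)
    covs <- list(control = build_group_covariance(sp, "control"),
                 patient = build_group_covariance(sp, "patient"))
    seeds <- roinet:::derive_seeds(sp$master_seed, 2 * sp$n_per_group)
    groups <- rep(c("control", "patient"), each = sp$n_per_group)
    i <- match(sp$planted_effects$seed, sp$roi_labels)
    j <- match(sp$planted_effects$target, sp$roi_labels)
    idx <- cbind(i, j)
    rs <- vapply(seq_along(seeds), function(s) {
      x <- as.matrix(simulate_subject(covs[[groups[s]]], sp, seeds[s]))
      mean(cor(x)[idx])
    }, numeric(1))
    sign(mean(rs[groups == "patient"]) - mean(rs[groups == "control"]))
  }, numeric(1))
  expect_gte(mean(sgn > 0), 0.95)
})
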