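# Synthetic cohort generator: behavior, target connectomes, time series,
# motion, reproducibility and planted-parameter recovery.

test_that("behavior scores respect the 1-5 rubric and the IBS summation rule", {
  set.seed(1)
  cfg <- cohort_config(n_success = 13, n_fail = 17, n_regions = 4,
                       volumes_per_run = 10)
  beh <- generate_behavior(cfg)
  for (col in c("retrieve", "hunt", "environment")) {
    expect_true(all(beh[[col]] %in% 1:5))
  }
  expect_equal(beh$ibs, beh$retrieve + beh$hunt + beh$environment)
  expect_true(all(beh$ibs >= 3 & beh$ibs <= 15))
  # population-level structure: IBS rises TP1 -> TP2 and plateaus TP2 -> TP3
  m <- tapply(beh$ibs, beh$timepoint, mean)
  expect_gt(m["TP2"] - m["TP1"], 1)
  expect_lt(abs(m["TP3"] - m["TP2"]), 1)
})

test_that("zero-effect behavior configuration yields identical IBS at all timepoints", {
  set.seed(2)
  cfg <- cohort_config(n_regions = 4, volumes_per_run = 10,
                       behavior_gain_mean = 0, behavior_gain_sd = 0,
                       behavior_tp3_sd = 0)
  beh <- generate_behavior(cfg)
  ibs <- matrix(beh$ibs, nrow = 3)  # timepoints x dogs
  expect_true(all(ibs[1, ] == ibs[2, ] & ibs[2, ] == ibs[3, ]))
})

test_that("a behavior gain that forces subscores off the rubric is rejected", {
  cfg <- cohort_config(n_regions = 4, volumes_per_run = 10)
  cfg$behavior_gain_mean <- 30
  expect_error(generate_behavior(cfg), "outside \\[1,5\\]")
})

test_that("mean observed IBS gain matches the configured gain (Monte Carlo)", {
  # base mean chosen so the 1-5 rubric is not saturated: rounding is then
  # unbiased and the observed mean gain tracks the latent gain
  set.seed(3)
  cfg <- cohort_config(n_success = 500, n_fail = 500, n_regions = 4,
                       volumes_per_run = 10, subscore_base_mean = 2.5,
                       subscore_success_shift = 0, subscore_sd = 0.5,
                       behavior_gain_mean = 3, behavior_gain_sd = 1)
  beh <- generate_behavior(cfg)
  ibs <- matrix(beh$ibs, nrow = 3)
  expect_lt(abs(mean(ibs[2, ] - ibs[1, ]) - 3), 0.1)
})

test_that("target FC is the identity with no planted edges and zero noise", {
  cfg <- cohort_config(n_regions = 8, volumes_per_run = 10, noise_sd = 0,
                       subscore_success_shift = 0)
  set.seed(1)
  st <- caninefc:::make_dog_state(cfg, success = TRUE, ibs_delta_std = 0)
  expect_equal(build_target_fc(cfg, st, "TP2"), diag(8), tolerance = 1e-12)
})

test_that("nearest_correlation is a fixed point on valid input and repairs invalid input", {
  set.seed(4)
  A <- cov2cor(crossprod(matrix(rnorm(100), 10, 10)) + diag(10))
  expect_lt(max(abs(nearest_correlation(A) - A)), 1e-12)
  B <- diag(3)
  B[1, 2] <- B[2, 1] <- 0.9
  B[1, 3] <- B[3, 1] <- 0.9
  B[2, 3] <- B[3, 2] <- -0.9   # impossible triangle: not PSD
  R <- nearest_correlation(B)
  expect_equal(diag(R), rep(1, 3))
  expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-8)
  expect_lt(max(abs(R - t(R))), 1e-12)
})

test_that("core edges carry the configured group offset on average (Monte Carlo)", {
  set.seed(5)
  core <- data.frame(i = 1, j = 2, group_effect_d = 1.5)
  cfg <- cohort_config(n_success = 13, n_fail = 17, n_regions = 12,
                       volumes_per_run = 10, noise_sd = 0.1,
                       core_edges = core, subscore_success_shift = 0)
  diffs <- replicate(500, {
    zs <- vapply(c(rep(TRUE, 13), rep(FALSE, 17)), function(succ) {
      st <- caninefc:::make_dog_state(cfg, succ, 0)
      atanh(build_target_fc(cfg, st, "TP1")[1, 2])
    }, numeric(1))
    mean(zs[1:13]) - mean(zs[14:30])
  })
  expect_lt(abs(mean(diffs) - 0.15), 0.01)
})

test_that("generated time series have the requested dimensions and converge to the target", {
  set.seed(6)
  ts <- generate_timeseries(diag(5), 200)
  expect_equal(dim(ts$samples), c(200, 5))
  r <- cor(ts$samples)
  expect_lt(mean(abs(r[upper.tri(r)])), 3 / sqrt(199))
  tgt <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  big <- generate_timeseries(tgt, 1e5)
  expect_lt(abs(cor(big$samples)[1, 2] - 0.8), 0.01)
})

test_that("non-PSD targets are rejected by the time-series sampler", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(generate_timeseries(bad, 50), "positive semi-definite")
})

test_that("AR(1) temporal kernel leaves the spatial correlation unchanged", {
  set.seed(7)
  tgt <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  ts <- generate_timeseries(tgt, 5e4, ar1 = 0.4)
  expect_lt(abs(cor(ts$samples)[1, 2] - 0.6), 0.02)
})

test_that("motion traces respect spike probabilities at the FD threshold", {
  set.seed(8)
  calm <- compute_fd(generate_motion(200, spike_prob = 0))
  expect_lt(max(calm$fd), 0.01)
  wild <- compute_fd(generate_motion(200, spike_prob = 1, spike_mm = 0.5))
  expect_true(all(wild$fd[-1] > 0.2))
  some <- compute_fd(generate_motion(10000, spike_prob = 0.1, spike_mm = 0.5))
  expect_lt(abs(mean(some$fd[-1] > 0.2) - 0.1), 0.01)
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- tiny_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("cohort structure matches the configuration", {
  pl <- planted_edges_default()
  cfg <- cohort_config(n_success = 3, n_fail = 4, n_regions = 30,
                       volumes_per_run = 20, runs_per_tp = 2,
                       n_complete = 5, spike_prob = 0,
                       periphery_edges = pl$periphery, core_edges = pl$core,
                       seed = 12)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$manifest), 7)
  expect_equal(sum(co$manifest$complete), 5)
  for (d in co$manifest$dog_id) {
    tps <- Filter(Negate(is.null), co$runs[[d]])
    n_expected <- if (co$manifest$complete[co$manifest$dog_id == d]) 3 else 1
    expect_length(tps, n_expected)
    expect_true(all(lengths(tps) == 2))  # runs_per_tp at every timepoint
  }
  # ground truth recorded exactly as configured
  expect_identical(co$truth$periphery_edges, pl$periphery)
  expect_identical(co$truth$core_edges, pl$core)
})

test_that("overlapping or out-of-range planted edge lists are rejected", {
  pe <- data.frame(i = 1, j = 2, coupling_rho = 0.8, fc_gain = 0.3)
  ce <- data.frame(i = 1, j = 2, group_effect_d = 1)
  expect_error(cohort_config(periphery_edges = pe, core_edges = ce),
               "disjoint")
  expect_error(cohort_config(core_edges = data.frame(i = 5, j = 3,
                                                     group_effect_d = 1)))
  expect_error(cohort_config(core_edges = data.frame(i = 1, j = 99,
                                                     group_effect_d = 1)))
  expect_error(cohort_config(periphery_edges = data.frame(
    i = 1, j = 2, coupling_rho = 1.2, fc_gain = 0.3)))
})

test_that("planted coupling is recovered across many cohorts (Fisher-z band)", {
  pe <- data.frame(i = 1, j = 2, coupling_rho = 0.8, fc_gain = 0.36)
  zr <- vapply(seq_len(200), function(k) {
    cfg <- cohort_config(n_success = 10, n_fail = 14, n_regions = 10,
                         volumes_per_run = 10, runs_per_tp = 1,
                         spike_prob = 0, periphery_edges = pe,
                         seed = 9000 + k)
    co <- generate_cohort(cfg)
    # planted truth: target-matrix Fisher-z change vs observed IBS change
    dz <- vapply(co$manifest$dog_id, function(d) {
      atanh(co$truth$targets[[d]][["TP2"]][1, 2]) -
        atanh(co$truth$targets[[d]][["TP1"]][1, 2])
    }, numeric(1))
    ibs <- matrix(co$behavior$ibs, nrow = 3)
    atanh(cor(dz, ibs[2, ] - ibs[1, ]))
  }, numeric(1))
  expect_lt(abs(tanh(mean(zr)) - 0.8), 0.03)
})

test_that("a cohort written to disk round-trips through the text layout", {
  co <- generate_cohort(tiny_config(seed = 13))
  dir <- tempfile()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "behavior.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  row <- man[3, ]
  rr <- read_run(file.path(dir, row$file), file.path(dir, row$motion_file))
  orig <- co$runs[[row$dog_id]][[row$timepoint]][[row$run]]
  expect_equal(rr$ts$samples, orig$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  orig_mo <- co$motion[[row$dog_id]][[row$timepoint]][[row$run]]
  expect_equal(rr$motion$translations, orig_mo$translations,
               tolerance = 1e-12, ignore_attr = TRUE)
})
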