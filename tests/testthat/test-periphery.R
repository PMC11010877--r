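# Periphery selection: delta computation, delta-delta correlation, paired
# change tests, and the three-criterion selection rule.

test_that("timepoint deltas are exact and antisymmetric", {
  set.seed(40)
  v <- array(rnorm(5 * 3 * 6, 0, 0.2), c(5, 3, 6))
  et <- make_edge_table(v, 4)
  beh <- make_behavior(cbind(rep(9, 5), 13, 13))
  d12 <- delta_across_timepoints(et, beh, "TP1", "TP2")
  expect_equal(d12$delta_ibs, rep(4, 5))
  expect_equal(d12$delta_fc, v[, 2, ] - v[, 1, ], ignore_attr = TRUE)
  d21 <- delta_across_timepoints(et, beh, "TP2", "TP1")
  expect_equal(d21$delta_fc, -d12$delta_fc)
  expect_equal(d21$delta_ibs, -d12$delta_ibs)

  same <- v; same[, 2, ] <- same[, 1, ]
  d0 <- delta_across_timepoints(make_edge_table(same, 4), beh, "TP1", "TP2")
  expect_true(all(d0$delta_fc == 0))
})

test_that("delta-delta correlation is exact in degenerate cases and calibrated under the null", {
  # proportional change with positive slope
  dibs <- c(1, 2, 3, 4, 6)
  delta <- list(delta_fc = matrix(2 * dibs, ncol = 1), delta_ibs = dibs,
                edges = cbind(1, 2))
  cd <- correlate_delta(delta)
  expect_equal(cd$r_delta, 1, tolerance = 1e-12)
  expect_lt(cd$p_delta, 1e-6)

  # zero behavioral spread: p = 1 with a warning
  flat <- list(delta_fc = matrix(rnorm(5)), delta_ibs = rep(2, 5),
               edges = cbind(1, 2))
  expect_warning(cdf <- correlate_delta(flat), "zero-variance")
  expect_equal(cdf$p_delta, 1)

  # null calibration over 10,000 independent edges
  set.seed(41)
  n <- 24
  null_delta <- list(delta_fc = matrix(rnorm(n * 10000), n),
                     delta_ibs = rnorm(n),
                     edges = edge_pairs(142)[1:10000, ])
  pn <- correlate_delta(null_delta)$p_delta
  expect_lt(abs(mean(pn < 0.05) - 0.05), 0.006)
})

test_that("the sampling distribution of the delta-delta correlation is centred on the planted rho", {
  set.seed(42)
  n <- 24
  rs <- replicate(500, {
    ibs <- rnorm(n)
    fcv <- 0.8 * ibs + sqrt(1 - 0.8^2) * rnorm(n)
    correlate_delta(list(delta_fc = matrix(fcv), delta_ibs = ibs,
                         edges = cbind(1, 2)))$r_delta
  })
  expect_lt(abs(mean(rs) - 0.8), 0.03)
})

test_that("paired change tests handle exact ties, constant shifts, and stay calibrated", {
  set.seed(43)
  v <- array(rnorm(6 * 3 * 3, 0, 0.2), c(6, 3, 3))
  v[, 2, ] <- v[, 1, ]              # TP2 identical to TP1
  v[, 3, 1] <- v[, 2, 1] + 1.0      # constant shift on edge 1
  et <- make_edge_table(v, 3)
  expect_warning(same <- paired_change_test(et, "TP1", "TP2"),
                 "zero within-pair variance")
  expect_equal(same$p, rep(1, 3))
  expect_equal(same$mean_change, rep(0, 3))
  expect_warning(shift <- paired_change_test(et, "TP2", "TP3"),
                 "zero within-pair variance")
  expect_equal(shift$mean_change[1], 1.0)
  expect_equal(shift$p[1], 0)

  # type-I calibration over 10,000 null edges
  n <- 24
  vv <- array(rnorm(n * 2 * 10000, 0, 1), c(n, 2, 10000))
  etn <- make_edge_table(vv, 142, timepoints = c("TP1", "TP2"))
  etn$edges <- etn$edges[1:10000, ]
  pn <- paired_change_test(etn, "TP1", "TP2")$p
  expect_lt(abs(mean(pn < 0.05) - 0.05), 0.006)
})

test_that("selection demands correlation, increase, and maintenance together", {
  base <- data.frame(
    i = 1, j = 2, region_i = "R01", region_j = "R02",
    r_delta = 0.7, p_delta = 0.001,
    mean_increase_tp1_tp2 = 0.3, p_increase_tp1_tp2 = 0.002,
    mean_change_tp2_tp3 = 0.01, p_change_tp2_tp3 = 0.6,
    r_delta_tp3_tp1 = 0.6, p_tp3_tp1_delta = 0.01, p_diff_of_diffs = 0.01)
  expect_true(select_periphery(base)$selected)

  keeps_growing <- base
  keeps_growing$p_change_tp2_tp3 <- 0.01  # fails only the maintenance rule
  expect_false(select_periphery(keeps_growing)$selected)

  decreasing <- base
  decreasing$mean_increase_tp1_tp2 <- -0.3
  expect_false(select_periphery(decreasing)$selected)

  no_corr <- base
  no_corr$p_delta <- 0.2
  expect_false(select_periphery(no_corr)$selected)

  # impossible threshold selects nothing
  expect_false(select_periphery(base, alpha = 1e-12)$selected)

  # strict mode additionally requires the confirmatory criteria
  weak_confirm <- base
  weak_confirm$p_tp3_tp1_delta <- 0.5
  expect_true(select_periphery(weak_confirm)$selected)
  expect_false(select_periphery(weak_confirm, strict = TRUE)$selected)
})

test_that("one-sided increase mode admits edges the two-sided rule would not", {
  border <- data.frame(
    i = 1, j = 2, region_i = "R01", region_j = "R02",
    r_delta = 0.6, p_delta = 0.01,
    mean_increase_tp1_tp2 = 0.2, p_increase_tp1_tp2 = 0.08,
    mean_change_tp2_tp3 = 0, p_change_tp2_tp3 = 0.9,
    r_delta_tp3_tp1 = 0.5, p_tp3_tp1_delta = 0.05, p_diff_of_diffs = 0.05)
  expect_false(select_periphery(border)$selected)
  expect_true(select_periphery(border, one_sided = TRUE)$selected)
})

test_that("selection is monotone in the planted effect size", {
  # direct simulation of the selection operating characteristic
  sel_rate <- function(gain, rho, n_rep = 150) {
    n <- 24
    mean(replicate(n_rep, {
      ibs <- rnorm(n)
      inc <- gain + 0.3 * (rho * ibs + sqrt(1 - rho^2) * rnorm(n))
      tp1 <- rnorm(n, 0, 0.25)
      noise <- function() rnorm(n, 0, 0.16)
      v <- array(NA_real_, c(n, 3, 1))
      v[, 1, 1] <- tp1 + noise()
      v[, 2, 1] <- tp1 + inc + noise()
      v[, 3, 1] <- tp1 + inc + noise()
      et <- make_edge_table(v, 2)
      beh <- make_behavior(cbind(9, 9 + 2 + ibs, 9 + 2 + ibs))
      sum(select_periphery(periphery_stats(et, beh))$selected)
    }))
  }
  set.seed(44)
  weak <- sel_rate(0.05, 0.3)
  strong <- sel_rate(0.36, 0.8)
  expect_gt(strong, weak)
  expect_gt(strong, 0.8)
})
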