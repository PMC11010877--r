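# Core selection, stability verification, the ridge logistic classifier,
# stratified shuffling, and ROC/AUC.

test_that("group differences are directional and vanish for identical groups", {
  n <- 10
  v <- array(rep(rnorm(6, 0, 0.3), each = n), c(n, 1, 6))
  et <- make_edge_table(v, 4, timepoints = "TP1")
  y <- rep(c(TRUE, FALSE), each = 5)
  expect_warning(gd <- group_difference_test(et, y, "TP1"), "zero-variance")
  expect_true(all(is.na(gd$p)))  # identical per-dog values: nothing passes

  set.seed(50)
  v2 <- array(rnorm(n * 6, 0, 0.3), c(n, 1, 6))
  v2[6:10, 1, 3] <- v2[6:10, 1, 3] + 5   # non-successful much stronger
  et2 <- make_edge_table(v2, 4, timepoints = "TP1")
  gd2 <- group_difference_test(et2, y, "TP1")
  expect_lt(gd2$p[3], 1e-4)
  expect_false(gd2$stronger_in_successful[3])
  expect_equal(nrow(select_core(gd2, alpha = 0.01)), 0)  # wrong direction

  v2[1:5, 1, 5] <- v2[1:5, 1, 5] + 5     # successful stronger
  gd3 <- group_difference_test(make_edge_table(v2, 4, "TP1"), y, "TP1")
  sel <- select_core(gd3, alpha = 0.01)
  expect_equal(sel$i, edge_pairs(4)[5, 1], ignore_attr = TRUE)
})

test_that("directional null rate is half the two-sided level", {
  set.seed(51)
  n <- 30
  y <- rep(c(TRUE, FALSE), c(13, 17))
  v <- array(rnorm(n * 10000, 0, 0.3), c(n, 1, 10000))
  et <- make_edge_table(v, 142, timepoints = "TP1")
  et$edges <- et$edges[1:10000, ]
  gd <- group_difference_test(et, y, "TP1")
  rate <- mean(gd$p < 0.01 & gd$stronger_in_successful, na.rm = TRUE)
  expect_lt(abs(rate - 0.005), 0.002)
})

test_that("group test matches t.test as an independent oracle", {
  set.seed(52)
  n <- 12
  v <- array(rnorm(n * 3), c(n, 1, 3))
  et <- make_edge_table(v, 3, timepoints = "TP1")
  y <- rep(c(TRUE, FALSE), each = 6)
  gd <- group_difference_test(et, y, "TP1")
  for (e in 1:3) {
    ref <- t.test(v[1:6, 1, e], v[7:12, 1, e])
    expect_equal(gd$p[e], ref$p.value, tolerance = 1e-12)
    expect_equal(gd$t[e], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("core stability flags drift and passes constant edges", {
  n <- 24
  y <- rep(c(TRUE, FALSE), c(11, 13))
  core <- data.frame(i = 1, j = 2)

  # identical values at every timepoint: degenerate rule gives p = 1, stable
  v <- array(rep(rnorm(n, 0, 0.3), 3), c(n, 3, 1))
  st <- verify_core_stability(make_edge_table(v, 2), y, core)
  expect_true(st$stable)
  expect_true(all(unlist(st[grep("^p_", names(st))]) == 1))

  # planted TP1 -> TP2 drift of two within-group SDs is caught
  set.seed(53)
  caught <- mean(replicate(60, {
    vv <- array(rnorm(n * 3, 0, 0.1), c(n, 3, 1))
    vv[, 2, 1] <- vv[, 2, 1] + 0.2
    vv[, 3, 1] <- vv[, 3, 1] + 0.2
    !verify_core_stability(make_edge_table(vv, 2), y, core)$stable
  }))
  expect_gt(caught, 0.9)
})

test_that("drift-free edges are flagged stable at the rate six correlated tests imply", {
  # Monte-Carlo derived: P(all six within/between-timepoint paired tests
  # accept at 0.05) for pure measurement noise is ~0.77, not 1 - 0.05.
  set.seed(54)
  n <- 24
  y <- rep(c(TRUE, FALSE), c(11, 13))
  core <- data.frame(i = 1, j = 2)
  stable <- mean(replicate(300, {
    base <- rnorm(n, 0, 0.25)
    vv <- array(base + rnorm(n * 3, 0, 0.115), c(n, 3, 1))
    verify_core_stability(make_edge_table(vv, 2), y, core)$stable
  }))
  expect_gt(stable, 0.65)
  expect_lt(stable, 0.88)
})

test_that("ridge logistic scores behave in the exact textbook configurations", {
  # two training points per class on one feature, test at the midpoint
  f <- matrix(c(1, 1, -1, -1, 0))
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  sc <- logistic_train_predict(f, y, 1:4, 5)
  expect_equal(sc, 0.5, tolerance = 1e-8)

  # constant feature: scores equal the training-set class prior
  fc <- matrix(rep(3, 6))
  yc <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  sc2 <- logistic_train_predict(fc, yc, 1:4, 5:6)
  expect_equal(unname(sc2), rep(0.5, 2), tolerance = 1e-8)
  sc3 <- logistic_train_predict(fc, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
                                1:4, 5:6)
  expect_equal(unname(sc3), rep(0.25, 2), tolerance = 1e-6)

  # a separating feature orders test classes perfectly
  set.seed(55)
  fs <- matrix(c(rnorm(10, 3), rnorm(10, -3)))
  ys <- rep(c(TRUE, FALSE), each = 10)
  sc4 <- logistic_train_predict(fs, ys, c(1:8, 11:18), c(9, 10, 19, 20))
  expect_true(all(sc4[1:2] > sc4[3:4]))

  expect_error(logistic_train_predict(fs, ys, 1:8, 11:20), "single class")
  expect_error(logistic_train_predict(fs, ys, 1:10, 5:20))  # overlap
})

test_that("ridge logistic agrees with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(56)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  y <- runif(n) < 1 / (1 + exp(-(0.5 + x[, 1] - 0.7 * x[, 2])))
  lambda <- 1
  beta <- caninefc:::ridge_logistic(x, y, lambda)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-12)
  ref <- as.numeric(coef(g))
  expect_equal(beta, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("stratified splits keep class proportions for the 13/17 cohort", {
  set.seed(57)
  y <- rep(c(TRUE, FALSE), c(13, 17))
  for (k in 1:50) {
    test <- caninefc:::stratified_test_split(y, 0.25)
    expect_true(sum(y[test]) %in% 3:4)
    expect_true(sum(!y[test]) %in% 4:5)
    expect_equal(length(test), 8)
  }
})

test_that("roc_auc reproduces hand-counted and degenerate cases", {
  auc1 <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc1$auc, 0.75)  # 3 of 4 concordant pairs

  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  r <- roc_auc(runif(30), rep(c(TRUE, FALSE), 15))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("roc_auc equals brute-force concordance and the Mann-Whitney statistic", {
  set.seed(58)
  for (k in 1:60) {
    n <- sample(4:60, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- if (k %% 2) runif(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    a <- roc_auc(s, y)$auc
    expect_equal(a, auc_bruteforce(s, y), tolerance = 1e-12)
    w <- suppressWarnings(wilcox.test(s[y], s[!y]))
    expect_equal(a, unname(w$statistic) / (sum(y) * sum(!y)),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(59)
  y <- runif(40) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  s <- rnorm(40)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(plogis(s)), y)$auc, a, tolerance = 1e-9)
})

test_that("stratified shuffling is near chance on label-independent features and perfect on separable ones", {
  set.seed(60)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  r_null <- replicate(10, {
    noise <- matrix(rnorm(n * 3), n, 3)
    r <- stratified_shuffle_eval(noise, y, n_iterations = 100)
    c(r$auc, r$mean_iteration_auc)
  })
  expect_lt(abs(mean(r_null[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(r_null[2, ]) - 0.5), 0.05)

  sep <- matrix(ifelse(y, 1, -1) + rnorm(n, 0, 0.01))
  r_sep <- stratified_shuffle_eval(sep, y, n_iterations = 100)
  expect_equal(r_sep$auc, 1)
})

test_that("nested feature selection removes the optimism of full-sample selection", {
  set.seed(61)
  n <- 24
  y <- rep(c(TRUE, FALSE), c(10, 14))
  gaps <- replicate(5, {
    v <- array(rnorm(n * 200, 0, 0.3), c(n, 1, 200))
    et <- make_edge_table(v, 21, timepoints = "TP1")
    et$edges <- et$edges[1:200, ]
    full_sel <- select_core(group_difference_test(et, y, "TP1"), alpha = 0.05)
    x <- matrix(v[, 1, ], n)
    faithful <- if (nrow(full_sel)) {
      ids <- caninefc:::edge_ids(full_sel[, c("i", "j")], 21)
      stratified_shuffle_eval(x[, ids, drop = FALSE], y,
                              n_iterations = 150)$auc
    } else 0.5
    selector <- function(train) {
      sub <- caninefc:::subset_edge_table(et, et$dogs[train])
      sel <- select_core(group_difference_test(sub, y[train], "TP1"),
                         alpha = 0.05)
      if (!nrow(sel)) integer(0)
      else caninefc:::edge_ids(sel[, c("i", "j")], 21)
    }
    nested <- stratified_shuffle_eval(x, y, n_iterations = 150,
                                      selector = selector)$auc
    faithful - nested
  })
  # circular selection on null data is optimistic; nested selection is not
  expect_gt(mean(gaps), 0.05)
})
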