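test_that("noiseless two-factor data give near-perfect cumulative Q2", {
  inst <- latent_instance(21, 6, m = 3, n_active = 6, snr = Inf, sd_x = 0,
                          seed = 5)
  cv <- crossval_q2(inst$X, inst$Y, a_max = 2, k = 7, seed = 1)
  expect_gt(cv$q2_cum[2], 0.99)
})

test_that("leave-one-out PRESS equals a brute-force refit loop", {
  set.seed(31)
  X <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- matrix(rnorm(12) + 0.6 * X[, 1], 12, 1, dimnames = list(NULL, "y"))
  a_max <- 3
  cv <- crossval_q2(X, y, a_max = a_max, k = 12, seed = 1)
  # independent oracle: refit on each leave-one-out set and predict the
  # held-out row, accumulating on the full-data scaled response
  sc_full <- center_scale(X, y)
  press <- numeric(a_max)
  for (i in 1:12) {
    f <- pls_fit(X[-i, ], y[-i, , drop = FALSE], a_max)
    for (a in 1:a_max) {
      pred <- predict(f, X[i, , drop = FALSE], ncomp = a)
      press[a] <- press[a] +
        ((pred - sc_full$preprocess$y_center) / sc_full$preprocess$y_scale -
           sc_full$Y[i, 1])^2
    }
  }
  expect_equal(unname(cv$press_overall), press, tolerance = 1e-10)
})

test_that("cross-validation is reproducible and respects fold contracts", {
  inst <- random_instance(23, 6, 2, seed = 17)
  cv1 <- crossval_q2(inst$X, inst$Y, a_max = 3, k = 7, seed = 9)
  cv2 <- crossval_q2(inst$X, inst$Y, a_max = 3, k = 7, seed = 9)
  expect_identical(cv1$press, cv2$press)
  expect_identical(cv1$folds, cv2$folds)
  # fold sizes differ by at most one; every row held out exactly once
  expect_lte(diff(range(table(cv1$folds))), 1)
  expect_identical(sort(unique(cv1$folds)), 1:7)
  expect_true(all(cv1$press >= 0))
  expect_error(crossval_q2(inst$X, inst$Y, a_max = 3, k = 40, seed = 1),
               "folds")
  expect_error(crossval_q2(inst$X, inst$Y, a_max = 19, k = 7, seed = 1),
               "cap")
})

test_that("degenerate folds are reported or tolerated as configured", {
  set.seed(2)
  X <- cbind(a = rnorm(12), b = c(1, rep(0, 11)))
  y <- matrix(rnorm(12), 12, 1)
  expect_error(crossval_q2(X, y, a_max = 1, k = 12, seed = 1), "fold")
  cv <- crossval_q2(X, y, a_max = 1, k = 12, seed = 1, on_constant = "keep")
  expect_true(is.finite(cv$q2_cum[1]))
})

test_that("pure-noise responses have non-positive Q2 on average", {
  q2 <- vapply(1:60, function(s) {
    inst <- random_instance(16, 5, 1, seed = 1000 + s)
    crossval_q2(inst$X, inst$Y, a_max = 2, k = 7, seed = s)$q2_cum[2]
  }, numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("component selection applies the per-component rule", {
  fake <- function(q2) structure(list(q2_comp = q2), class = "cv_result")
  expect_identical(select_components(fake(c(0.4, 0.2, -0.1)))$ncomp, 2L)
  expect_identical(select_components(fake(c(0.5, 0.3, 0.1)))$ncomp, 3L)
  low <- select_components(fake(c(0.01, 0.2)))
  expect_identical(low$ncomp, 1L)
  expect_true(low$flag_floor)
})

test_that("VIP matches hand arithmetic on a fixed small model", {
  # 3 variables, 2 components with hand-set weights and explained SS
  model <- structure(list(
    ncomp = 2L,
    W = matrix(c(1, 0, 0, 0, 0.6, 0.8), 3, 2,
               dimnames = list(c("v1", "v2", "v3"), NULL)),
    ssy_comp = c(3, 1)), class = "pls_model")
  v <- vip(model)
  # VIP_j = sqrt(3 * (3 w_j1^2 + 1 w_j2^2) / 4)
  expect_equal(unclass(v),
               c(v1 = sqrt(9 / 4), v2 = sqrt(3 * 0.36 / 4),
                 v3 = sqrt(3 * 0.64 / 4)),
               tolerance = 1e-10)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
})

test_that("identical informative columns all get VIP exactly one", {
  set.seed(6)
  base <- rnorm(20)
  X <- matrix(rep(base, 4), 20, 4) + 0  # p identical columns
  colnames(X) <- paste0("x", 1:4)
  y <- matrix(base + rnorm(20, sd = 0.2), 20, 1)
  f <- pls_fit(X + matrix(rnorm(80, sd = 1e-8), 20, 4), y, 1)
  expect_equal(unclass(vip(f)), rep(1, 4), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("VIP normalization holds on every fitted model", {
  for (seed in 1:10) {
    inst <- random_instance(12 + seed, 4 + seed %% 5, 1 + seed %% 3, seed)
    f <- pls_fit(inst$X, inst$Y, 2 + seed %% 2)
    v <- vip(f)
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
    expect_gte(max(v), 1)  # the VIP < 1 filter can never empty the set
    expect_true(all(v >= 0))
  }
})

test_that("signal variables earn VIP above one in most replicates", {
  hits <- vapply(1:40, function(s) {
    inst <- latent_instance(60, 16, m = 2, n_active = 1, snr = 5, seed = s)
    f <- pls_fit(inst$X, inst$Y, 2)
    unclass(vip(f))["x1"] > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the VIP filter keeps the boundary and refits exactly once", {
  inst <- latent_instance(24, 10, m = 3, n_active = 4, snr = 5, seed = 44)
  res <- vip_filter_refit(inst$X, inst$Y, seed = 3)
  v <- unclass(res$vip)
  expect_setequal(res$retained, names(v)[v >= 1])
  # the reported model uses only the retained columns
  expect_identical(rownames(res$fit$W), res$retained)
  expect_identical(colnames(res$X), res$retained)
  # all-retained edge: threshold 0 keeps everything; refit on the full set
  res0 <- vip_filter_refit(inst$X, inst$Y, threshold = 0, seed = 3)
  expect_identical(res0$retained, colnames(inst$X))
  expect_equal(res0$fit$W, res0$fit_full$W, tolerance = 1e-12)
})

test_that("recovery: active variables survive the filter at moderate SNR", {
  ok <- vapply(1:50, function(s) {
    inst <- latent_instance(80, 20, m = 3, n_active = 5, snr = 3, seed = s)
    res <- vip_filter_refit(inst$X, inst$Y, seed = s)
    sum(inst$active %in% res$retained) >= 4
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("RMSRE matches its definition and scale invariance", {
  expect_equal(rmsre(c(3, 5, 7), c(3, 5, 7)), 0)
  expect_equal(rmsre(c(1, 2, 4), c(1.1, 2.2, 4.4)), 10, tolerance = 1e-10)
  expect_equal(rmsre(c(2, 4), c(1, 5)), 100 * sqrt(0.15625),
               tolerance = 1e-10)
  y <- c(2, 3, 9); yh <- c(2.5, 2.4, 10)
  expect_equal(rmsre(5 * y, 5 * yh), rmsre(y, yh), tolerance = 1e-12)
  expect_equal(rmsre(-2 * y, -2 * yh), rmsre(y, yh), tolerance = 1e-12)
  expect_error(rmsre(c(1, 0), c(1, 1)), "zero")
  expect_error(rmsre(1:3, 1:4), "length")
})

test_that("Q2 approaches R2Y as the response noise vanishes", {
  r2_gap <- vapply(c(Inf, 20, 5), function(snr) {
    inst <- latent_instance(28, 8, m = 2, n_active = 8, snr = snr,
                            sd_x = 0.05, seed = 3)
    cv <- crossval_q2(inst$X, inst$Y, a_max = 2, k = 7, seed = 2)
    f <- pls_fit(inst$X, inst$Y, 2)
    r2y(f)$overall - cv$q2_cum[2]
  }, numeric(1))
  # the fit/prediction gap shrinks along the noise ladder
  expect_lt(r2_gap[1], 0.05)
  expect_true(all(diff(r2_gap) >= -0.02))
})

test_that("two-factor structure is recovered by component selection", {
  picks <- vapply(1:50, function(s) {
    inst <- latent_instance(34, 15, m = 5, n_active = 8, snr = 3,
                            sd_x = 0.4, seed = 100 + s)
    cv <- crossval_q2(inst$X, inst$Y, a_max = 4, k = 7, seed = s)
    select_components(cv)$ncomp
  }, integer(1))
  expect_gte(mean(picks == 2), 0.8)
})
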