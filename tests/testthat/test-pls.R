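test_that("center_scale standardizes training columns and is reusable", {
  inst <- random_instance(10, 3, 2, seed = 1)
  sc <- center_scale(inst$X, inst$Y)
  expect_equal(colMeans(sc$X), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(sc$X, 2, sd), rep(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(colMeans(sc$Y), rep(0, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # new data are transformed with the training statistics, not their own
  Xnew <- inst$X[1:3, ] + 100
  Xs_new <- agropls:::scale_x(sc$preprocess, Xnew)
  expect_equal(Xs_new, sc$X[1:3, ] + sweep(
    matrix(0, 3, 3), 2, 100 / sc$preprocess$x_scale, "+"),
    tolerance = 1e-10)
})

test_that("center_scale rejects constant columns by name", {
  X <- cbind(a = rnorm(5), b = rep(5, 5))
  expect_error(center_scale(X), "b")
  sc <- center_scale(X, on_constant = "keep")
  expect_equal(sc$X[, "b"], rep(0, 5), ignore_attr = TRUE)
})

test_that("NIPALS models satisfy the decomposition invariants", {
  cases <- list(c(n = 20, p = 8, m = 3, A = 3),
                c(n = 30, p = 5, m = 1, A = 4),
                c(n = 15, p = 12, m = 7, A = 5))
  for (cs in cases) {
    inst <- random_instance(cs["n"], cs["p"], cs["m"], seed = sum(cs))
    f <- pls_fit(inst$X, inst$Y, cs[["A"]])
    # weight columns unit norm
    expect_equal(sqrt(colSums(f$W^2)), rep(1, cs[["A"]]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # score orthogonality
    G <- crossprod(f$T)
    expect_lt(max(abs(G - diag(diag(G)))),
              1e-8 * max(sqrt(diag(G)) %o% sqrt(diag(G))))
    # reconstruction of both matrices
    expect_lt(max(abs(f$Xs - tcrossprod(f$T, f$P) - f$E)), 1e-8)
    expect_lt(max(abs(f$Ys - tcrossprod(f$T, f$Q) - f$F)), 1e-8)
    # orthogonal variance decomposition of X
    expect_equal(sum(f$ssx_comp) + sum(f$E^2), f$ss_x_total,
                 tolerance = 1e-6)
    # cumulative R2Y non-decreasing
    expect_true(all(diff(cumsum(f$r2y)) >= -1e-12))
    # deterministic refit
    f2 <- pls_fit(inst$X, inst$Y, cs[["A"]])
    expect_identical(f$W, f2$W)
  }
})

test_that("a response equal to one X column is fit perfectly by one factor", {
  # mutually orthogonal X columns: the first weight vector then selects the
  # matching column exactly, so a single component fits Y perfectly
  set.seed(3)
  M <- scale(matrix(rnorm(20 * 4), 20, 4), center = TRUE, scale = FALSE)
  X <- qr.Q(qr(M))  # orthogonal zero-mean columns
  Y <- X[, 2, drop = FALSE]
  f <- pls_fit(X, Y, 1)
  expect_equal(r2y(f)$overall, 1, tolerance = 1e-8)
})

test_that("first weight vector is the dominant singular vector of Xs'Ys", {
  for (seed in 1:5) {
    inst <- random_instance(4 + seed, 2 + seed %% 3, 1 + seed %% 2, seed)
    sc <- center_scale(inst$X, inst$Y)
    f <- nipals_pls(sc$X, sc$Y, 1)
    sv <- svd(crossprod(sc$X, sc$Y))$u[, 1]
    err <- min(max(abs(f$W[, 1] - sv)), max(abs(f$W[, 1] + sv)))
    expect_lt(err, 1e-8)
  }
})

test_that("full-rank single-response PLS equals ordinary least squares", {
  set.seed(11)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- matrix(rnorm(15), 15, 1)
  f <- pls_fit(X, y, 4)
  ols <- unname(fitted(lm(y ~ X)))
  expect_equal(drop(predict(f, X)), ols, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("prediction contracts: training rows, mean row, single row", {
  inst <- random_instance(18, 6, 3, seed = 21)
  f <- pls_fit(inst$X, inst$Y, 3)
  fitted_vals <- predict(f, inst$X)
  # residuals in original units equal unscaled F
  resid <- inst$Y - fitted_vals
  expect_equal(resid,
               sweep(f$F, 2, f$preprocess$y_scale, "*"),
               tolerance = 1e-10, ignore_attr = TRUE)
  # the column-mean row predicts the column means of Y
  expect_equal(drop(predict(f, colMeans(inst$X))), colMeans(inst$Y),
               tolerance = 1e-10)
  expect_equal(dim(predict(f, inst$X[4, ])), c(1L, 3L))
  expect_error(predict(f, inst$X[, 1:4]), "columns")
})

test_that("model dimensions and inputs are validated", {
  inst <- random_instance(6, 3, 2, seed = 2)
  sc <- center_scale(inst$X, inst$Y)
  expect_error(nipals_pls(sc$X, sc$Y, 4), "ncomp")
  expect_error(nipals_pls(matrix(0, 6, 3), sc$Y, 1), "zero")
})

test_that("zero-component R2Y is zero and full fit explains in between", {
  inst <- random_instance(12, 5, 2, seed = 8)
  f <- pls_fit(inst$X, inst$Y, 3)
  expect_equal(r2y(f, 0)$overall, 0)
  expect_true(r2y(f)$overall > 0 && r2y(f)$overall <= 1)
  expect_length(r2y(f)$per_response, 2L)
})

test_that("Hotelling region covers about 95 percent of normal scores", {
  set.seed(41)
  n <- 4000
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- X %*% matrix(c(1, 0.5, -0.5, 1), 2, 2) +
    matrix(rnorm(n * 2, sd = 0.1), n, 2)
  f <- pls_fit(X, Y, 2)
  h <- hotelling_ellipse(f)
  expect_equal(mean(h$outside), 0.05, tolerance = 0.3)
  expect_true(all(hotelling_ellipse(f, alpha = 1)$outside))
  # degenerate: all scores at the origin are never flagged
  f0 <- f
  f0$T[] <- 0
  expect_false(any(hotelling_ellipse(f0)$outside))
  expect_error(hotelling_ellipse(pls_fit(X, Y, 1)), "2 components")
})

test_that("model export tables carry one row per entity and component", {
  inst <- random_instance(10, 4, 2, seed = 13)
  f <- pls_fit(inst$X, inst$Y, 2)
  tabs <- model_tables(f)
  expect_identical(nrow(tabs$weights), 8L)
  expect_identical(nrow(tabs$y_loadings), 4L)
  expect_identical(nrow(tabs$scores), 20L)
  expect_equal(tabs$scalars$r2y_cum[2], r2y(f)$overall)
})
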