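test_that("default generator reproduces the study design counts", {
  d <- generate_synthetic_farms(synthetic_config(), seed = 1)
  expect_length(d$farms, 34L)
  regions <- farm_regions_of(d$farms)
  types <- farm_types_of(d$farms)
  expect_identical(unname(table(regions)), c(17L, 17L), ignore_attr = TRUE)
  expect_identical(sum(types == "CF"), 12L)
  expect_identical(sum(types %in% c("YOF", "OOF")), 22L)
  expect_identical(dim(d$Y), c(34L, 7L))
  expect_identical(colnames(d$Y), default_indicators())
})

test_that("generation is a deterministic function of config and seed", {
  d1 <- generate_synthetic_farms(synthetic_config(), seed = 9)
  d2 <- generate_synthetic_farms(synthetic_config(), seed = 9)
  expect_equal(design_matrix(d1$farms), design_matrix(d2$farms))
  expect_equal(d1$Y, d2$Y)
  expect_equal(d1$truth$T0, d2$truth$T0)
  d3 <- generate_synthetic_farms(synthetic_config(), seed = 10)
  expect_false(isTRUE(all.equal(d1$Y, d3$Y)))
})

test_that("generated columns respect their declared kinds and ranges", {
  sch <- default_schema()
  for (seed in c(1, 7, 23, 101)) {
    d <- generate_synthetic_farms(synthetic_config(), seed = seed)
    X <- design_matrix(d$farms)
    for (nm in colnames(X)) {
      spec <- sch[[nm]]
      if (!is.null(spec$range)) {
        expect_gte(min(X[, nm]), spec$range[1])
        expect_lte(max(X[, nm]), spec$range[2])
      }
      if (spec$kind == "dummy")
        expect_true(all(X[, nm] %in% c(0, 1)))
      if (spec$kind == "ordinal")
        expect_true(all(X[, nm] == round(X[, nm])))
    }
    expect_true(all(d$Y > 0))
  }
})

test_that("noiseless responses reconstruct the latent signal exactly", {
  cfg <- synthetic_config(snr_of = Inf)
  d <- generate_synthetic_farms(cfg, seed = 13)
  expected <- sweep(sweep(d$truth$T0 %*% t(cfg$q0), 2, cfg$y_scale, "*"),
                    2, cfg$y_center, "+")
  expect_equal(unname(d$Y), unname(expected), tolerance = 1e-12)
})

test_that("design_r2 gives the closed-form variance ratio", {
  cfg0 <- synthetic_config(snr_of = Inf)
  expect_equal(unname(design_r2(cfg0)), rep(1, 7))
  # signal SD equal to noise SD on a one-factor response gives 0.5
  q0 <- cbind(c(1, 0.5, 2, 1, 1, 1, 1), 0)
  rownames(q0) <- default_indicators()
  cfg1 <- synthetic_config(q0 = q0, noise_sd_y = 1, region_effect = 0)
  expect_equal(unname(design_r2(cfg1))[1], 0.5)
  # SNR parameterization: R2 = snr / (1 + snr) for every response when
  # the factors have unit variance (no region shift)
  cfg3 <- synthetic_config(snr_of = 3, region_effect = 0)
  expect_equal(unname(design_r2(cfg3)), rep(0.75, 7))
  # the region shift inflates factor-1 variance by 1 + effect^2
  cfgd <- synthetic_config(snr_of = 3, region_effect = 0.5)
  sig <- drop(cfgd$q0^2 %*% c(1.25, 1))
  expect_equal(unname(design_r2(cfgd)),
               unname(sig / (sig + rowSums(cfgd$q0^2) / 3)))
})

test_that("design_r2 matches a large-sample oracle regression on the scores", {
  cfg <- synthetic_config(n_cf = 0L, n_yof = 1250L, n_oof = 1250L)
  d <- generate_synthetic_farms(cfg, seed = 31)
  # oracle: regress each response on the true latent scores
  r2_emp <- vapply(seq_len(ncol(d$Y)), function(j) {
    summary(lm(d$Y[, j] ~ d$truth$T0))$r.squared
  }, numeric(1))
  expect_equal(r2_emp, unname(design_r2(cfg)), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("fitted R2Y approaches the design value as n grows", {
  # continuous-only active set and low X-noise, so the coded design
  # matrix carries the latent factors almost losslessly
  cfg <- synthetic_config(n_cf = 0L, n_yof = 125L, n_oof = 125L,
                          active_core = c("SMN1", "Tot_C", "Tot_N",
                                          "AOFert", "Seed"),
                          active_of_extra = c("Weed", "LHI", "Freq_OFe"),
                          sd_x = 0.3)
  d <- generate_synthetic_farms(cfg, seed = 17)
  X <- design_matrix(d$farms)
  act <- d$truth$active$OF
  f <- pls_fit(X[, act], d$Y, 2)
  expect_equal(r2y(f)$overall, mean(design_r2(cfg)), tolerance = 0.05)
})

test_that("ground truth serializes to JSON and reloads", {
  d <- generate_synthetic_farms(synthetic_config(), seed = 5)
  path <- tempfile(fileext = ".json")
  write_ground_truth(d$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 5)
  expect_setequal(back$active$OF, d$truth$active$OF)
  expect_equal(back$design_r2$OF[["Grain_M"]],
               unname(d$truth$design_r2$OF["Grain_M"]))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(active_core = c("SMN1", "NotAVar")),
               "NotAVar")
  expect_error(synthetic_config(active_core = c("SMN1", "Tot_C"),
                                active_of_extra = c("SMN1")),
               "overlapping")
  expect_error(synthetic_config(q0 = matrix(1, 3, 2)), "q0")
  expect_error(synthetic_config(noise_sd_y = -1), "non-negative")
})
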