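# Fixture builders shared across the test files. Everything is generated in
# code so the repository stays text-only.

# small random regression instance with named columns
random_instance <- function(n, p, m, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))),
       Y = matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("y", 1:m))))
}

# two-factor data with known active columns: first `n_active` X-columns
# carry the latent signal, the rest are standard-normal noise
latent_instance <- function(n, p, m = 3, n_active = 5, snr = 3,
                            sd_x = 0.3, seed = 1) {
  set.seed(seed)
  T0 <- matrix(rnorm(n * 2), n, 2)
  P0 <- matrix(rnorm(n_active * 2), n_active, 2)
  P0 <- P0 / sqrt(rowSums(P0^2))
  Q0 <- matrix(rnorm(m * 2), m, 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  X[, 1:n_active] <- T0 %*% t(P0) +
    matrix(rnorm(n * n_active, sd = sd_x), n, n_active)
  sig_sd <- sqrt(rowSums(Q0^2))
  noise <- if (is.infinite(snr)) rep(0, m) else sig_sd / sqrt(snr)
  Y <- T0 %*% t(Q0) + sweep(matrix(rnorm(n * m), n, m), 2, noise, "*")
  colnames(Y) <- paste0("y", 1:m)
  list(X = X, Y = Y, T0 = T0, active = paste0("x", 1:n_active))
}

# default 34-farm synthetic dataset written out as CSV files
write_farm_fixture <- function(dir = tempfile("farms"), seed = 1) {
  dir.create(dir, showWarnings = FALSE)
  d <- generate_synthetic_farms(synthetic_config(), seed = seed)
  farm_csv <- file.path(dir, "farms.csv")
  resp_csv <- file.path(dir, "responses.csv")
  write_farm_table(d$farms, farm_csv)
  write_response_table(d$Y, resp_csv)
  list(dir = dir, farm_csv = farm_csv, resp_csv = resp_csv, data = d)
}

farm_types_of <- function(farms) vapply(farms, `[[`, character(1), "farm_type")
farm_regions_of <- function(farms) vapply(farms, `[[`, character(1), "region")
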