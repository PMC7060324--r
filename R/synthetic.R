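#' Configuration of the synthetic farm generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a small number of latent factors drives both a subset of the
#' explanatory variables and the seven response indicators. Farms come in
#' two regions and three types; organic farms (YOF, OOF) draw on a larger
#' active variable set and a higher response signal-to-noise ratio than
#' conventional farms (CF), so the organic subsets are more explainable —
#' the qualitative contrast the method is meant to detect.
#'
#' Defaults: 17 farms per region (6 CF, 5 YOF, 6 OOF; totals 12 CF and 22
#' organic farms over 34), two latent factors, response SNR 3 for all rows
#' (design R2 = 0.75 relative to the unit-variance factor part; slightly
#' higher once the region shift on factor 1 is counted — see
#' [design_r2()]), X-noise SD 0.5 around unit-norm variable loadings, and
#' a mild additive region effect on the first factor so regions separate
#' in score plots. The organic/conventional contrast study uses the same
#' config with `snr_cf = 0.5`, making conventional rows much less
#' explainable on top of their smaller active set.
#'
#' @param n_cf,n_yof,n_oof Farms per region and type (scalar: same in both
#'   regions, or length-2 vector).
#' @param a0 Latent dimension (default 2; custom `p0`/`q0` must match).
#' @param active_core Variables active on every farm (default 5: soil N,
#'   C, N-total, weed cover, undersowing).
#' @param active_of_extra Additional variables active on organic farms
#'   only (default 7: management-history and landscape variables).
#' @param p0 Optional loading matrix for the active X-variables (rows
#'   named by variable, `a0` columns); default unit-norm loadings spreading
#'   both factors over the active set.
#' @param q0 Response loading matrix (7 x `a0`); default loads both
#'   factors on every indicator.
#' @param snr_of,snr_cf Response signal-to-noise (variance ratio) for
#'   organic / conventional rows; `Inf` means noiseless.
#' @param noise_sd_y Optional explicit response noise SD (scalar or
#'   per-response vector, same for all farm types); overrides the SNRs.
#' @param sd_x Noise SD added to active X-variables on the latent scale.
#' @param region_effect Additive shift of factor 1 (`+` in zone_A, `-` in
#'   zone_B).
#' @param y_center,y_scale Units mapping: response `j` in original units is
#'   `y_center[j] + y_scale[j] * (latent + noise)`; defaults give plausible
#'   barley indicator magnitudes (t/ha, %, ears per m2).
#' @param schema Variable schema (default [default_schema()]).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cf = 6L, n_yof = 5L, n_oof = 6L, a0 = 2L,
                             active_core = c("SMN1", "Tot_C", "Tot_N",
                                             "Weed", "US_12"),
                             active_of_extra = c("SMR_L12", "OFe_AT12",
                                                 "StdSd", "PC_leys", "LHI",
                                                 "Freq_OFe", "AOFert"),
                             p0 = NULL, q0 = NULL,
                             snr_of = 3, snr_cf = snr_of, noise_sd_y = NULL,
                             sd_x = 0.5, region_effect = 0.5,
                             y_center = NULL, y_scale = NULL,
                             schema = default_schema()) {
  rep2 <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  n_cf <- rep2(as.integer(n_cf)); n_yof <- rep2(as.integer(n_yof))
  n_oof <- rep2(as.integer(n_oof))
  nms <- schema_names(schema)
  active <- c(active_core, active_of_extra)
  if (!all(active %in% nms))
    stop("active variables not in schema: ",
         paste(setdiff(active, nms), collapse = ", "), call. = FALSE)
  if (anyDuplicated(active))
    stop("overlapping active sets", call. = FALSE)
  if (is.null(p0)) p0 <- default_x_loadings(active, a0)
  if (is.null(q0)) q0 <- default_y_loadings(a0)
  if (!identical(rownames(p0), active) || ncol(p0) != a0)
    stop("p0 must have one named row per active variable and a0 columns",
         call. = FALSE)
  if (nrow(q0) != 7L || ncol(q0) != a0)
    stop("q0 must be 7 x a0", call. = FALSE)
  if (is.null(y_center))
    y_center <- c(DM1 = 1.5, N_Cut1 = 3.5, DM2 = 8, Grain_M = 4.5,
                  Grain_N = 1.8, Straw_N = 0.8, Ears = 650)
  if (is.null(y_scale))
    y_scale <- c(DM1 = 0.25, N_Cut1 = 0.4, DM2 = 1.2, Grain_M = 0.8,
                 Grain_N = 0.25, Straw_N = 0.12, Ears = 110)
  if (!is.null(noise_sd_y) && any(noise_sd_y < 0))
    stop("noise_sd_y must be non-negative", call. = FALSE)
  structure(list(n_cf = n_cf, n_yof = n_yof, n_oof = n_oof, a0 = a0,
                 active_core = active_core,
                 active_of_extra = active_of_extra,
                 p0 = p0, q0 = q0, snr_of = snr_of, snr_cf = snr_cf,
                 noise_sd_y = noise_sd_y, sd_x = sd_x,
                 region_effect = region_effect,
                 y_center = y_center, y_scale = y_scale, schema = schema),
            class = "synthetic_config")
}

# deterministic unit-norm loading pattern spreading both factors over the
# active variables
default_x_loadings <- function(active, a0) {
  base <- matrix(c(0.9, 0.4,  0.4, 0.9,  -0.7, 0.6,  0.8, -0.5,  0.6, 0.7,
                   -0.5, 0.8,  0.9, -0.3,  0.3, 0.9,  0.7, 0.6,  -0.6, 0.7,
                   0.8, 0.4,  0.5, -0.8), ncol = 2, byrow = TRUE)
  if (a0 != 2) stop("default loadings cover a0 = 2; supply p0", call. = FALSE)
  P <- base[rep_len(seq_len(nrow(base)), length(active)), , drop = FALSE]
  P <- P / sqrt(rowSums(P^2))
  rownames(P) <- active
  P
}

default_y_loadings <- function(a0) {
  if (a0 != 2) stop("default loadings cover a0 = 2; supply q0", call. = FALSE)
  Q <- matrix(c(0.9, 0.3,  0.5, -0.7,  0.8, 0.4,  0.9, 0.2,
                0.3, 0.9,  -0.4, 0.8,  0.8, -0.5), ncol = 2, byrow = TRUE)
  rownames(Q) <- c("DM1", "N_Cut1", "DM2", "Grain_M", "Grain_N", "Straw_N",
                   "Ears")
  Q
}

noise_sd_for <- function(config, snr) {
  sig <- rowSums(config$q0^2)
  if (!is.null(config$noise_sd_y))
    return(rep_len(config$noise_sd_y, length(sig)))
  if (is.infinite(snr)) return(rep(0, length(sig)))
  sqrt(sig / snr)
}

# per-response signal variance: factor 1 carries the region shift, so its
# variance across farms is 1 + region_effect^2
signal_var <- function(config) {
  v <- rep(1, config$a0)
  v[1] <- 1 + config$region_effect^2
  drop(config$q0^2 %*% v)
}

#' Expected explained response variation implied by the design
#'
#' Closed form: per response `j`, the signal variance is the loading row's
#' quadratic form in the latent score variances — factor 1 has variance
#' `1 + region_effect^2` because of the region shift, the others 1 — and
#' the expected R2 is `signal / (signal + noise^2)` with the noise SD
#' implied by the farm type's SNR (or the explicit `noise_sd_y`). With
#' `region_effect = 0` and the SNR parameterization this reduces to
#' `snr / (1 + snr)` for every response.
#'
#' @param config A [synthetic_config()].
#' @param farm_type `"OF"` (organic, the default) or `"CF"`.
#' @return Named vector of expected R2Y per response.
#' @export
design_r2 <- function(config, farm_type = c("OF", "CF")) {
  stopifnot(inherits(config, "synthetic_config"))
  farm_type <- match.arg(farm_type)
  snr <- if (farm_type == "OF") config$snr_of else config$snr_cf
  sig <- signal_var(config)
  nz <- noise_sd_for(config, snr)
  stats::setNames(sig / (sig + nz^2), rownames(config$q0))
}

map_to_kind <- function(z, spec) {
  switch(spec$kind,
    dummy = as.numeric(z > stats::median(z)),
    ordinal = {
      lo <- spec$range[1]; hi <- spec$range[2]
      nlev <- hi - lo + 1
      # empirical quantile binning keeps the levels balanced
      r <- (rank(z, ties.method = "first") - 0.5) / length(z)
      lo + pmin(nlev - 1, floor(r * nlev))
    },
    {
      lo <- spec$range[1]; hi <- spec$range[2]
      mid <- (lo + hi) / 2
      pmin(hi, pmax(lo, mid + (hi - lo) / 6 * z))
    })
}

#' Generate a synthetic farm dataset with known ground truth
#'
#' Draws latent factor scores per farm (independent standard normal plus
#' the region effect on factor 1), builds each explanatory column as
#' latent signal plus noise for farms on which the variable is active —
#' organic farms draw on the core plus the organic-extra set, conventional
#' farms on the core set only — and pure standard-normal noise elsewhere,
#' then maps the latent column into the variable's declared kind
#' (continuous clipped to its range, dummies thresholded at the column
#' median, ordinals quantile-binned, percentages bounded). Responses are
#' the latent scores times the response loadings plus type-specific noise,
#' mapped to plausible indicator units (floored just above zero so
#' relative errors stay defined). The farm-type variable (time since
#' transition) and region-standardized columns are handled structurally:
#' TST is derived from the farm type, and region-standardized columns are
#' median-centered per region after generation.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(config, seed)`.
#' @return List with `farms` (a `farm_set`), `Y` (response matrix) and
#'   `truth` (latent scores, active sets, per-type design R2, config).
#' @export
generate_synthetic_farms <- function(config = synthetic_config(),
                                     seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    schema <- config$schema
    nms <- schema_names(schema)
    regions <- c("zone_A", "zone_B")
    type <- character(0); region <- character(0)
    for (r in 1:2) {
      type <- c(type, rep(c("CF", "YOF", "OOF"),
                          c(config$n_cf[r], config$n_yof[r],
                            config$n_oof[r])))
      region <- c(region,
                  rep(regions[r],
                      config$n_cf[r] + config$n_yof[r] + config$n_oof[r]))
    }
    n <- length(type)
    farm_id <- sprintf("%s%02d", ifelse(region == "zone_A", "A", "B"),
                       stats::ave(seq_len(n), region, FUN = seq_along))
    organic <- type %in% c("YOF", "OOF")
    tst <- integer(n)
    tst[type == "YOF"] <- sample(1:5, sum(type == "YOF"), replace = TRUE)
    tst[type == "OOF"] <- sample(11:26, sum(type == "OOF"), replace = TRUE)

    T0 <- matrix(stats::rnorm(n * config$a0), n, config$a0)
    T0[, 1] <- T0[, 1] + ifelse(region == "zone_A", 1, -1) *
      config$region_effect
    active_of <- c(config$active_core, config$active_of_extra)

    X <- matrix(NA_real_, n, length(nms), dimnames = list(farm_id, nms))
    for (j in seq_along(nms)) {
      v <- nms[j]
      spec <- schema[[v]]
      if (v == "TST") { X[, j] <- tst; next }
      z <- stats::rnorm(n)
      if (v %in% active_of) {
        on <- if (v %in% config$active_core) rep(TRUE, n) else organic
        sig <- drop(T0 %*% config$p0[v, ])
        z[on] <- sig[on] + stats::rnorm(sum(on), sd = config$sd_x)
      }
      X[, j] <- map_to_kind(z, spec)
      if (spec$region_standardized) {
        X[, j] <- standardize_by_region_median(X[, j], region)
        # median-centering can push clipped extremes past the envelope
        X[, j] <- pmin(spec$range[2], pmax(spec$range[1], X[, j]))
      }
    }

    sd_of <- noise_sd_for(config, config$snr_of)
    sd_cf <- noise_sd_for(config, config$snr_cf)
    Ystd <- T0 %*% t(config$q0)
    for (j in seq_len(ncol(Ystd))) {
      sds <- ifelse(organic, sd_of[j], sd_cf[j])
      Ystd[, j] <- Ystd[, j] + stats::rnorm(n, sd = sds)
    }
    Y <- sweep(sweep(Ystd, 2, config$y_scale, "*"), 2, config$y_center, "+")
    Y <- pmax(Y, matrix(1e-3 * config$y_center, n, ncol(Y), byrow = TRUE))
    colnames(Y) <- names(config$y_center)
    rownames(Y) <- farm_id

    df <- data.frame(farm_id = farm_id, region = region, farm_type = type,
                     years_since_transition = tst,
                     as.data.frame(X, check.names = FALSE),
                     stringsAsFactors = FALSE, check.names = FALSE)
    farms <- farms_from_df(df, schema)
    truth <- list(
      T0 = T0, active = list(CF = config$active_core, OF = active_of),
      design_r2 = list(OF = design_r2(config, "OF"),
                       CF = design_r2(config, "CF")),
      seed = seed, config = config)
    list(farms = farms, Y = response_matrix(Y), truth = truth)
  })
}

#' Write the generator ground truth as JSON
#'
#' @param truth The `truth` element of [generate_synthetic_farms()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(seed = truth$seed,
              latent_scores = unname(apply(truth$T0, 1, as.numeric,
                                           simplify = FALSE)),
              active = truth$active,
              design_r2 = lapply(truth$design_r2, as.list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
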