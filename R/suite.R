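#' Suite configuration
#'
#' Bundles the settings shared by every model of the subset suite.
#'
#' @param k Cross-validation folds (default 7).
#' @param a_max Maximum components considered (default 5).
#' @param limit Per-component Q2 limit for component selection.
#' @param threshold VIP elimination threshold.
#' @param seed Master seed; per-model seeds are derived as
#'   `seed * 100 + model_index`, so adding models never perturbs the
#'   subsets or folds of earlier ones.
#' @param scale_y Unit-variance scale the responses.
#' @return List of class `suite_config`.
#' @export
suite_config <- function(k = 7L, a_max = 5L, limit = 0.05, threshold = 1,
                         seed = 1L, scale_y = TRUE) {
  stopifnot(seed == round(seed), abs(seed) < 2^24)
  structure(list(k = k, a_max = a_max, limit = limit, threshold = threshold,
                 seed = as.integer(seed), scale_y = scale_y),
            class = "suite_config")
}

model_seed <- function(config, index) config$seed * 100L + as.integer(index)

#' Build the nineteen model subsets
#'
#' The suite fits one model per farm subset: Model 1 uses all farms;
#' Model 2 the organic farms only (YOF and OOF); Model 3 the conventional
#' farms only; Models 4-9 are six independent balanced draws of 6 organic
#' and 6 conventional farms from each region (n = 24, without replacement
#' within stratum); Models 10-19 are ten draws of 6 organic farms from
#' each region (n = 12). Strata are region crossed with farm type
#' collapsed to organic/conventional.
#'
#' @param farms A `farm_set`.
#' @param seed Master seed, or a `suite_config`.
#' @return List of `model_spec` objects (label, subset rule, replicate,
#'   seed, resolved farm ids).
#' @export
build_subsets <- function(farms, seed = 1L) {
  stopifnot(inherits(farms, "farm_set"))
  config <- if (inherits(seed, "suite_config")) seed else
    suite_config(seed = seed)
  ids <- vapply(farms, `[[`, character(1), "farm_id")
  region <- vapply(farms, `[[`, character(1), "region")
  type <- vapply(farms, `[[`, character(1), "farm_type")
  organic <- type %in% c("YOF", "OOF")
  regions <- sort(unique(region))
  for (r in regions) {
    for (grp in c("OF", "CF")) {
      cnt <- sum(region == r & (organic == (grp == "OF")))
      if (cnt < 6)
        stop("stratum too small: ", cnt, " ", grp, " farms in region ", r,
             " (need >= 6)", call. = FALSE)
    }
  }
  spec <- function(label, rule, replicate, index, farm_ids) {
    structure(list(label = label, rule = rule, replicate = replicate,
                   seed = model_seed(config, index), farm_ids = farm_ids),
              class = "model_spec")
  }
  draw <- function(pool, size, sd) with_seed(sd, sample(pool, size))
  specs <- list(
    spec("Model 1", "all", NA_integer_, 1L, ids),
    spec("Model 2", "organic_only", NA_integer_, 2L, ids[organic]),
    spec("Model 3", "conventional_only", NA_integer_, 3L, ids[!organic]))
  for (i in 1:6) {
    sd_i <- model_seed(config, 3L + i)
    sel <- unlist(lapply(regions, function(r) c(
      draw(ids[region == r & organic], 6L, sd_i),
      draw(ids[region == r & !organic], 6L, sd_i + 50L))))
    specs[[3L + i]] <- spec(sprintf("Model %d", 3L + i), "balanced_resample",
                            i, 3L + i, sel)
  }
  for (i in 1:10) {
    sd_i <- model_seed(config, 9L + i)
    sel <- unlist(lapply(regions, function(r)
      draw(ids[region == r & organic], 6L, sd_i)))
    specs[[9L + i]] <- spec(sprintf("Model %d", 9L + i), "of_region_resample",
                            i, 9L + i, sel)
  }
  specs
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s [%s] n = %d\n", x$label, x$rule,
              length(x$farm_ids)))
  invisible(x)
}

#' Run the full model suite
#'
#' For every subset of [build_subsets()]: assemble the explanatory and
#' response matrices, drop columns that are constant within the subset
#' (they carry no information there and cannot be unit-variance scaled),
#' run the VIP filter-and-refit workflow, and collect the fit report.
#' Resampling summaries (mean and SD of overall R2Y(cum) and Q2Y(cum)) are
#' computed over the balanced draws (Models 4-9) and over the
#' organic-per-region draws (Models 10-19). Inside cross-validation the
#' tolerant scaling mode is used so that a dummy going constant within a
#' training fold does not abort a resampled model.
#'
#' @param farms A `farm_set`.
#' @param Y Response matrix with farm ids as row names.
#' @param config A [suite_config()].
#' @param verbose Print per-model progress (retained variables, metrics).
#' @return Object of class `suite_result`: `reports` (19 `fit_report`s),
#'   `fits` (the `vip_filter_fit` objects), `specs`, `summaries`.
#' @export
run_suite <- function(farms, Y, config = suite_config(), verbose = FALSE) {
  stopifnot(inherits(farms, "farm_set"), inherits(config, "suite_config"))
  specs <- build_subsets(farms, config)
  X_all <- design_matrix(farms)
  Y <- Y[rownames(X_all), , drop = FALSE]
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    Xi <- X_all[sp$farm_ids, , drop = FALSE]
    Yi <- Y[sp$farm_ids, , drop = FALSE]
    keep <- apply(Xi, 2, function(col) stats::sd(col) > 0)
    dropped <- colnames(Xi)[!keep]
    Xi <- Xi[, keep, drop = FALSE]
    res <- tryCatch(
      vip_filter_refit(Xi, Yi, threshold = config$threshold,
                       a_max = config$a_max, k = config$k, seed = sp$seed,
                       limit = config$limit, scale_y = config$scale_y,
                       on_constant = "keep", label = sp$label),
      error = function(e)
        stop(sp$label, ": ", conditionMessage(e), call. = FALSE))
    res$report$dropped <- dropped
    fits[[i]] <- res
    if (verbose)
      message(sprintf("%s (n = %d): A = %d, %d retained, R2Y = %.3f, Q2Y = %.3f",
                      sp$label, length(sp$farm_ids), res$report$ncomp,
                      length(res$retained), res$report$r2y_overall,
                      res$report$q2y_overall))
  }
  reports <- lapply(fits, `[[`, "report")
  summarize <- function(idx) {
    r2 <- vapply(reports[idx], `[[`, numeric(1), "r2y_overall")
    q2 <- vapply(reports[idx], `[[`, numeric(1), "q2y_overall")
    data.frame(models = paste(range(idx), collapse = "-"),
               n_models = length(idx),
               r2y_mean = mean(r2), r2y_sd = stats::sd(r2),
               q2y_mean = mean(q2), q2y_sd = stats::sd(q2))
  }
  summaries <- rbind(cbind(group = "balanced_resample", summarize(4:9)),
                     cbind(group = "of_region_resample", summarize(10:19)))
  structure(list(reports = reports, fits = fits, specs = specs,
                 summaries = summaries, config = config),
            class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("<suite_result> %d models\n", length(x$reports)))
  for (r in x$reports[1:3])
    cat(sprintf("  %s: n = %d, A = %d, %d vars, R2Y = %.3f, Q2Y = %.3f\n",
                r$label, r$n, r$ncomp, length(r$retained), r$r2y_overall,
                r$q2y_overall))
  s <- x$summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s (Models %s): R2Y = %.2f (SD %.2f), Q2Y = %.2f (SD %.2f)\n",
                s$group[i], s$models[i], s$r2y_mean[i], s$r2y_sd[i],
                s$q2y_mean[i], s$q2y_sd[i]))
  invisible(x)
}

#' Predicted-versus-observed table
#'
#' Tabulates, for one fitted model or every model of a suite, the observed
#' and model-predicted value of each response on each farm, plus the
#' per-response squared correlation between observed and predicted (the
#' R2 of the linear predicted-observed relationship).
#'
#' @param x A `vip_filter_fit` or `suite_result`.
#' @return List with `table` (farm, response, observed, predicted, and a
#'   model label for suites) and `r2_linear` (per response, per model for
#'   suites).
#' @export
predicted_vs_observed <- function(x) {
  one <- function(fit_res, label = fit_res$report$label) {
    pred <- predict(fit_res$fit, fit_res$X)
    obs <- fit_res$Y
    tab <- data.frame(
      model = label,
      farm_id = rep(rownames(obs) %||% seq_len(nrow(obs)), ncol(obs)),
      response = rep(colnames(obs), each = nrow(obs)),
      observed = as.vector(obs), predicted = as.vector(pred),
      stringsAsFactors = FALSE)
    r2l <- vapply(seq_len(ncol(obs)), function(j) {
      if (stats::sd(pred[, j]) == 0 || stats::sd(obs[, j]) == 0) return(0)
      stats::cor(obs[, j], pred[, j])^2
    }, numeric(1))
    names(r2l) <- colnames(obs)
    list(table = tab, r2_linear = r2l)
  }
  if (inherits(x, "vip_filter_fit")) return(one(x))
  stopifnot(inherits(x, "suite_result"))
  parts <- lapply(x$fits, one)
  list(table = do.call(rbind, lapply(parts, `[[`, "table")),
       r2_linear = do.call(rbind, lapply(parts, `[[`, "r2_linear")))
}

fmt <- function(x, digits = 6L) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

#' Write report tables to CSV
#'
#' Serializes a fit report or a suite result as tidy CSV files: `metrics.csv`
#' (one row per model and response: R2Y(cum), Q2Y(cum), RMSRE),
#' `overall.csv` (one row per model), `vip.csv` (one row per model and
#' variable, full-model VIP with the retained flag), `loadings.csv` (one
#' row per model, matrix role, name and component) and, for suites,
#' `resample_summary.csv` and `predicted_vs_observed.csv`. Numeric values
#' are written with 6 fixed decimal places, so re-reading reproduces the
#' formatted values exactly.
#'
#' @param x A `fit_report`, `vip_filter_fit` or `suite_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_report_tables <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  put <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, path)
  }
  metrics_rows <- function(rep) data.frame(
    model = rep$label, response = names(rep$r2y_resp), n = rep$n,
    ncomp = rep$ncomp,
    r2y_cum = fmt(rep$r2y_resp), q2y_cum = fmt(rep$q2y_resp),
    rmsre_pct = fmt(rep$rmsre_resp), stringsAsFactors = FALSE)
  overall_rows <- function(rep) data.frame(
    model = rep$label, n = rep$n, ncomp = rep$ncomp,
    n_retained = length(rep$retained),
    retained = paste(rep$retained, collapse = ";"),
    r2y_cum = fmt(rep$r2y_overall), q2y_cum = fmt(rep$q2y_overall),
    stringsAsFactors = FALSE)
  vip_rows <- function(fit_res) data.frame(
    model = fit_res$report$label, variable = names(fit_res$vip),
    vip = fmt(unclass(fit_res$vip)),
    retained = as.integer(names(fit_res$vip) %in% fit_res$retained),
    stringsAsFactors = FALSE)
  loading_rows <- function(fit_res) {
    tabs <- model_tables(fit_res$fit)
    lab <- fit_res$report$label
    rbind(
      data.frame(model = lab, role = "x_weight", name = tabs$weights$variable,
                 component = tabs$weights$component,
                 value = fmt(tabs$weights$value)),
      data.frame(model = lab, role = "x_loading",
                 name = tabs$x_loadings$variable,
                 component = tabs$x_loadings$component,
                 value = fmt(tabs$x_loadings$value)),
      data.frame(model = lab, role = "y_loading",
                 name = tabs$y_loadings$response,
                 component = tabs$y_loadings$component,
                 value = fmt(tabs$y_loadings$value)))
  }

  if (inherits(x, "fit_report")) {
    put(metrics_rows(x), "metrics.csv")
    put(overall_rows(x), "overall.csv")
  } else if (inherits(x, "vip_filter_fit")) {
    put(metrics_rows(x$report), "metrics.csv")
    put(overall_rows(x$report), "overall.csv")
    put(vip_rows(x), "vip.csv")
    put(loading_rows(x), "loadings.csv")
    pvo <- predicted_vs_observed(x)
    tab <- pvo$table
    tab$observed <- fmt(tab$observed); tab$predicted <- fmt(tab$predicted)
    put(tab, "predicted_vs_observed.csv")
  } else if (inherits(x, "suite_result")) {
    empty <- length(x$reports) == 0L
    if (empty) {
      put(metrics_rows(fit_report("x", character(0), character(0), 0L,
            list(overall = NA_real_,
                 per_response = stats::setNames(numeric(0), character(0))),
            stats::setNames(numeric(0), character(0)), NA_real_,
            stats::setNames(numeric(0), character(0))))[0, ], "metrics.csv")
    } else {
      put(do.call(rbind, lapply(x$reports, metrics_rows)), "metrics.csv")
      put(do.call(rbind, lapply(x$reports, overall_rows)), "overall.csv")
      put(do.call(rbind, lapply(x$fits, vip_rows)), "vip.csv")
      put(do.call(rbind, lapply(x$fits, loading_rows)), "loadings.csv")
      s <- x$summaries
      for (cn in c("r2y_mean", "r2y_sd", "q2y_mean", "q2y_sd"))
        s[[cn]] <- fmt(s[[cn]])
      put(s, "resample_summary.csv")
      pvo <- predicted_vs_observed(x)
      tab <- pvo$table
      tab$observed <- fmt(tab$observed); tab$predicted <- fmt(tab$predicted)
      put(tab, "predicted_vs_observed.csv")
    }
  } else stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
  invisible(paths)
}
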