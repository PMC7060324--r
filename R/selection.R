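#' Evaluate code with a local, restored RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Cross-validated predictive ability (Q2Y)
#'
#' K-fold cross-validation of a PLS model: rows are shuffled once (seeded)
#' and cut into K contiguous blocks whose sizes differ by at most one; for
#' every component count `a <= a_max` the model is refitted on each
#' training fold — preprocessing statistics recomputed inside the fold, so
#' no information leaks from held-out rows — and held-out rows predicted.
#' PRESS is accumulated on the full-data scaled response so it is
#' commensurate with the full fit's residual sums of squares.
#'
#' Per-component `Q2_a = 1 - PRESS_a / SS_{a-1}` with `SS_{a-1}` the
#' residual SS after `a - 1` components of the full fit; the cumulative
#' value is the multiplicative `1 - prod_a(PRESS_a / SS_{a-1})`. The simple
#' variant `1 - PRESS_A / SS_0` is also reported. Q2 is never floored at
#' zero: negative values indicate the model predicts worse than the
#' response mean.
#'
#' @param X,Y Raw (unscaled) matrices.
#' @param a_max Maximum number of components, at most
#'   `min(n - ceiling(n/k) - 1, p)`.
#' @param k Number of folds (default 7); `k = n` gives leave-one-out.
#' @param seed Seed for the fold shuffle.
#' @param scale_y Unit-variance scale Y (default `TRUE`).
#' @param on_constant Handling of fold-constant columns: `"error"`
#'   (default) fails naming the fold; `"keep"` centers without scaling.
#' @return An object of class `cv_result` with fold assignment, per
#'   component/response PRESS, and per-component and cumulative Q2Y
#'   (per response and overall).
#' @export
crossval_q2 <- function(X, Y, a_max, k = 7L, seed = 1L, scale_y = TRUE,
                        on_constant = c("error", "keep")) {
  on_constant <- match.arg(on_constant)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(Y)
  if (k > n) stop("k = ", k, " folds exceed n = ", n, " rows", call. = FALSE)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  a_cap <- min(n - ceiling(n / k) - 1L, ncol(X))
  if (a_max > a_cap)
    stop("a_max = ", a_max, " exceeds the cross-validation cap ", a_cap,
         call. = FALSE)
  # contiguous blocks over a seeded shuffle; sizes differ by at most one
  perm <- with_seed(seed, sample.int(n))
  sizes <- diff(round(seq(0, n, length.out = k + 1L)))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), times = sizes)

  sc_full <- center_scale(X, Y, scale_y = scale_y, on_constant = on_constant)
  full <- nipals_pls(sc_full$X, sc_full$Y, a_max)
  ss_prev_resp <- full$ssy_resid_resp[seq_len(a_max), , drop = FALSE]
  ss_prev_overall <- rowSums(ss_prev_resp)

  press <- matrix(0, a_max, m, dimnames = list(NULL, colnames(Y)))
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- setdiff(seq_len(n), test)
    sc <- tryCatch(
      center_scale(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                   scale_y = scale_y, on_constant = on_constant),
      error = function(e)
        stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    fit <- nipals_pls(sc$X, sc$Y, a_max)
    fit$preprocess <- sc$preprocess
    for (a in seq_len(a_max)) {
      pred <- predict(fit, X[test, , drop = FALSE], ncomp = a)
      pred_s <- sweep(sweep(pred, 2, sc_full$preprocess$y_center, "-"),
                      2, sc_full$preprocess$y_scale, "/")
      press[a, ] <- press[a, ] +
        colSums((sc_full$Y[test, , drop = FALSE] - pred_s)^2)
    }
  }
  press_overall <- rowSums(press)
  ratio_resp <- press / ss_prev_resp
  ratio_overall <- press_overall / ss_prev_overall
  structure(list(
    k = k, seed = seed, a_max = a_max, folds = fold_of,
    press = press, press_overall = press_overall,
    q2_comp = 1 - ratio_overall,
    q2_comp_resp = 1 - ratio_resp,
    q2_cum = 1 - cumprod(ratio_overall),
    q2_cum_resp = 1 - matrix(apply(ratio_resp, 2, cumprod), nrow = a_max,
                             dimnames = dimnames(ratio_resp)),
    q2_simple = 1 - press_overall / sum(full$ssy_resid_resp[1L, ]),
    ss_prev_resp = ss_prev_resp),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV (seed %s), a_max = %d\n", x$k,
              format(x$seed), x$a_max))
  cat("  per-component Q2Y:", sprintf("%.3f", x$q2_comp), "\n")
  cat("  cumulative   Q2Y:", sprintf("%.3f", x$q2_cum), "\n")
  invisible(x)
}

#' Choose the number of components from cross-validation
#'
#' Retains the largest `a` such that every component `1..a` has overall
#' per-component Q2 above `limit`; at least one component is always
#' retained, with a warning flag when even the first fails the rule.
#'
#' @param cv A [crossval_q2()] result.
#' @param limit Per-component significance limit (default 0.05).
#' @return List with `ncomp` (selected A), `flag_floor` (`TRUE` when the
#'   first component fell below the limit) and `q2_comp`.
#' @export
select_components <- function(cv, limit = 0.05) {
  stopifnot(inherits(cv, "cv_result"))
  ok <- cv$q2_comp > limit
  a <- if (all(ok)) length(ok) else which(!ok)[1L] - 1L
  list(ncomp = max(a, 1L), flag_floor = a < 1L, q2_comp = cv$q2_comp,
       limit = limit)
}

#' Variable importance in the projection
#'
#' For variable `j` over `A` components:
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`, with `SSY_a` the
#' Y-sum-of-squares explained by component `a` and `w_a` the unit-norm
#' X-weight vector. The mean of the squared VIP scores over variables is
#' exactly 1, so at least one variable always has `VIP >= 1`.
#'
#' @param model A `pls_model`.
#' @param ncomp Components to accumulate over (default: all fitted).
#' @return Named numeric vector of VIP scores (class `vip_result`).
#' @export
vip <- function(model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"), ncomp >= 1, ncomp <= model$ncomp)
  ssy <- model$ssy_comp[seq_len(ncomp)]
  if (sum(ssy) <= 0)
    stop("model explains no Y-variance; VIP undefined", call. = FALSE)
  W <- model$W[, seq_len(ncomp), drop = FALSE]
  p <- nrow(W)
  scores <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(scores) <- rownames(W)
  class(scores) <- "vip_result"
  scores
}

#' @export
print.vip_result <- function(x, ...) {
  v <- sort(unclass(x), decreasing = TRUE)
  cat(sprintf("<vip_result> %d variables, %d with VIP >= 1\n",
              length(v), sum(v >= 1)))
  print(round(utils::head(v, 10L), 3))
  invisible(x)
}

#' Root mean square relative error
#'
#' `RMSRE = 100 * sqrt( (1/N) * sum_i ((y_i - yhat_i) / y_i)^2 )`, in
#' percent. Relative error is used because the response indicators carry
#' different units and scales; it is undefined when any observed value is
#' zero.
#'
#' @param y Observed values (all nonzero).
#' @param yhat Predicted values, same length.
#' @return RMSRE in percent (scalar, `>= 0`; 0 iff `y == yhat`).
#' @export
rmsre <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (any(y == 0))
    stop("RMSRE undefined: observed value equal to zero", call. = FALSE)
  100 * sqrt(mean(((y - yhat) / y)^2))
}

#' Per-model fit report
#' @noRd
fit_report <- function(label, farm_ids, retained, ncomp, r2, q2_resp,
                       q2_overall, rmsre_resp, flag_floor = FALSE,
                       dropped = character(0)) {
  structure(list(label = label, n = length(farm_ids), farm_ids = farm_ids,
                 retained = retained, ncomp = ncomp,
                 r2y_overall = r2$overall, r2y_resp = r2$per_response,
                 q2y_overall = q2_overall, q2y_resp = q2_resp,
                 rmsre_resp = rmsre_resp, flag_floor = flag_floor,
                 dropped = dropped),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s: n = %d, A = %d, %d variables retained\n",
              x$label, x$n, x$ncomp, length(x$retained)))
  cat(sprintf("  R2Y(cum) = %.3f, Q2Y(cum) = %.3f\n",
              x$r2y_overall, x$q2y_overall))
  tab <- rbind(R2Y = x$r2y_resp, Q2Y = x$q2y_resp, RMSRE = x$rmsre_resp)
  print(round(tab, 3))
  invisible(x)
}

#' VIP filter-and-refit workflow
#'
#' The two-round variable selection procedure: (1) cross-validate the full
#' model, select the component count, fit, and compute VIP; (2) eliminate
#' every variable with VIP strictly below `threshold` (scores exactly at
#' the threshold are retained), refit on the survivors with its own
#' cross-validated component count, and report final metrics. The VIP
#' normalization identity guarantees the survivor set is never empty.
#' Exactly two rounds are run — no iteration to a fixed point — unless
#' `iterate = TRUE`, which repeats elimination until the retained set is
#' stable.
#'
#' @inheritParams crossval_q2
#' @param threshold VIP elimination threshold (default 1).
#' @param limit Per-component Q2 limit for [select_components()].
#' @param label Model label carried into the report.
#' @param iterate Iterate the filter to a fixed point (default `FALSE`).
#' @return List of class `vip_filter_fit`: `report` (a `fit_report`),
#'   `retained`, `vip` (full-model VIP scores), `fit` (final `pls_model`),
#'   `cv` (final `cv_result`), `fit_full`, `cv_full`, `X`, `Y`.
#' @export
vip_filter_refit <- function(X, Y, threshold = 1, a_max = 5L, k = 7L,
                             seed = 1L, limit = 0.05, scale_y = TRUE,
                             on_constant = c("error", "keep"),
                             label = "Model", iterate = FALSE) {
  on_constant <- match.arg(on_constant)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) < 2) stop("need at least 2 variables", call. = FALSE)
  n <- nrow(X)

  run_round <- function(Xr) {
    amx <- min(a_max, n - ceiling(n / k) - 1L, ncol(Xr))
    cv <- crossval_q2(Xr, Y, a_max = amx, k = k, seed = seed,
                      scale_y = scale_y, on_constant = on_constant)
    sel <- select_components(cv, limit)
    fit <- pls_fit(Xr, Y, ncomp = sel$ncomp, scale_y = scale_y,
                   on_constant = on_constant)
    list(cv = cv, sel = sel, fit = fit)
  }

  r1 <- run_round(X)
  v <- vip(r1$fit)
  retained <- names(v)[unclass(v) >= threshold]
  stopifnot(length(retained) >= 1L)  # guaranteed by the VIP identity
  repeat {
    r2_ <- run_round(X[, retained, drop = FALSE])
    if (!iterate) break
    v2 <- vip(r2_$fit)
    keep2 <- names(v2)[unclass(v2) >= threshold]
    if (identical(keep2, retained)) break
    retained <- keep2
  }
  fit2 <- r2_$fit
  sel2 <- r2_$sel
  fitted_vals <- predict(fit2, X[, retained, drop = FALSE])
  rms <- vapply(seq_len(ncol(Y)), function(j) rmsre(Y[, j], fitted_vals[, j]),
                numeric(1))
  names(rms) <- colnames(Y)
  q2_resp <- r2_$cv$q2_cum_resp[sel2$ncomp, ]
  report <- fit_report(
    label = label, farm_ids = rownames(X) %||% seq_len(n),
    retained = retained, ncomp = sel2$ncomp,
    r2 = r2y(fit2), q2_resp = q2_resp,
    q2_overall = r2_$cv$q2_cum[sel2$ncomp], rmsre_resp = rms,
    flag_floor = sel2$flag_floor)
  structure(list(report = report, retained = retained, vip = v,
                 fit = fit2, cv = r2_$cv, fit_full = r1$fit,
                 cv_full = r1$cv, X = X[, retained, drop = FALSE], Y = Y),
            class = "vip_filter_fit")
}

#' @export
print.vip_filter_fit <- function(x, ...) {
  print(x$report)
  invisible(x)
}
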