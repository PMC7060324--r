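#' Center and unit-variance scale training matrices
#'
#' Computes per-column means and standard deviations on the training data
#' and returns the scaled matrices together with a reusable preprocessing
#' model. All columns — including 0/1 dummies — are scaled to unit
#' variance, the convention of the chemometrics software this package
#' mirrors; the caveat that scaling inflates the influence of rare dummy
#' categories is accepted for fidelity and discussed in the vignette.
#'
#' @param X Numeric n x p matrix.
#' @param Y Optional numeric n x m matrix (scaled with its own statistics).
#' @param scale_y Scale Y columns to unit variance (default `TRUE`); when
#'   `FALSE`, Y is centered only.
#' @param on_constant `"error"` (default) stops on a zero-variance column,
#'   naming it; `"keep"` centers the column and records scale 1 — useful
#'   inside resampling where a dummy may go constant in a training split
#'   and then carries no information.
#' @return List with `X`, `Y` (scaled matrices) and `preprocess`, a
#'   `pls_preprocess` object storing the training statistics.
#' @export
center_scale <- function(X, Y = NULL, scale_y = TRUE,
                         on_constant = c("error", "keep")) {
  on_constant <- match.arg(on_constant)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to scale", call. = FALSE)
  stat <- function(M, do_scale, what) {
    ctr <- colMeans(M)
    scl <- apply(M, 2, stats::sd)
    bad <- which(scl <= 0 | !is.finite(scl))
    if (length(bad)) {
      if (on_constant == "error")
        stop("constant column in ", what, ": ",
             paste(colnames(M)[bad] %||% bad, collapse = ", "),
             call. = FALSE)
      scl[bad] <- 1
    }
    if (!do_scale) scl[] <- 1
    list(center = ctr, scale = scl,
         scaled = sweep(sweep(M, 2, ctr, "-"), 2, scl, "/"))
  }
  sx <- stat(X, TRUE, "X")
  pp <- structure(list(x_center = sx$center, x_scale = sx$scale,
                       y_center = NULL, y_scale = NULL),
                  class = "pls_preprocess")
  Ys <- NULL
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    sy <- stat(Y, scale_y, "Y")
    pp$y_center <- sy$center
    pp$y_scale <- sy$scale
    Ys <- sy$scaled
  }
  list(X = sx$scaled, Y = Ys, preprocess = pp)
}

scale_x <- function(pp, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(pp$x_center))
    stop("new data has ", ncol(X), " columns; model was trained on ",
         length(pp$x_center), call. = FALSE)
  if (!is.null(colnames(X)) && !is.null(names(pp$x_center)) &&
      !identical(colnames(X), names(pp$x_center)))
    stop("new data columns do not match training schema", call. = FALSE)
  sweep(sweep(X, 2, pp$x_center, "-"), 2, pp$x_scale, "/")
}

unscale_y <- function(pp, Ys) {
  sweep(sweep(Ys, 2, pp$y_scale, "*"), 2, pp$y_center, "+")
}

#' NIPALS multi-response PLS on pre-scaled matrices
#'
#' Extracts `ncomp` latent components from centered/scaled `Xs` and `Ys` by
#' the NIPALS algorithm with deflation of both matrices (classical PLS2; a
#' single-column `Ys` reduces to PLS1 through the same code path). Each
#' weight vector has unit norm and a deterministic sign (its
#' largest-magnitude element is positive), score vectors are mutually
#' orthogonal, and `Xs = T P' + E`, `Ys = T Q' + F` hold to numerical
#' precision.
#'
#' @param Xs,Ys Centered (and typically unit-variance scaled) matrices.
#' @param ncomp Number of latent components `A` (`<= min(n - 1, p)`).
#' @param tol Inner-loop convergence tolerance on the relative change of
#'   the Y-score vector `u`.
#' @param max_iter Inner-loop iteration cap per component. If the cap is
#'   reached — which happens only when the two leading covariance
#'   directions nearly tie, making power iteration arbitrarily slow — the
#'   component is completed by solving the loop's fixed-point problem
#'   exactly (symmetric eigendecomposition of the small `Y'XX'Y` matrix).
#' @return An object of class `pls_model`; see Details for slots.
#'
#' @details Slots: `W` (p x A X-weights), `P` (p x A X-loadings), `Q`
#'   (m x A Y-loadings), `T` (n x A X-scores), `U` (n x A Y-scores), `B`
#'   (p x m regression coefficients in scaled space), `E`, `F` (residuals),
#'   `ssx_comp`/`ssy_comp` (X- and Y-sum-of-squares explained per
#'   component), `r2x`/`r2y` (per-component fractions), `r2y_cum_resp`
#'   (A x m cumulative per-response R2Y), `ssy_resid_resp`
#'   ((A+1) x m per-response residual SS after 0..A components, used by
#'   cross-validation), `preprocess` (filled by [pls_fit()]).
#' @export
nipals_pls <- function(Xs, Ys, ncomp, tol = 1e-10, max_iter = 10000L) {
  Xs <- as.matrix(Xs); Ys <- as.matrix(Ys)
  n <- nrow(Xs); p <- ncol(Xs); m <- ncol(Ys)
  if (nrow(Ys) != n) stop("X and Y row counts differ", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be between 1 and min(n - 1, p) = ", min(n - 1, p),
         call. = FALSE)
  if (all(Xs == 0)) stop("X is all zero", call. = FALSE)
  ss_x_total <- sum(Xs^2)
  ss_y_total <- sum(Ys^2)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(Xs), NULL))
  P <- W
  Q <- matrix(0, m, ncomp, dimnames = list(colnames(Ys), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(Xs), NULL))
  U <- Tm
  ssx_comp <- ssy_comp <- numeric(ncomp)
  ssy_resid_resp <- matrix(0, ncomp + 1L, m,
                           dimnames = list(NULL, colnames(Ys)))
  ssy_resid_resp[1L, ] <- colSums(Ys^2)
  Xd <- Xs; Yd <- Ys
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var)), drop = TRUE]
    if (all(u == 0)) u <- Yd[, 1L]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      wn <- sqrt(sum(w^2))
      if (wn == 0)
        stop("component ", a, ": X carries no remaining covariance with Y",
             call. = FALSE)
      w <- w / wn
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      u_new <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) <= tol * sqrt(sum(u_new^2)) || m == 1L) {
        u <- u_new
        converged <- TRUE
        break
      }
      u <- u_new
    }
    if (!converged) {
      # the inner loop's fixed point is the dominant eigenvector of the
      # m x m matrix Yd'Xd Xd'Yd; power iteration converges arbitrarily
      # slowly when the leading eigenvalues nearly tie, so complete the
      # same fixed-point problem exactly
      C <- crossprod(Xd, Yd)
      v <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 1L]
      w <- drop(C %*% v)
      wn <- sqrt(sum(w^2))
      if (wn == 0)
        stop("component ", a, ": inner iteration failed to converge and ",
             "X carries no remaining covariance with Y", call. = FALSE)
      w <- w / wn
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      u <- drop(Yd %*% q) / sum(q^2)
    }
    # deterministic sign: largest-magnitude weight element positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; tt <- -tt; q <- -q; u <- -u
    }
    pp_ <- drop(crossprod(Xd, tt)) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp_)
    Yd <- Yd - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pp_; Q[, a] <- q; Tm[, a] <- tt; U[, a] <- u
    ssx_comp[a] <- sum(tt^2) * sum(pp_^2)
    ssy_comp[a] <- sum(tt^2) * sum(q^2)
    ssy_resid_resp[a + 1L, ] <- colSums(Yd^2)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  ss0_resp <- ssy_resid_resp[1L, ]
  r2y_cum_resp <- 1 - sweep(ssy_resid_resp[-1L, , drop = FALSE], 2,
                            pmax(ss0_resp, .Machine$double.eps), "/")
  structure(list(
    ncomp = ncomp, W = W, P = P, Q = Q, T = Tm, U = U, B = B,
    E = Xd, F = Yd,
    ss_x_total = ss_x_total, ss_y_total = ss_y_total,
    ssx_comp = ssx_comp, ssy_comp = ssy_comp,
    r2x = ssx_comp / ss_x_total, r2y = ssy_comp / ss_y_total,
    r2y_cum_resp = r2y_cum_resp,
    ssy_resid_resp = ssy_resid_resp,
    Xs = Xs, Ys = Ys,
    preprocess = NULL),
    class = "pls_model")
}

#' Fit a PLS model on raw matrices
#'
#' Convenience wrapper: centers and unit-variance scales `X` and `Y` (see
#' [center_scale()]), runs [nipals_pls()], and stores the preprocessing
#' model so that [predict.pls_model()] returns predictions in original
#' units.
#'
#' @inheritParams center_scale
#' @inheritParams nipals_pls
#' @param ... Passed to [nipals_pls()].
#' @return A `pls_model` with the preprocessing model attached.
#' @export
pls_fit <- function(X, Y, ncomp, scale_y = TRUE,
                    on_constant = c("error", "keep"), ...) {
  sc <- center_scale(X, Y, scale_y = scale_y,
                     on_constant = match.arg(on_constant))
  fit <- nipals_pls(sc$X, sc$Y, ncomp, ...)
  fit$preprocess <- sc$preprocess
  fit
}

#' @export
print.pls_model <- function(x, ...) {
  r2 <- cumsum(x$r2y)
  cat(sprintf("<pls_model> %d observations, %d X-variables, %d responses\n",
              nrow(x$T), nrow(x$W), nrow(x$Q)))
  cat(sprintf("  A = %d components; R2X(cum) = %.3f, R2Y(cum) = %.3f\n",
              x$ncomp, sum(x$r2x), r2[length(r2)]))
  invisible(x)
}

coef_ncomp <- function(model, ncomp) {
  if (ncomp == model$ncomp) return(model$B)
  idx <- seq_len(ncomp)
  model$W[, idx, drop = FALSE] %*%
    solve(crossprod(model$P[, idx, drop = FALSE],
                    model$W[, idx, drop = FALSE]),
          t(model$Q[, idx, drop = FALSE]))
}

#' Predict responses from a fitted PLS model
#'
#' New data are scaled with the *training* statistics, projected through
#' the coefficient matrix, and back-transformed to original response units.
#' Applied to the training matrix this reproduces the fitted values.
#'
#' @param object A `pls_model` fitted via [pls_fit()].
#' @param newdata Matrix (or single row) with the training columns.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Matrix of predictions in original units.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(object$preprocess))
    stop("model has no preprocessing attached; fit with pls_fit()",
         call. = FALSE)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  Xs <- scale_x(object$preprocess, newdata)
  unscale_y(object$preprocess, Xs %*% coef_ncomp(object, ncomp))
}

#' Explained Y-variation of a fitted model
#'
#' Per-response and overall cumulative R2Y on the scaled response matrix:
#' `1 - SS(residual) / SS(total)`.
#'
#' @param model A `pls_model`.
#' @param ncomp Components to account for (default: all fitted).
#' @return List with `overall` (scalar), `per_response` (named vector) and
#'   `per_component` (overall R2Y gained by each component).
#' @export
r2y <- function(model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"), ncomp >= 0, ncomp <= model$ncomp)
  if (ncomp == 0)
    return(list(overall = 0,
                per_response = stats::setNames(numeric(nrow(model$Q)),
                                               rownames(model$Q)),
                per_component = numeric(0)))
  list(overall = sum(model$ssy_comp[seq_len(ncomp)]) / model$ss_y_total,
       per_response = model$r2y_cum_resp[ncomp, ],
       per_component = model$r2y[seq_len(ncomp)])
}

#' Hotelling 95 percent region in the score plot
#'
#' Computes the Hotelling T-squared ellipse for a pair of score vectors:
#' the critical value is `k (n - 1) / (n - k)` times the F-quantile at
#' `1 - alpha` with `(k, n - k)` degrees of freedom (`k = 2` components),
#' and the ellipse semi-axes are the score standard deviations times the
#' square root of the critical value. Farms whose T-squared exceeds the
#' critical value lie outside the confidence region of the model.
#'
#' @param model A `pls_model` with at least two components.
#' @param alpha Significance level (default 0.05 for a 95 percent region).
#' @param comps Which two components to use (default first two).
#' @return Object of class `hotelling_ellipse`: `semi_axes`, `t2`
#'   (per-farm statistic), `crit`, `outside` (logical per farm).
#' @export
hotelling_ellipse <- function(model, alpha = 0.05, comps = c(1L, 2L)) {
  stopifnot(inherits(model, "pls_model"))
  if (model$ncomp < 2 || length(comps) != 2)
    stop("Hotelling ellipse requires a model with at least 2 components",
         call. = FALSE)
  S <- model$T[, comps, drop = FALSE]
  n <- nrow(S)
  k <- 2L
  v <- apply(S, 2, stats::var)
  t2 <- rowSums(sweep(S^2, 2, ifelse(v > 0, v, Inf), "/"))
  crit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  structure(list(semi_axes = sqrt(v * crit), t2 = t2, crit = crit,
                 alpha = alpha, comps = comps, outside = t2 > crit),
            class = "hotelling_ellipse")
}

#' @export
print.hotelling_ellipse <- function(x, ...) {
  cat(sprintf(
    "<hotelling_ellipse> alpha = %g, crit T2 = %.3f, %d/%d outside\n",
    x$alpha, x$crit, sum(x$outside), length(x$outside)))
  invisible(x)
}

#' Export model matrices as tidy tables
#'
#' @param model A `pls_model`.
#' @return List of data frames: `weights`, `x_loadings`, `y_loadings`,
#'   `scores` — one row per (variable or farm, component) — and `scalars`
#'   (per-component variance accounting).
#' @export
model_tables <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  long <- function(M, dim1) {
    data.frame(dim1 = rep(rownames(M) %||% seq_len(nrow(M)), model$ncomp),
               component = rep(seq_len(model$ncomp), each = nrow(M)),
               value = as.vector(M[, seq_len(model$ncomp), drop = FALSE]),
               stringsAsFactors = FALSE)
  }
  w <- long(model$W); names(w)[1] <- "variable"
  p <- long(model$P); names(p)[1] <- "variable"
  q <- long(model$Q); names(q)[1] <- "response"
  tt <- long(model$T); names(tt)[1] <- "farm_id"
  scal <- data.frame(component = seq_len(model$ncomp),
                     r2x = model$r2x, r2y = model$r2y,
                     r2x_cum = cumsum(model$r2x), r2y_cum = cumsum(model$r2y))
  list(weights = w, x_loadings = p, y_loadings = q, scores = tt,
       scalars = scal)
}
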