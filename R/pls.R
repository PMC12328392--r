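# From-scratch latent-variable regression: NIPALS-PLS1 and OPLS with a
# single scalar response (the RACI), plus leave-one-out cross-validation and
# the standard chemometric fit metrics.

prepare_xy <- function(X, y, scale_mode) {
  fm <- NULL
  if (inherits(X, "fingerprint_matrix")) {
    fm <- X
    X <- fm$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("Response `y` is constant.", call. = FALSE)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  x_scale <- rep(1, ncol(X))
  if (scale_mode == "autoscale") {
    x_scale <- apply(X, 2, stats::sd)
    if (any(x_scale == 0)) {
      stop("Autoscaling impossible: constant predictor column(s).",
        call. = FALSE
      )
    }
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  list(
    Xc = Xc, x_mean = x_mean, x_scale = x_scale,
    y = y, y_mean = mean(y), yc = y - mean(y),
    time_min = if (!is.null(fm)) fm$time_min else NULL,
    wavelength_nm = if (!is.null(fm)) fm$wavelength_nm else NA_integer_
  )
}

# one NIPALS component for a single-column response; the inner loop converges
# immediately for scalar y but the iteration cap mirrors the general scheme
nipals_component <- function(Xc, yc, max_iter = 500L, tol = 1e-12) {
  w <- drop(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("NIPALS weight vector collapsed to zero.", call. = FALSE)
  w <- w / nw
  for (it in seq_len(max_iter)) {
    t_ <- drop(Xc %*% w)
    q <- sum(yc * t_) / sum(t_^2)
    u <- yc / q
    w_new <- drop(crossprod(Xc, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    delta <- sqrt(sum((w_new - w)^2))
    w <- w_new
    if (delta < tol) break
    if (it == max_iter) {
      stop(sprintf("NIPALS failed to converge within %d iterations.", max_iter),
        call. = FALSE
      )
    }
  }
  t_ <- drop(Xc %*% w)
  p <- drop(crossprod(Xc, t_)) / sum(t_^2)
  q <- sum(yc * t_) / sum(t_^2)
  list(w = w, t = t_, p = p, q = q)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares with a scalar response, extracted component by
#' component with NIPALS deflation. Deterministic: the weight vector is
#' initialised from `X'y`, never randomly. Regression coefficients on the
#' original (centred) predictors are recovered through the closed form
#' `B = W (P'W)^{-1} q`, so `predict()` reproduces the sequential NIPALS
#' predictions exactly.
#'
#' @param X Predictor matrix (samples x variables) or a
#'   `fingerprint_matrix`.
#' @param y Response vector (e.g. RACI per sample).
#' @param n_components Number of latent variables (default 2).
#' @param scale_mode `"center"` (default; mean-centring only, standard for
#'   chromatographic profiles) or `"autoscale"` (unit variance columns).
#' @return An object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, coefficients `B`, centring/scaling vectors,
#'   per-component explained X-variance `r2x_per_component`, and grid
#'   metadata when fitted on a `fingerprint_matrix`.
#' @export
fit_pls <- function(X, y, n_components = 2L, scale_mode = c("center", "autoscale")) {
  scale_mode <- match.arg(scale_mode)
  pp <- prepare_xy(X, y, scale_mode)
  n <- nrow(pp$Xc)
  p <- ncol(pp$Xc)
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, p)) {
    stop(sprintf(
      "`n_components` must lie in [1, min(n-1, p)] = [1, %d].", min(n - 1, p)
    ), call. = FALSE)
  }
  ssx_total <- sum(pp$Xc^2)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  r2x <- numeric(A)
  Xd <- pp$Xc
  yd <- pp$yc
  for (a in seq_len(A)) {
    cmp <- nipals_component(Xd, yd)
    W[, a] <- cmp$w
    P[, a] <- cmp$p
    Tm[, a] <- cmp$t
    q[a] <- cmp$q
    r2x[a] <- sum(cmp$t^2) * sum(cmp$p^2) / ssx_total
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    yd <- yd - cmp$q * cmp$t
  }
  B <- drop(W %*% solve(crossprod(P, W), q))
  structure(
    list(
      kind = "pls",
      x_mean = pp$x_mean, x_scale = pp$x_scale, y_mean = pp$y_mean,
      scale_mode = scale_mode,
      W = W, P = P, T = Tm, q = q, B = B,
      n_components = A, n_orthogonal = 0L,
      r2x_per_component = r2x,
      fitted = drop(pp$Xc %*% B) + pp$y_mean,
      y = pp$y,
      time_min = pp$time_min,
      wavelength_nm = pp$wavelength_nm
    ),
    class = "pls_model"
  )
}

#' Fit an OPLS regression
#'
#' Orthogonal projections to latent structures with a scalar response:
#' variation in `X` orthogonal to `y` is peeled off into `n_orthogonal`
#' components (weight direction `p - (w'p) w`, the orthogonal-filtering
#' construction), after which a single predictive PLS component is fitted on
#' the filtered matrix. The orthogonal scores are uncorrelated with `y` by
#' construction. With `n_orthogonal = 0` the fit is identical to a
#' one-component PLS.
#'
#' @inheritParams fit_pls
#' @param n_orthogonal Number of orthogonal components (>= 0, default 1).
#' @return An object of classes `opls_model` and `pls_model`, with the
#'   additional orthogonal block `W_o`, `P_o`, `T_o` and
#'   `r2x_orthogonal`.
#' @export
fit_opls <- function(X, y, n_orthogonal = 1L, scale_mode = c("center", "autoscale")) {
  scale_mode <- match.arg(scale_mode)
  pp <- prepare_xy(X, y, scale_mode)
  n <- nrow(pp$Xc)
  p <- ncol(pp$Xc)
  k <- as.integer(n_orthogonal)
  if (k < 0) stop("`n_orthogonal` must be >= 0.", call. = FALSE)
  if (k + 1 > min(n - 1, p)) {
    stop("Too many orthogonal components for the data size.", call. = FALSE)
  }
  ssx_total <- sum(pp$Xc^2)
  w <- drop(crossprod(pp$Xc, pp$yc))
  w <- w / sqrt(sum(w^2))
  Xd <- pp$Xc
  W_o <- matrix(0, p, k)
  P_o <- matrix(0, p, k)
  T_o <- matrix(0, n, k)
  r2x_o <- numeric(k)
  for (j in seq_len(k)) {
    t_ <- drop(Xd %*% w)
    p_ <- drop(crossprod(Xd, t_)) / sum(t_^2)
    w_o <- p_ - sum(w * p_) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) {
      stop("No orthogonal variation left to extract.", call. = FALSE)
    }
    w_o <- w_o / nw
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    W_o[, j] <- w_o
    P_o[, j] <- p_o
    T_o[, j] <- t_o
    r2x_o[j] <- sum(t_o^2) * sum(p_o^2) / ssx_total
    Xd <- Xd - tcrossprod(t_o, p_o)
  }
  cmp <- nipals_component(Xd, pp$yc)
  r2x_pred <- sum(cmp$t^2) * sum(cmp$p^2) / ssx_total

  # coefficients on the original centred X: compose the orthogonal filters
  # (I - w_o p_o') right-to-left onto the predictive direction
  v <- cmp$w * cmp$q
  if (k > 0) {
    for (j in rev(seq_len(k))) {
      v <- v - W_o[, j] * sum(P_o[, j] * v)
    }
  }
  B <- v
  structure(
    list(
      kind = "opls",
      x_mean = pp$x_mean, x_scale = pp$x_scale, y_mean = pp$y_mean,
      scale_mode = scale_mode,
      W = matrix(cmp$w, ncol = 1), P = matrix(cmp$p, ncol = 1),
      T = matrix(cmp$t, ncol = 1), q = cmp$q, B = B,
      W_o = W_o, P_o = P_o, T_o = T_o,
      n_components = 1L, n_orthogonal = k,
      r2x_per_component = c(r2x_pred, r2x_o),
      fitted = drop(pp$Xc %*% B) + pp$y_mean,
      y = pp$y,
      time_min = pp$time_min,
      wavelength_nm = pp$wavelength_nm
    ),
    class = c("opls_model", "pls_model")
  )
}

#' Predict from a fitted PLS/OPLS model
#'
#' @param object A `pls_model` or `opls_model`.
#' @param newdata New predictor matrix (same columns as training) or
#'   `fingerprint_matrix`; defaults to the training fitted values.
#' @param ... Unused.
#' @return Predicted response vector `(x - x_mean) . B + y_mean`.
#' @export
predict.pls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  X <- if (inherits(newdata, "fingerprint_matrix")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop(sprintf(
      "`newdata` has %d columns; the model was trained on %d.",
      ncol(X), length(object$x_mean)
    ), call. = FALSE)
  }
  Xc <- sweep(X, 2, object$x_mean)
  if (object$scale_mode == "autoscale") {
    Xc <- sweep(Xc, 2, object$x_scale, "/")
  }
  drop(Xc %*% object$B) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "<%s_model> %d predictive component(s)%s, %d predictors, R2X = %.3f\n",
    x$kind, x$n_components,
    if (x$n_orthogonal > 0) sprintf(" + %d orthogonal", x$n_orthogonal) else "",
    length(x$B), sum(x$r2x_per_component)
  ))
  invisible(x)
}

#' Leave-one-out cross-validation for PLS/OPLS
#'
#' Refits the model on every leave-one-out fold (re-centring, and re-scaling
#' under autoscaling, inside the fold) and predicts the held-out sample.
#'
#' @param X Predictor matrix or `fingerprint_matrix`.
#' @param y Response vector (n >= 3).
#' @param method `"pls"` or `"opls"`.
#' @param n_components Latent variables for PLS.
#' @param n_orthogonal Orthogonal components for OPLS.
#' @param scale_mode `"center"` or `"autoscale"`.
#' @return A list of class `cv_result`: `y_hat_cv`, `rmsecv`
#'   (`sqrt(PRESS/n)`), `mse_cv`, `q2` (`1 - PRESS/TSS`, TSS about the
#'   full-data mean), `press`.
#' @export
loo_cv <- function(X, y, method = c("pls", "opls"), n_components = 2L,
                   n_orthogonal = 1L, scale_mode = "center") {
  method <- match.arg(method)
  Xm <- if (inherits(X, "fingerprint_matrix")) X$X else as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(Xm)
  stopifnot(n == length(y))
  if (n < 3) stop("Need at least 3 samples for LOO-CV.", call. = FALSE)
  y_hat <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (stats::sd(yi) == 0) {
      stop(sprintf("Fold %d has a constant response.", i), call. = FALSE)
    }
    fit <- if (method == "pls") {
      fit_pls(Xm[-i, , drop = FALSE], yi, n_components, scale_mode)
    } else {
      fit_opls(Xm[-i, , drop = FALSE], yi, n_orthogonal, scale_mode)
    }
    y_hat[i] <- predict(fit, Xm[i, , drop = FALSE])
  }
  press <- sum((y - y_hat)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      y_hat_cv = y_hat,
      rmsecv = sqrt(press / n),
      mse_cv = press / n,
      q2 = 1 - press / tss,
      press = press
    ),
    class = "cv_result"
  )
}

#' Chemometric fit metrics
#'
#' Standard calibration and cross-validation diagnostics: per-component and
#' total explained X-variance, R2Y, MSE and RMSE of calibration, the ratio of
#' performance to deviation `RPD = sd(y) / RMSE` (sample sd, n-1), and the
#' corresponding CV quantities when a `cv_result` is supplied. A perfect fit
#' reports `rpd_cal = Inf`.
#'
#' @param model A fitted `pls_model`/`opls_model`.
#' @param X Training predictors (matrix or `fingerprint_matrix`).
#' @param y Training response.
#' @param cv Optional `cv_result` from [loo_cv()].
#' @return A one-row tibble of class `fit_metrics`.
#' @export
fit_metrics <- function(model, X, y, cv = NULL) {
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("Response has zero variance.", call. = FALSE)
  y_hat <- predict(model, X)
  stopifnot(length(y_hat) == length(y))
  rss <- sum((y - y_hat)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  mse_cal <- rss / n
  rmsec <- sqrt(mse_cal)
  sd_y <- stats::sd(y)
  out <- tibble::tibble(
    kind = model$kind,
    n_components = model$n_components,
    n_orthogonal = model$n_orthogonal,
    r2x_total = sum(model$r2x_per_component),
    r2y = 1 - rss / tss,
    mse_cal = mse_cal,
    rmsec = rmsec,
    rpd_cal = if (rmsec <= 1e-10 * sd_y) Inf else sd_y / rmsec,
    rmsecv = NA_real_,
    mse_cv = NA_real_,
    q2 = NA_real_,
    rpd_cv = NA_real_
  )
  if (!is.null(cv)) {
    out$rmsecv <- cv$rmsecv
    out$mse_cv <- cv$mse_cv
    out$q2 <- cv$q2
    out$rpd_cv <- if (cv$rmsecv <= 1e-10 * sd_y) Inf else sd_y / cv$rmsecv
  }
  attr(out, "r2x_per_component") <- model$r2x_per_component
  class(out) <- c("fit_metrics", class(out))
  out
}

#' Regression coefficients aligned to retention time
#'
#' @param model A `pls_model` fitted on a `fingerprint_matrix` (so retention
#'   times are available).
#' @return A tibble with columns `time_min` and `coefficient`.
#' @export
regression_coefficients <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$time_min)) {
    stop(paste0(
      "Model carries no retention-time grid; fit it on a ",
      "`fingerprint_matrix` to align coefficients."
    ), call. = FALSE)
  }
  tibble::tibble(
    time_min = model$time_min,
    coefficient = model$B / model$x_scale
  )
}
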