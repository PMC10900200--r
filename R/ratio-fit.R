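#' Construct a kinetic series of Z/E signal integrals
#'
#' Container for a monitored balance experiment: HSQC cross-peak integrals of
#' the Z- and E-enamine against evolution time. Both integrals are assumed to
#' share one proportionality constant to concentration, so their ratio equals
#' the concentration ratio.
#'
#' @param t times (min), strictly increasing
#' @param z_signal,e_signal non-negative signal integrals (arbitrary units)
#' @param meta optional named list of labels (balance_id, solvent, aldehyde,
#'   counterion)
#' @return a `kinetic_series` data frame with columns
#'   `t_min, z_integral, e_integral`
#' @export
kinetic_series <- function(t, z_signal, e_signal, meta = list()) {
  if (length(t) != length(z_signal) || length(t) != length(e_signal))
    stop("t, z_signal and e_signal must have equal length", call. = FALSE)
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(z_signal)) || any(!is.finite(e_signal)) ||
      any(z_signal < 0) || any(e_signal < 0))
    stop("signals must be finite and >= 0", call. = FALSE)
  structure(data.frame(t_min = t, z_integral = z_signal, e_integral = e_signal),
            meta = meta, class = c("kinetic_series", "data.frame"))
}

#' Build a Z/E ratio curve from a kinetic series
#'
#' Divides the Z integral by the E integral pointwise, excluding points where
#' the E signal (the denominator) falls below `min_signal_fraction` of its
#' maximum. Early points, where the enamines have barely formed, would
#' otherwise contribute ratios dominated by noise or by division by zero.
#'
#' @param series a [kinetic_series()]
#' @param min_signal_fraction points with
#'   `e_integral < min_signal_fraction * max(e_integral)` are dropped
#'   (default 0.02)
#' @return data frame with columns `t_min` and `ratio`; attribute `meta`
#'   carried over
#' @export
build_ratio_series <- function(series, min_signal_fraction = 0.02) {
  if (!inherits(series, "kinetic_series"))
    series <- kinetic_series(series$t_min, series$z_integral, series$e_integral)
  keep <- series$e_integral >= min_signal_fraction * max(series$e_integral)
  if (sum(keep) < 4L)
    stop("insufficient data: fewer than 4 points with usable E signal",
         call. = FALSE)
  curve <- data.frame(t_min = series$t_min[keep],
                      ratio = series$z_integral[keep] / series$e_integral[keep])
  if (any(!is.finite(curve$ratio)))
    stop("ratio curve contains non-finite values", call. = FALSE)
  attr(curve, "meta") <- attr(series, "meta")
  curve
}

# Evaluate the n-exponential ratio model at times t given a parameter vector
# c(keq, A1, c1[, A2, c2]).
.ratio_model <- function(par, t) {
  v <- rep(par[1], length(t))
  n <- (length(par) - 1L) / 2L
  for (i in seq_len(n)) v <- v + par[2 * i] * exp(-t / par[2 * i + 1])
  v
}

# Parameter transform: the optimizer works unconstrained on
# (log keq, A_i, qlogis(c_i / cmax)); keq stays positive and every timescale
# stays inside (0, cmax]. A timescale much longer than the observation span
# is indistinguishable from a shift of the asymptote, so bounding c protects
# the keq estimate.
.to_internal <- function(par, cmax) {
  p <- par
  p[1] <- log(max(par[1], 1e-10))
  ci <- seq(3, length(par), by = 2)
  p[ci] <- stats::qlogis(pmin(pmax(par[ci] / cmax, 1e-6), 0.99))
  p
}

.to_natural <- function(p, cmax) {
  par <- p
  par[1] <- exp(p[1])
  ci <- seq(3, length(p), by = 2)
  par[ci] <- cmax * stats::plogis(p[ci])
  par
}

# One Levenberg-Marquardt attempt on the transformed parameters; returns
# list(par, sse, converged) or NULL on failure. Uses the residual-function
# interface of nls.lm: the two exponential components can collapse onto one
# another (c1 ~ c2, or an amplitude at zero), which leaves the final
# Jacobian singular even though the least-squares solution is good, so no
# nls model object is ever constructed.
.try_nls <- function(t, y, start, cmax) {
  p0 <- .to_internal(unname(start), cmax)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) y - .ratio_model(.to_natural(p, cmax), t),
                       control = minpack.lm::nls.lm.control(maxiter = 1024,
                                                            maxfev = 100000)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  par <- .to_natural(unlist(fit$par), cmax)
  names(par) <- names(start)
  list(par = par, sse = sum(fit$fvec^2), converged = fit$info %in% 1:4)
}

#' Fit the exponential ratio model to a Z/E ratio curve
#'
#' Fits, by nonlinear least squares, the model the ratio curve follows as the
#' balance equilibrates:
#' \deqn{[Z]/[E] = K_{eq} + A e^{-t/c}}
#' or, for curves with two resolvable relaxation modes,
#' \deqn{[Z]/[E] = K_{eq} + A_1 e^{-t/c_1} + A_2 e^{-t/c_2}.}
#' The fitted asymptote estimates the Z/E equilibrium constant and the
#' extrapolated t = 0 value, `keq + sum(A)`, estimates the initial flux ratio
#' k1Z/k1E. Keq and the timescales are constrained positive. Initial guesses
#' are taken from the data (asymptote from the last point, amplitude from
#' first minus last, timescale a third of the span); on non-convergence five
#' deterministically perturbed restarts are attempted and the best converged
#' solution kept.
#'
#' @param curve data frame with columns `t_min` and `ratio`
#'   (from [build_ratio_series()]), or a [kinetic_series()]
#' @param n_exponentials 1 or 2
#' @return an object of class `ratio_fit`; see [coef.ratio_fit()],
#'   [predict.ratio_fit()], [summary.ratio_fit()]
#' @examples
#' t <- seq(0, 400, length.out = 20)
#' curve <- data.frame(t_min = t, ratio = 8 - 6 * exp(-t / 50))
#' fit_ratio_exponential(curve, 1)
#' @export
fit_ratio_exponential <- function(curve, n_exponentials = 1) {
  if (inherits(curve, "kinetic_series")) curve <- build_ratio_series(curve)
  stopifnot(is.data.frame(curve), all(c("t_min", "ratio") %in% names(curve)))
  n_exponentials <- as.integer(n_exponentials)
  if (!n_exponentials %in% 1:2)
    stop("'n_exponentials' must be 1 or 2", call. = FALSE)
  t <- curve$t_min; y <- curve$ratio
  npt <- length(t)
  need <- if (n_exponentials == 1L) 4L else 6L
  if (npt < need)
    stop("insufficient data: need at least ", need, " points for ",
         n_exponentials, " exponential(s)", call. = FALSE)

  span <- max(t) - min(t)
  keq0 <- max(y[npt], 1e-8)
  amp0 <- y[1] - y[npt]

  # flat curve: the exponential term is unidentifiable; report the mean
  if (diff(range(y)) <= 1e-10 * max(1, abs(mean(y)))) {
    par <- if (n_exponentials == 1L)
      c(keq = mean(y), A1 = 0, c1 = span / 3)
    else c(keq = mean(y), A1 = 0, c1 = span / 3, A2 = 0, c2 = span)
    return(.ratio_fit_result(par, t, y, n_exponentials, TRUE,
                             attr(curve, "meta")))
  }

  cmax <- 5 * span
  if (n_exponentials == 1L) {
    start <- c(keq = keq0, A1 = amp0, c1 = span / 3)
    best <- .try_nls(t, y, start, cmax)
  } else {
    # sigmoidal ratio curves (an induction period before the rise) need
    # opposite-sign amplitudes, so several start patterns are explored
    starts <- list(
      c(keq = keq0, A1 = 0.7 * amp0, c1 = span / 10,
        A2 = 0.3 * amp0, c2 = span / 2),
      c(keq = keq0, A1 = -1.5 * abs(amp0), c1 = span / 20,
        A2 = amp0 + 1.5 * abs(amp0), c2 = span / 4),
      c(keq = keq0, A1 = 1.5 * abs(amp0), c1 = span / 20,
        A2 = amp0 - 1.5 * abs(amp0), c2 = span / 4))
    start <- starts[[1]]
    best <- NULL
    for (s in starts) {
      cand <- .try_nls(t, y, s, cmax)
      if (!is.null(cand) &&
          (is.null(best) || (cand$converged && !best$converged) ||
           (cand$converged == best$converged && cand$sse < best$sse)))
        best <- cand
    }
  }
  if (is.null(best) || !best$converged) {
    # deterministic multi-start: fixed multiplicative perturbations
    perturb <- list(c(1, 1, 0.3), c(1, 1, 3), c(1.5, 0.5, 1),
                    c(0.7, 1.5, 0.1), c(1, -1, 1))
    for (p in perturb) {
      s2 <- start
      s2["keq"] <- start["keq"] * p[1]
      s2[grep("^A", names(s2))] <- start[grep("^A", names(start))] * p[2]
      s2[grep("^c", names(s2))] <- start[grep("^c", names(start))] * abs(p[3])
      cand <- .try_nls(t, y, s2, cmax)
      if (!is.null(cand) &&
          (is.null(best) || (cand$converged && !best$converged) ||
           (cand$converged == best$converged && cand$sse < best$sse)))
        best <- cand
      if (!is.null(best) && best$converged) break
    }
  }
  if (is.null(best))
    return(.ratio_fit_result(c(keq = keq0,
                               stats::setNames(rep(c(0, span / 3),
                                                   n_exponentials),
                                               paste0(rep(c("A", "c"),
                                                          n_exponentials),
                                                      rep(1:n_exponentials,
                                                          each = 2)))),
                             t, y, n_exponentials, FALSE, attr(curve, "meta")))
  .ratio_fit_result(best$par, t, y, n_exponentials, isTRUE(best$converged),
                    attr(curve, "meta"))
}

.ratio_fit_result <- function(par, t, y, n_exp, converged, meta = NULL) {
  if (n_exp == 2L && all(c("c1", "c2") %in% names(par)) &&
      par[["c2"]] < par[["c1"]]) {   # report timescales in increasing order
    par <- par[c("keq", "A2", "c2", "A1", "c1")]
    names(par) <- c("keq", "A1", "c1", "A2", "c2")
  }
  fitted <- .ratio_model(unname(par), t)
  amps <- par[grep("^A", names(par))]
  structure(list(
    keq = unname(par[["keq"]]),
    amplitudes = unname(amps),
    timescales = unname(par[grep("^c", names(par))]),
    initial_ratio = max(unname(par[["keq"]]) + sum(amps), 0),
    n_exponentials = n_exp,
    residual_sse = sum((y - fitted)^2),
    converged = converged,
    coefficients = par,
    data = data.frame(t_min = t, ratio = y),
    fitted_values = fitted,
    meta = meta), class = "ratio_fit")
}

# Corrected AIC under iid Gaussian residuals; k counts model parameters
# plus the residual variance.
.aicc <- function(sse, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a ratio curve, choosing one or two exponentials
#'
#' Fits both the single- and double-exponential ratio models and keeps the
#' single-exponential fit unless the double fit lowers the corrected AIC by
#' more than 2 — the single form is adequate for most curves, but some rate
#' combinations produce two resolvable relaxation modes.
#'
#' @inheritParams fit_ratio_exponential
#' @return a `ratio_fit` object with `n_exponentials` set to the selected form
#' @export
select_fit <- function(curve) {
  if (inherits(curve, "kinetic_series")) curve <- build_ratio_series(curve)
  if (nrow(curve) < 6L)
    stop("insufficient data: model selection needs at least 6 points",
         call. = FALSE)
  f1 <- fit_ratio_exponential(curve, 1)
  f2 <- tryCatch(fit_ratio_exponential(curve, 2), error = function(e) NULL)
  if (is.null(f2) || !f2$converged) return(f1)
  n <- nrow(curve)
  a1 <- .aicc(f1$residual_sse, n, 4)
  a2 <- .aicc(f2$residual_sse, n, 6)
  # guard the log of a numerically zero SSE on exact single-exponential data
  if (f1$residual_sse <= 1e-20 * max(1, sum(curve$ratio^2))) return(f1)
  if (a1 - a2 > 2) f2 else f1
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf(
    "Z/E ratio fit (%d exponential%s)%s\n", x$n_exponentials,
    if (x$n_exponentials > 1) "s" else "",
    if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  Keq           = %.6g\n", x$keq))
  for (i in seq_along(x$amplitudes))
    cat(sprintf("  A%d = %.6g   c%d = %.6g min\n",
                i, x$amplitudes[i], i, x$timescales[i]))
  cat(sprintf("  initial Z/E   = %.6g (extrapolated t = 0)\n", x$initial_ratio))
  cat(sprintf("  SSE           = %.4g over %d points\n",
              x$residual_sse, nrow(x$data)))
  invisible(x)
}

#' @export
summary.ratio_fit <- function(object, temperature = 293, ...) {
  tier <- assign_keq_error_tier(object$keq)
  out <- list(fit = object, temperature = temperature,
              keq_rel_error = tier,
              dG_ZE = delta_g_from_keq(object$keq, temperature),
              dG_ZE_err = dg_error_from_keq_error(tier, temperature))
  class(out) <- "summary.ratio_fit"
  out
}

#' @export
print.summary.ratio_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Keq error tier = %.1f%% (duplicate-based tiers)\n",
              100 * x$keq_rel_error))
  cat(sprintf("  dG(Z/E) at %g K = %.4g +/- %.4g kcal/mol\n",
              x$temperature, x$dG_ZE, x$dG_ZE_err))
  invisible(x)
}

#' @export
coef.ratio_fit <- function(object, ...) object$coefficients

#' Predict the fitted ratio curve
#' @param object a `ratio_fit`
#' @param t times (min) at which to evaluate; defaults to the fitting times
#' @param ... unused
#' @export
predict.ratio_fit <- function(object, t = object$data$t_min, ...) {
  .ratio_model(unname(object$coefficients), t)
}

#' @export
residuals.ratio_fit <- function(object, ...) {
  object$data$ratio - object$fitted_values
}

#' @export
fitted.ratio_fit <- function(object, ...) object$fitted_values

#' Plot a fitted Z/E ratio curve
#' @param x a `ratio_fit`
#' @param ... passed to [plot()]
#' @export
plot.ratio_fit <- function(x, ...) {
  plot(x$data$t_min, x$data$ratio, xlab = "time (min)", ylab = "[Z]/[E]",
       pch = 16, ...)
  tt <- seq(min(x$data$t_min), max(x$data$t_min), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3")
  graphics::abline(h = x$keq, lty = 3)
  invisible(x)
}
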