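#' Simulate the enamine-balance reaction network
#'
#' Deterministic mass-action integration of the three-reaction network
#'
#' \deqn{A + L \rightleftharpoons I \rightleftharpoons Z, \quad
#'       I \rightleftharpoons E}
#'
#' with ODEs
#' dA/dt = dL/dt = -k1 A L + k_m1 I;
#' dI/dt = k1 A L - (k_m1 + k1Z + k1E) I + k_m1Z Z + k_m1E E;
#' dZ/dt = k1Z I - k_m1Z Z; dE/dt = k1E I - k_m1E E.
#'
#' Integration uses a stiff-capable solver (lsoda) with rtol 1e-10 and
#' atol 1e-13 M, because realistic rate constants span four or more orders
#' of magnitude. Both mass totals (amine: A + I + Z + E; aldehyde:
#' L + I + Z + E) are conserved by the model and checked after integration.
#'
#' @param rates a [rate_constants()] object
#' @param a0 initial free amine concentration (M), default 1 mM
#' @param l0 initial free aldehyde concentration (M), default 0.5 mM
#' @param time_grid strictly increasing output times in minutes, starting at 0
#' @param init optional named vector overriding the initial state
#'   (A, L, I, Z, E); default starts from free reagents only
#' @return a `balance_trajectory`: a data frame with columns
#'   `t_min, A_M, L_M, I_M, Z_M, E_M` and attributes `rates` and
#'   `initial_totals`
#' @examples
#' k <- rate_constants(10, 0.002, 0.02, 0.002, 0.01, 0.004)
#' traj <- simulate_network(k, 1e-3, 5e-4, seq(0, 600, by = 15))
#' head(traj)
#' @export
simulate_network <- function(rates, a0 = 1e-3, l0 = 5e-4, time_grid,
                             init = NULL) {
  rates <- .as_rate_constants(rates)
  for (nm in c("a0", "l0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive concentration (M)",
           call. = FALSE)
  }
  if (!is.numeric(time_grid) || length(time_grid) < 2L)
    stop("'time_grid' must contain at least two times", call. = FALSE)
  if (time_grid[1] != 0)
    stop("'time_grid' must start at 0", call. = FALSE)
  if (any(diff(time_grid) <= 0))
    stop("'time_grid' must be strictly increasing", call. = FALSE)

  y0 <- c(A = a0, L = l0, I = 0, Z = 0, E = 0)
  if (!is.null(init)) {
    if (is.null(names(init)) || !all(names(init) %in% names(y0)))
      stop("'init' must be named with a subset of A, L, I, Z, E",
           call. = FALSE)
    y0[names(init)] <- init
    if (any(y0 < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  }

  deriv <- function(t, y, p) {
    bi <- p$k1 * y[1] * y[2] - p$k_m1 * y[3]
    dZ <- p$k1Z * y[3] - p$k_m1Z * y[4]
    dE <- p$k1E * y[3] - p$k_m1E * y[5]
    list(c(-bi, -bi, bi - dZ - dE, dZ, dE))
  }

  out <- deSolve::lsoda(y = y0, times = time_grid, func = deriv, parms = rates,
                        rtol = 1e-10, atol = 1e-13, maxsteps = 50000)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE integration failed (istate = ", diagn[1],
         "); rate constants span may exceed solver capability", call. = FALSE)
  out <- as.data.frame(out)
  if (anyNA(out))
    stop("ODE integration produced NA values; check rate constants",
         call. = FALSE)

  conc <- as.matrix(out[, c("A", "L", "I", "Z", "E")])
  # solver round-off can leave concentrations a hair below zero
  neg <- conc < 0
  if (any(conc[neg] < -1e-11))
    stop("integration produced significantly negative concentrations",
         call. = FALSE)
  conc[neg] <- 0

  amine_tot <- y0[["A"]] + y0[["I"]] + y0[["Z"]] + y0[["E"]]
  ald_tot   <- y0[["L"]] + y0[["I"]] + y0[["Z"]] + y0[["E"]]
  traj <- data.frame(t_min = out$time, A_M = conc[, "A"], L_M = conc[, "L"],
                     I_M = conc[, "I"], Z_M = conc[, "Z"], E_M = conc[, "E"])
  structure(traj,
            rates = rates,
            initial_totals = c(A0 = amine_tot, L0 = ald_tot),
            class = c("balance_trajectory", "data.frame"))
}

#' Mass-conservation error of a trajectory
#'
#' Maximum relative deviation of the two conserved totals
#' (A + I + Z + E and L + I + Z + E) from their initial values.
#'
#' @param traj a `balance_trajectory`
#' @return named numeric vector with the worst relative error for each total
#' @export
conservation_error <- function(traj) {
  stopifnot(inherits(traj, "balance_trajectory"))
  tot <- attr(traj, "initial_totals")
  prod <- traj$I_M + traj$Z_M + traj$E_M
  c(amine = max(abs(traj$A_M + prod - tot[["A0"]])) / tot[["A0"]],
    aldehyde = max(abs(traj$L_M + prod - tot[["L0"]])) / tot[["L0"]])
}

#' Time for a curve to settle within a band around its asymptote
#'
#' Convergence-time metric used to compare the Z/E ratio curve with the
#' individual concentration curves: the first time after which the curve
#' stays within `frac` (relative) of the asymptote `y_inf` at every later
#' sampled point.
#'
#' @param t times
#' @param y curve values at `t`
#' @param y_inf asymptote; defaults to the last value of `y`
#' @param frac relative half-width of the band (default 0.1)
#' @return the first such time, or `Inf` if the curve never settles
#' @export
time_to_asymptote <- function(t, y, y_inf = y[length(y)], frac = 0.1) {
  stopifnot(length(t) == length(y), length(t) >= 2L, is.finite(y_inf))
  inside <- abs(y - y_inf) <= frac * abs(y_inf)
  # last exit from the band determines settling
  out_idx <- which(!inside)
  if (length(out_idx) == 0L) return(t[1])
  if (max(out_idx) == length(t)) return(Inf)
  t[max(out_idx) + 1L]
}

#' @export
print.balance_trajectory <- function(x, ...) {
  tot <- attr(x, "initial_totals")
  cat(sprintf(
    "Balance-network trajectory: %d points over [0, %g] min (A0 = %g M, L0 = %g M)\n",
    nrow(x), x$t_min[nrow(x)], tot[["A0"]], tot[["L0"]]))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
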