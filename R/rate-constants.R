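# Gas constant in kcal mol^-1 K^-1; all free energies in the package use it.
.R_KCAL <- 1.98720e-3

#' Rate constants of the enamine-balance reaction network
#'
#' The in situ balance chemistry is modelled as three coupled reactions:
#' bimolecular condensation of amine (A) and aldehyde (L) to a lumped
#' hemiaminal/imine intermediate (I), followed by two competing unimolecular
#' rearrangements of I to the Z- and E-enamine. Six effective rate constants
#' define the network; the acid catalyst is not an explicit species, so all
#' constants are effective values at fixed catalyst load.
#'
#' @param k1 bimolecular adduct formation rate (M^-1 min^-1)
#' @param k_m1 adduct dissociation rate (min^-1)
#' @param k1Z,k_m1Z forward/reverse Z-enamine rates (min^-1)
#' @param k1E,k_m1E forward/reverse E-enamine rates (min^-1)
#' @return an object of class `rate_constants` (named list of the six rates)
#' @examples
#' rate_constants(k1 = 10, k_m1 = 0.002, k1Z = 0.02, k_m1Z = 0.002,
#'                k1E = 0.01, k_m1E = 0.004)
#' @export
rate_constants <- function(k1, k_m1, k1Z, k_m1Z, k1E, k_m1E) {
  k <- list(k1 = k1, k_m1 = k_m1, k1Z = k1Z, k_m1Z = k_m1Z,
            k1E = k1E, k_m1E = k_m1E)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("rate constant '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Enamine-balance rate constants (M, min units):\n")
  cat(sprintf("  k1   = %.6g M^-1 min^-1   k_m1  = %.6g min^-1\n", x$k1, x$k_m1))
  cat(sprintf("  k1Z  = %.6g min^-1        k_m1Z = %.6g min^-1\n", x$k1Z, x$k_m1Z))
  cat(sprintf("  k1E  = %.6g min^-1        k_m1E = %.6g min^-1\n", x$k1E, x$k_m1E))
  cf <- closed_form_ratios(x)
  cat(sprintf("  implied Keq(Z/E) = %.4g, initial Z/E = %.4g\n",
              cf$keq_ze, cf$initial_ratio))
  invisible(x)
}

.as_rate_constants <- function(rates) {
  if (inherits(rates, "rate_constants")) return(rates)
  if (is.list(rates) || is.numeric(rates)) {
    rates <- as.list(rates)
    need <- c("k1", "k_m1", "k1Z", "k_m1Z", "k1E", "k_m1E")
    if (all(need %in% names(rates)))
      return(do.call(rate_constants, rates[need]))
  }
  stop("'rates' must be a rate_constants object or a named list with ",
       "k1, k_m1, k1Z, k_m1Z, k1E, k_m1E", call. = FALSE)
}

#' Closed-form Z/E ratios implied by the rate constants
#'
#' At equilibrium, detailed balance across the two branches gives
#' Keq(Z/E) = (k1Z * k_m1E) / (k1E * k_m1Z). At t -> 0+ (starting from
#' Z = E = 0) both enamines grow by draining the same intermediate pool, so
#' the concentration ratio tends to the flux ratio k1Z / k1E. These are the
#' two quantities a ratio-curve fit estimates as its asymptote and its
#' extrapolated t = 0 value.
#'
#' @param rates a [rate_constants()] object
#' @return list with `keq_ze` and `initial_ratio`, both dimensionless
#' @examples
#' k <- rate_constants(10, 0.002, 0.02, 0.002, 0.01, 0.004)
#' closed_form_ratios(k)  # keq_ze = 4, initial_ratio = 2
#' @export
closed_form_ratios <- function(rates) {
  rates <- .as_rate_constants(rates)
  list(keq_ze = (rates$k1Z * rates$k_m1E) / (rates$k1E * rates$k_m1Z),
       initial_ratio = rates$k1Z / rates$k1E)
}

#' Classify the kinetic regime of a balance experiment
#'
#' The network shows two limiting behaviours depending on the rate of the
#' bimolecular step relative to the unimolecular rearrangements, measured by
#' rho = k1 * a0 / (k1Z + k1E). When rho is large the intermediate
#' pre-equilibrates and the enamine curves evolve on the rearrangement
#' timescale (`fast_preequilibrium`); when rho is small the bimolecular step
#' is rate limiting, the intermediate sits at quasi-steady state and the Z/E
#' ratio settles before either individual curve (`slow_bimolecular`).
#' Thresholds are one order of magnitude either side of unity.
#'
#' @param rates a [rate_constants()] object
#' @param a0 initial amine concentration (M)
#' @return one of `"fast_preequilibrium"`, `"slow_bimolecular"`,
#'   `"intermediate"`
#' @export
classify_regime <- function(rates, a0) {
  rates <- .as_rate_constants(rates)
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    stop("'a0' must be a single positive concentration (M)", call. = FALSE)
  rho <- (rates$k1 * a0) / (rates$k1Z + rates$k1E)
  if (rho >= 10) "fast_preequilibrium"
  else if (rho <= 0.1) "slow_bimolecular"
  else "intermediate"
}
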