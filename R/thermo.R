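#' Free energy difference from a Z/E equilibrium constant
#'
#' dG(Z/E) = -R T ln(Keq), with R = 1.98720e-3 kcal mol^-1 K^-1. Negative
#' values mean the Z-enamine — the only isomer able to form the intramolecular
#' aromatic contact — is the more stable species.
#'
#' @param keq dimensionless Z/E equilibrium constant, > 0
#' @param temperature absolute temperature in K (default 293, the assay
#'   temperature)
#' @return free energy difference in kcal/mol
#' @examples
#' delta_g_from_keq(8.0)   # -1.211 kcal/mol
#' delta_g_from_keq(0.45)  # +0.465 kcal/mol
#' @export
delta_g_from_keq <- function(keq, temperature = 293) {
  if (any(!is.finite(keq)) || any(keq <= 0))
    stop("'keq' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("'temperature' must be finite and > 0 (K)", call. = FALSE)
  -.R_KCAL * temperature * log(keq)
}

#' Relative error tier for a measured Keq
#'
#' Duplicate experiments support a conservative piecewise-constant error
#' model for the Z/E equilibrium constants: below 5% relative for Keq in
#' [1, 5), below 7.5% in [5, 10), about 10% in [10, 15), and at most 15%
#' above 15. Intervals are half-open, lower-inclusive. Values of Keq below 1
#' are assigned by reciprocal symmetry (the tier of 1/Keq), since
#' -RT ln(Keq) is antisymmetric in ln(Keq).
#'
#' @param keq dimensionless equilibrium constant, > 0
#' @return relative error as a fraction (0.05, 0.075, 0.10 or 0.15)
#' @export
assign_keq_error_tier <- function(keq) {
  if (any(!is.finite(keq)) || any(keq <= 0))
    stop("'keq' must be finite and > 0", call. = FALSE)
  k <- ifelse(keq < 1, 1 / keq, keq)
  ifelse(k < 5, 0.05, ifelse(k < 10, 0.075, ifelse(k < 15, 0.10, 0.15)))
}

#' Free energy error implied by a relative Keq error
#'
#' A (1 + f)-fold error in Keq shifts -RT ln(Keq) by at most RT ln(1 + f);
#' that bound is returned as the half-width of the dG error bar. At 293 K the
#' four tier fractions give 0.028, 0.042, 0.056 and 0.081 kcal/mol.
#'
#' @param fraction relative Keq error in [0, 1)
#' @param temperature absolute temperature in K (default 293)
#' @return error half-width in kcal/mol
#' @export
dg_error_from_keq_error <- function(fraction, temperature = 293) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction >= 1))
    stop("'fraction' must lie in [0, 1)", call. = FALSE)
  .R_KCAL * temperature * log1p(fraction)
}

#' Quadrature propagation of two free-energy errors
#'
#' Differential quantities (interaction, charge and polarization free
#' energies) are differences of two dG(Z/E) values; their error is the
#' quadrature sum of the two contributing errors.
#'
#' @param e_model,e_reference error half-widths in kcal/mol, >= 0
#' @return sqrt(e_model^2 + e_reference^2)
#' @export
propagate_dg_error <- function(e_model, e_reference) {
  if (any(!is.finite(c(e_model, e_reference))) ||
      any(c(e_model, e_reference) < 0))
    stop("errors must be finite and >= 0", call. = FALSE)
  sqrt(e_model^2 + e_reference^2)
}

#' Free-energy record for a balance measurement
#'
#' A tagged value/error pair in kcal/mol, carrying the provenance needed to
#' combine records safely: quantity kind, temperature, solvent, and the
#' contributing balance identifiers.
#'
#' @param quantity one of `"dG_ZE"`, `"dG_int"`, `"dG_charge"`, `"dG_pol"`
#' @param value free energy in kcal/mol (negative = Z-stabilizing/attractive)
#' @param error error half-width in kcal/mol, >= 0
#' @param temperature absolute temperature in K
#' @param solvent solvent label (NA allowed)
#' @param provenance character vector of contributing balance ids
#' @return an object of class `free_energy_record`
#' @export
free_energy_record <- function(quantity, value, error, temperature = 293,
                               solvent = NA_character_,
                               provenance = character()) {
  quantity <- match.arg(quantity, c("dG_ZE", "dG_int", "dG_charge", "dG_pol"))
  if (!is.finite(value)) stop("'value' must be finite", call. = FALSE)
  if (!is.finite(error) || error < 0)
    stop("'error' must be finite and >= 0", call. = FALSE)
  structure(list(quantity = quantity, value = value, error = error,
                 temperature = temperature, solvent = solvent,
                 provenance = as.character(provenance)),
            class = "free_energy_record")
}

#' @export
print.free_energy_record <- function(x, ...) {
  cat(sprintf("%s = %.4g +/- %.4g kcal/mol (T = %g K%s)%s\n",
              x$quantity, x$value, x$error, x$temperature,
              if (is.na(x$solvent)) "" else paste0(", ", x$solvent),
              if (length(x$provenance))
                paste0("  [", paste(x$provenance, collapse = " vs "), "]")
              else ""))
  invisible(x)
}

#' dG(Z/E) record from a measured equilibrium constant
#'
#' Convenience constructor combining [delta_g_from_keq()],
#' [assign_keq_error_tier()] and [dg_error_from_keq_error()].
#'
#' @inheritParams delta_g_from_keq
#' @param balance_id label of the balance
#' @param solvent solvent label
#' @return a `free_energy_record` with quantity `dG_ZE`
#' @examples
#' dg_ze_record(8.0, balance_id = "M6")
#' @export
dg_ze_record <- function(keq, temperature = 293, balance_id = "balance",
                         solvent = NA_character_) {
  tier <- assign_keq_error_tier(keq)
  free_energy_record("dG_ZE", delta_g_from_keq(keq, temperature),
                     dg_error_from_keq_error(tier, temperature),
                     temperature, solvent, balance_id)
}

.check_pairable <- function(model, reference) {
  stopifnot(inherits(model, "free_energy_record"),
            inherits(reference, "free_energy_record"))
  if (model$quantity != "dG_ZE" || reference$quantity != "dG_ZE")
    stop("both records must be dG_ZE measurements", call. = FALSE)
  if (abs(model$temperature - reference$temperature) > 1e-9)
    stop("temperature mismatch between model and reference records",
         call. = FALSE)
  same_solvent <- (is.na(model$solvent) && is.na(reference$solvent)) ||
    (!is.na(model$solvent) && !is.na(reference$solvent) &&
       model$solvent == reference$solvent)
  if (!same_solvent)
    stop("solvent mismatch between model and reference records",
         call. = FALSE)
}

#' Interaction free energy of an aromatic complex
#'
#' dG_int(model) = dG(Z/E, model) - dG(Z/E, R0): the stability the
#' interaction fragment confers on the Z-enamine beyond the intrinsic Z/E
#' preference measured with the fragment-free reference balance R0. Errors
#' propagate in quadrature.
#'
#' @param model dG_ZE `free_energy_record` of the model balance
#' @param r0 dG_ZE record of the reference balance (same solvent and
#'   temperature)
#' @return a `free_energy_record` with quantity `dG_int`
#' @examples
#' m6 <- dg_ze_record(8.0, balance_id = "M6")
#' r0 <- dg_ze_record(0.45, balance_id = "R0")
#' interaction_free_energy(m6, r0)  # -1.676 kcal/mol
#' @export
interaction_free_energy <- function(model, r0) {
  .check_pairable(model, r0)
  free_energy_record("dG_int", model$value - r0$value,
                     propagate_dg_error(model$error, r0$error),
                     model$temperature, model$solvent,
                     c(model$provenance, r0$provenance))
}

#' Charge or polarization contribution from an isostere pair
#'
#' Subtracting the dG(Z/E) of a neutral (or nonpolarized) isostere from the
#' value of its charged (or CH-polarized) model isolates the net free-energy
#' contribution of the charge (dG_charge) or of the CH-bond polarization
#' (dG_pol) to the complex stability.
#'
#' @param model dG_ZE record of the charged/polarized balance
#' @param isostere dG_ZE record of its matched neutral isostere
#' @param kind `"charge"` or `"polarization"`
#' @return a `free_energy_record` with quantity `dG_charge` or `dG_pol`
#' @export
isostere_contribution <- function(model, isostere,
                                  kind = c("charge", "polarization")) {
  kind <- match.arg(kind)
  .check_pairable(model, isostere)
  free_energy_record(if (kind == "charge") "dG_charge" else "dG_pol",
                     model$value - isostere$value,
                     propagate_dg_error(model$error, isostere$error),
                     model$temperature, model$solvent,
                     c(model$provenance, isostere$provenance))
}

#' Per-class summary of interaction free energies
#'
#' Mean and sample standard deviation of dG values within each complex class
#' (e.g. cationic CH/pi, polarized CH/pi), ordered from most to least
#' stabilizing (most negative mean first). Classes with a single record are
#' reported without a standard deviation; empty classes are dropped with a
#' warning.
#'
#' @param values numeric dG values in kcal/mol, or a list of
#'   `free_energy_record`s
#' @param class_labels class label per value (factor or character); unused
#'   factor levels count as empty classes
#' @return data frame with columns `class`, `n`, `mean`, `sd`, ordered by
#'   ascending mean
#' @export
summarize_complex_class <- function(values, class_labels) {
  if (is.list(values) && all(vapply(values, inherits, TRUE,
                                    "free_energy_record")))
    values <- vapply(values, `[[`, numeric(1), "value")
  stopifnot(is.numeric(values), length(values) == length(class_labels))
  f <- as.factor(class_labels)
  empty <- levels(f)[tabulate(f, nbins = nlevels(f)) == 0]
  if (length(empty))
    warning("omitting empty class(es): ", paste(empty, collapse = ", "),
            call. = FALSE)
  keep <- levels(f)[tabulate(f, nbins = nlevels(f)) > 0]
  out <- do.call(rbind, lapply(keep, function(cl) {
    v <- values[f == cl]
    data.frame(class = cl, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out <- out[order(out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}
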