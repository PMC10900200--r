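#' Solvent hydrogen-bonding descriptor table
#'
#' Hunter's empirical hydrogen-bond donor (alpha) and acceptor (beta)
#' parameters for the solvents of a study. Values are user-supplied (they
#' come from the solvation literature); the package never hard-codes them.
#'
#' @param name solvent labels, unique
#' @param alpha hydrogen-bond donor parameters
#' @param beta hydrogen-bond acceptor parameters
#' @return a `solvent_table` data frame with columns `name, alpha, beta`
#' @export
solvent_table <- function(name, alpha, beta) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicated solvent name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(alpha)) || any(!is.finite(beta)))
    stop("alpha and beta must be finite", call. = FALSE)
  structure(data.frame(name = name, alpha = alpha, beta = beta),
            class = c("solvent_table", "data.frame"))
}

#' Regress free-energy contributions against a solvent H-bond parameter
#'
#' Ordinary least-squares line of dG values (one per solvent) against the
#' solvent's Hunter alpha (donor) or beta (acceptor) parameter, with the
#' coefficient of determination. Charge contributions of good hydrogen-bond
#' donors (guanidinium) track beta closely because acceptor solvents compete
#' directly for the cation.
#'
#' @param values data frame with columns `solvent` and `value` (kcal/mol), or
#'   a list of `free_energy_record`s with their `solvent` fields set
#' @param solvents a [solvent_table()]
#' @param parameter `"alpha"` or `"beta"`
#' @return a `trend_fit` list: `slope` (kcal/mol per parameter unit),
#'   `intercept` (kcal/mol), `r_squared`, `n_points`
#' @export
regress_vs_parameter <- function(values, solvents,
                                 parameter = c("beta", "alpha")) {
  parameter <- match.arg(parameter)
  if (!inherits(solvents, "solvent_table"))
    solvents <- solvent_table(solvents$name, solvents$alpha, solvents$beta)
  if (is.list(values) && all(vapply(values, inherits, TRUE,
                                    "free_energy_record")))
    values <- data.frame(
      solvent = vapply(values, `[[`, character(1), "solvent"),
      value = vapply(values, `[[`, numeric(1), "value"))
  stopifnot(is.data.frame(values),
            all(c("solvent", "value") %in% names(values)))
  idx <- match(values$solvent, solvents$name)
  ok <- !is.na(idx) & is.finite(values$value)
  if (sum(ok) < 3L)
    stop("insufficient data: need at least 3 solvents with both a value ",
         "and a descriptor", call. = FALSE)
  x <- solvents[[parameter]][idx[ok]]
  y <- values$value[ok]
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * sum(y^2) || ss_tot == 0) 0
  else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = min(max(r2, 0), 1),
                 n_points = sum(ok),
                 parameter = parameter),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "dG vs solvent %s: slope = %.4g kcal/mol per unit, intercept = %.4g, R^2 = %.3f (n = %d)\n",
    x$parameter, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Rank complex classes by stability in one solvent
#'
#' Orders complex classes from most to least stabilizing (ascending dG, most
#' negative first). Ties are broken alphabetically and flagged, since a tie
#' means the hierarchy is not resolved at the available precision.
#'
#' @param per_class_means named numeric vector: class label -> mean dG
#'   (kcal/mol)
#' @param solvent optional solvent label, carried into the result
#' @return list with `classes` (ordered labels), `values` (ordered dG),
#'   `ties` (logical), `solvent`
#' @examples
#' rank_hierarchy(c(polarized = -1.0, cationic = -0.6,
#'                  nonpolarized = -0.3, anionic = 0.2))
#' @export
rank_hierarchy <- function(per_class_means, solvent = NA_character_) {
  stopifnot(is.numeric(per_class_means), !is.null(names(per_class_means)))
  if (length(per_class_means) < 2L)
    stop("need at least 2 classes to rank", call. = FALSE)
  ord <- order(per_class_means, names(per_class_means))
  structure(list(classes = names(per_class_means)[ord],
                 values = unname(per_class_means[ord]),
                 ties = anyDuplicated(per_class_means) > 0,
                 solvent = solvent),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("Stability ranking",
      if (!is.na(x$solvent)) paste0(" (", x$solvent, ")"), ":\n", sep = "")
  cat(" ", paste(x$classes, collapse = " > "), "\n")
  if (x$ties) cat("  [tie detected: order among tied classes is alphabetical]\n")
  invisible(x)
}
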