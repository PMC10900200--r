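#' Read a kinetic CSV of Z/E signal integrals
#'
#' Strict reader for the exchange format: a UTF-8 CSV with header exactly
#' `t_min,z_integral,e_integral` and decimal-point numbers. Rows are sorted
#' by time; duplicated times are rejected.
#'
#' @param path file path
#' @return a [kinetic_series()]
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    stop("parse error: ", path, " has no data rows", call. = FALSE)
  header <- strsplit(trimws(lines[1]), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("t_min", "z_integral", "e_integral")))
    stop("parse error at line 1: header must be exactly ",
         "'t_min,z_integral,e_integral'", call. = FALSE)
  rows <- lapply(seq(2L, length(lines)), function(i) {
    if (!nzchar(trimws(lines[i]))) return(NULL)
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 3L || anyNA(vals))
      stop("parse error at line ", i, ": expected 3 numeric fields",
           call. = FALSE)
    vals
  })
  m <- do.call(rbind, rows)
  if (anyDuplicated(m[, 1]))
    stop("validation error: duplicated times in ", path, call. = FALSE)
  m <- m[order(m[, 1]), , drop = FALSE]
  kinetic_series(m[, 1], m[, 2], m[, 3])
}

#' Write a kinetic series to CSV
#'
#' Writes the exchange format read by [read_kinetic_csv()] at full double
#' precision, so a write/read round trip preserves every value.
#'
#' @param series a [kinetic_series()]
#' @param path output path
#' @export
write_kinetic_csv <- function(series, path) {
  stopifnot(inherits(series, "kinetic_series"))
  lines <- c("t_min,z_integral,e_integral",
             sprintf("%.17g,%.17g,%.17g",
                     series$t_min, series$z_integral, series$e_integral))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic experiment
#'
#' One-row CSV with the six rate constants, the implied keq_ze and initial
#' ratio, the seed and design parameters — kept in a separate file so the
#' kinetic series itself stays blind.
#'
#' @param series a synthetic [kinetic_series()] from [generate_experiment()]
#' @param path output path
#' @export
write_ground_truth_csv <- function(series, path) {
  gt <- attr(series, "ground_truth")
  if (is.null(gt)) stop("series carries no ground truth", call. = FALSE)
  k <- gt$rates
  df <- data.frame(k1 = k$k1, k_m1 = k$k_m1, k1Z = k$k1Z, k_m1Z = k$k_m1Z,
                   k1E = k$k1E, k_m1E = k$k_m1E, keq_ze = gt$keq_ze,
                   initial_ratio = gt$initial_ratio, seed = gt$seed,
                   a0 = gt$a0, l0 = gt$l0, noise_rel_sd = gt$noise_rel_sd,
                   signal_scale = gt$signal_scale)
  utils::write.csv(format(df, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a solvent descriptor CSV
#'
#' Expected header: `name,alpha,beta`.
#'
#' @param path file path
#' @return a [solvent_table()]
#' @export
read_solvent_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "alpha", "beta") %in% names(df)))
    stop("parse error: solvent table needs columns name, alpha, beta",
         call. = FALSE)
  solvent_table(df$name, df$alpha, df$beta)
}

.CLASS_VOCAB <- c("nonpolarized_CHpi", "polarized_CHpi",
                  "cationic_CHpi_poor_donor", "cationic_CHpi_good_donor",
                  "anionic_CHpi")

#' Validate a balance registry
#'
#' The registry maps every balance to its role and differential references:
#' models point at a reference (`R0` for dG_int, or a matched isostere for
#' dG_charge / dG_pol) and carry solvent, aldehyde, counterion, complex class
#' and temperature metadata.
#'
#' @param registry a list with a `version` key and an `entries` list; each
#'   entry is a list with fields `balance_id`, `role` (`model` or
#'   `reference`), and optionally `reference_id`, `isostere_id`,
#'   `isostere_kind` (`charge`, `polarization` or `none`), `complex_class`,
#'   `solvent`, `aldehyde`, `counterion`, `temperature`
#' @return the registry, invisibly, after validation
#' @export
validate_registry <- function(registry) {
  if (is.null(registry$version))
    stop("registry must declare a 'version' key", call. = FALSE)
  entries <- registry$entries
  if (is.null(entries) || !length(entries))
    stop("registry has no entries", call. = FALSE)
  ids <- vapply(entries, `[[`, character(1), "balance_id")
  if (anyDuplicated(ids))
    stop("duplicated balance_id in registry", call. = FALSE)
  for (e in entries) {
    if (!e$role %in% c("model", "reference"))
      stop("entry ", e$balance_id, ": role must be model or reference",
           call. = FALSE)
    if (e$role == "model") {
      if (is.null(e$reference_id) || !e$reference_id %in% ids)
        stop("entry ", e$balance_id,
             ": reference_id missing or unresolved", call. = FALSE)
      ik <- if (is.null(e$isostere_kind)) "none" else e$isostere_kind
      if (!ik %in% c("charge", "polarization", "none"))
        stop("entry ", e$balance_id, ": invalid isostere_kind", call. = FALSE)
      if (ik != "none" &&
          (is.null(e$isostere_id) || !e$isostere_id %in% ids))
        stop("entry ", e$balance_id, ": isostere_id missing or unresolved",
             call. = FALSE)
    }
    if (!is.null(e$complex_class) && !e$complex_class %in% .CLASS_VOCAB)
      stop("entry ", e$balance_id, ": complex_class must be one of ",
           paste(.CLASS_VOCAB, collapse = ", "), call. = FALSE)
  }
  invisible(registry)
}

#' Read a balance registry from a YAML config
#'
#' @param path YAML file with `version` and `entries`
#' @return validated registry list
#' @export
read_registry <- function(path) {
  validate_registry(yaml::read_yaml(path))
}

.entry_field <- function(e, field, default = NA) {
  if (is.null(e[[field]])) default else e[[field]]
}

#' Run the full balance-analysis pipeline
#'
#' Orchestrates the analysis workflow for a set of balances: per balance,
#' obtain the kinetic series (from a CSV under `data_dir`, file
#' `<balance_id>.csv`, or synthetically when the config carries a
#' `synthetic` section), build the Z/E ratio curve, fit the exponential
#' model with automatic selection, and derive Keq, its error tier and
#' dG(Z/E). Models are then paired with their registry references to form
#' dG_int and dG_charge / dG_pol with quadrature errors; complex classes are
#' summarized per solvent, and — when a solvent table with three or more
#' solvents applies — dG_charge / dG_pol values are regressed against the
#' Hunter parameters. Identical config and seeds give identical outputs.
#'
#' @param config list (or path to a YAML file) with components:
#'   `registry` (inline registry list, or path), optionally `data_dir`,
#'   `synthetic` (list with `regime` and `seed` for generated data),
#'   `solvent_table` (path to CSV, or data frame), `min_signal_fraction`,
#'   `output_dir`
#' @param quiet suppress the per-balance log line
#' @return list with data frames `balances`, `differentials`,
#'   `class_summary`, and `trends` (possibly empty)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  registry <- config$registry
  if (is.character(registry)) registry <- yaml::read_yaml(registry)
  validate_registry(registry)
  entries <- registry$entries
  ids <- vapply(entries, `[[`, character(1), "balance_id")
  msf <- if (is.null(config$min_signal_fraction)) 0.02
         else config$min_signal_fraction

  solvents <- config$solvent_table
  if (is.character(solvents)) solvents <- read_solvent_csv(solvents)

  # --- per-balance fits -----------------------------------------------------
  series_of <- function(e, idx) {
    if (!is.null(config$data_dir)) {
      path <- file.path(config$data_dir, paste0(e$balance_id, ".csv"))
      if (!file.exists(path))
        stop("no kinetic data for balance ", e$balance_id, " (", path, ")",
             call. = FALSE)
      return(read_kinetic_csv(path))
    }
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      base_seed <- if (is.null(syn$seed)) 1L else as.integer(syn$seed)
      regime <- if (is.null(syn$regime)) "mixed" else syn$regime
      noise <- if (is.null(syn$noise_rel_sd)) 0.03 else syn$noise_rel_sd
      design <- experiment_design(noise_rel_sd = noise,
                                  seed = base_seed + idx)
      k <- sample_rate_constants(regime, 1, seed = base_seed + idx,
                                 design = design)[[1]]
      return(generate_experiment(k, design))
    }
    stop("config must provide either data_dir or a synthetic section",
         call. = FALSE)
  }

  fits <- vector("list", length(entries))
  rows <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    temp <- .entry_field(e, "temperature", 293)
    series <- series_of(e, i)
    curve <- build_ratio_series(series, msf)
    fit <- select_fit(curve)
    tier <- assign_keq_error_tier(fit$keq)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      balance_id = e$balance_id, role = e$role,
      solvent = .entry_field(e, "solvent", NA_character_),
      aldehyde = .entry_field(e, "aldehyde", NA_character_),
      counterion = .entry_field(e, "counterion", NA_character_),
      complex_class = .entry_field(e, "complex_class", NA_character_),
      temperature = temp,
      keq = fit$keq, keq_err_tier = tier,
      initial_ratio = fit$initial_ratio,
      n_exp = fit$n_exponentials, sse = fit$residual_sse,
      converged = fit$converged,
      dG_ZE = delta_g_from_keq(fit$keq, temp),
      dG_ZE_err = dg_error_from_keq_error(tier, temp))
    if (!quiet)
      message(sprintf(
        "[%s] keq = %.4g (tier %.1f%%), n_exp = %d, converged = %s",
        e$balance_id, fit$keq, 100 * tier, fit$n_exponentials,
        fit$converged))
  }
  balances <- do.call(rbind, rows)

  rec_of <- function(id) {
    r <- balances[balances$balance_id == id, ]
    free_energy_record("dG_ZE", r$dG_ZE, r$dG_ZE_err, r$temperature,
                       r$solvent, id)
  }

  # --- differential quantities ---------------------------------------------
  diffs <- list()
  for (e in entries) {
    if (e$role != "model") next
    m <- rec_of(e$balance_id)
    dint <- interaction_free_energy(m, rec_of(e$reference_id))
    row <- data.frame(balance_id = e$balance_id,
                      solvent = .entry_field(e, "solvent", NA_character_),
                      complex_class = .entry_field(e, "complex_class",
                                                   NA_character_),
                      dG_int = dint$value, dG_int_err = dint$error,
                      contribution = NA_character_,
                      dG_contrib = NA_real_, dG_contrib_err = NA_real_)
    ik <- .entry_field(e, "isostere_kind", "none")
    if (ik != "none") {
      kind <- if (ik == "charge") "charge" else "polarization"
      dc <- isostere_contribution(m, rec_of(e$isostere_id), kind)
      row$contribution <- dc$quantity
      row$dG_contrib <- dc$value
      row$dG_contrib_err <- dc$error
    }
    diffs[[length(diffs) + 1L]] <- row
  }
  differentials <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame()

  # --- class summaries and solvent trends ----------------------------------
  class_summary <- data.frame()
  if (nrow(differentials) && any(!is.na(differentials$complex_class))) {
    keep <- !is.na(differentials$complex_class)
    per_solvent <- split(differentials[keep, ],
                         differentials$solvent[keep])
    class_summary <- do.call(rbind, lapply(names(per_solvent), function(s) {
      d <- per_solvent[[s]]
      cbind(solvent = s,
            summarize_complex_class(d$dG_int, d$complex_class))
    }))
    rownames(class_summary) <- NULL
  }

  trends <- data.frame()
  if (!is.null(solvents) && nrow(differentials)) {
    has_contrib <- !is.na(differentials$dG_contrib)
    for (q in unique(differentials$contribution[has_contrib])) {
      d <- differentials[has_contrib & differentials$contribution == q, ]
      if (length(unique(d$solvent)) < 3L) next
      vals <- data.frame(solvent = d$solvent, value = d$dG_contrib)
      for (p in c("alpha", "beta")) {
        tf <- regress_vs_parameter(vals, solvents, p)
        trends <- rbind(trends, data.frame(
          quantity = q, parameter = p, slope = tf$slope,
          intercept = tf$intercept, r_squared = tf$r_squared,
          n = tf$n_points))
      }
    }
  }

  out <- list(balances = balances, differentials = differentials,
              class_summary = class_summary, trends = trends)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      if (is.data.frame(out[[nm]]) && nrow(out[[nm]]))
        utils::write.table(out[[nm]],
                           file.path(config$output_dir, paste0(nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
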