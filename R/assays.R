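#' Catalase assay constants
#'
#' The spectrophotometric catalase assay follows the classic
#' Beers-Sizer design: H2O2 decomposition is monitored as the decline of
#' absorbance at 240 nm, and activity is read off the time the trace
#' takes to fall from 0.45 to 0.40 — an interval corresponding to the
#' decomposition of 3.45 umol H2O2. One active unit (AU) decomposes
#' 1 umol H2O2 per minute.
#'
#' @param decomposed_umol umol H2O2 decomposed between the two levels
#'   (default 3.45).
#' @param sample_volume_ml Volume of enzyme sample added to the cuvette
#'   in mL (default 0.1).
#' @param upper_level,lower_level The two A240 levels bounding the timed
#'   interval (defaults 0.45 and 0.40).
#' @param initial_window Acceptable A240 range for the first reading of
#'   a well-prepared substrate solution (default 0.48-0.52); traces
#'   starting outside it are flagged with a warning, not rejected.
#'
#' @return A list of class `assay_constants`.
#' @export
assay_constants <- function(decomposed_umol = 3.45, sample_volume_ml = 0.1,
                            upper_level = 0.45, lower_level = 0.40,
                            initial_window = c(0.48, 0.52)) {
  if (upper_level <= lower_level) abort("upper_level must exceed lower_level")
  if (sample_volume_ml <= 0) abort("sample_volume_ml must be positive")
  structure(
    list(decomposed_umol = decomposed_umol, sample_volume_ml = sample_volume_ml,
         upper_level = upper_level, lower_level = lower_level,
         initial_window = initial_window),
    class = "assay_constants"
  )
}

# Fixed dilution implied by the base-hydrolysis release protocol:
# 100 uL nanoparticle sample + 50 uL NaOH + 50 uL PBS = 2x.
#' Dilution factor of the nanoparticle hydrolysis protocol
#'
#' Releasing encapsulated protein by base hydrolysis combines 100 uL of
#' sample with 50 uL NaOH and 50 uL PBS, a fixed 2x volumetric dilution
#' to apply when quantifying the released protein.
#'
#' @return The numeric dilution factor (2).
#' @export
hydrolysis_dilution_factor <- function() 2

check_trace <- function(trace) {
  if (!all(c("time_s", "a240") %in% names(trace))) {
    abort("trace must have columns time_s and a240")
  }
  if (nrow(trace) < 2) abort("trace must have at least 2 readings")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("trace times must be strictly increasing")
  }
  if (!all(is.finite(trace$a240)) || any(trace$a240 < 0)) {
    abort("absorbances must be finite and non-negative")
  }
  invisible(trace)
}

#' First downward crossing time of an absorbance level
#'
#' Scans the trace for the first point at which it crosses the level
#' from above and interpolates between the two bracketing samples. An
#' exact sample hit returns that sample's time. If noise produces
#' several crossings, the first wins.
#'
#' Interpolation is linear in log-absorbance, which is exact for
#' first-order (exponential) decay — the regime this assay operates in —
#' and indistinguishable from linear interpolation for slowly decaying
#' traces; plain linear interpolation of fast traces (k near 0.05/s)
#' sampled at 2 s would bias the crossing interval by several tenths of
#' a percent. If either bracketing absorbance is non-positive the
#' interpolation falls back to linear.
#'
#' @param trace A data frame with columns `time_s` and `a240`.
#' @param level Absorbance level to cross.
#' @return Crossing time in seconds.
#' @export
crossing_time <- function(trace, level) {
  check_trace(trace)
  s <- trace$a240 - level
  t <- trace$time_s
  a <- trace$a240
  n <- length(s)
  if (s[1] == 0 && n >= 2 && s[2] < 0) return(t[1])
  for (j in seq_len(n - 1)) {
    if (s[j] > 0 && s[j + 1] <= 0) {
      if (s[j + 1] == 0) return(t[j + 1])
      frac <- if (a[j] > 0 && a[j + 1] > 0 && level > 0) {
        (log(a[j]) - log(level)) / (log(a[j]) - log(a[j + 1]))
      } else {
        s[j] / (s[j] - s[j + 1])
      }
      return(t[j] + frac * (t[j + 1] - t[j]))
    }
  }
  abort(sprintf("level not crossed: trace never falls through %.3g", level))
}

#' Catalase activity from kinetic A240 traces
#'
#' Computes active units per mL from the crossing-time assay:
#' `AU/mL = decomposed_umol * dilution_factor / (delta_t_min *
#' sample_volume_ml)`, where `delta_t_min` is the time (minutes) the
#' trace takes to fall from the upper to the lower level. A trace whose
#' first reading lies outside the substrate preparation window is
#' processed but flagged in the `warnings` column.
#'
#' @param traces A data frame of readings with columns `time_s`, `a240`
#'   and optionally `sample_id` (multiple samples are processed
#'   per-sample) and `dilution_factor`.
#' @param dilution_factor Sample pre-dilution factor (>= 1); used when
#'   the data carry no `dilution_factor` column.
#' @param constants An [assay_constants()].
#'
#' @return A tibble with one row per sample: `sample_id`,
#'   `dilution_factor`, `t_cross_045_s`, `t_cross_040_s`, `delta_t_min`,
#'   `au_per_ml`, `warnings`.
#' @export
#' @examples
#' tr <- gen_kinetic_trace(a0 = 0.50, k = 0.002)$trace
#' catalase_activity(tr, dilution_factor = 10)
catalase_activity <- function(traces, dilution_factor = 1,
                              constants = assay_constants()) {
  traces <- as_tibble(traces)
  if (!"sample_id" %in% names(traces)) traces$sample_id <- "sample"
  if (!"dilution_factor" %in% names(traces)) {
    traces$dilution_factor <- dilution_factor
  }
  one <- function(tr) {
    dil <- tr$dilution_factor[1]
    if (dil < 1) abort("dilution_factor must be >= 1")
    check_trace(tr)
    warns <- character(0)
    a0 <- tr$a240[1]
    if (a0 < constants$initial_window[1] || a0 > constants$initial_window[2]) {
      warns <- c(warns, sprintf(
        "initial A240 %.3f outside substrate window (%.2f, %.2f)",
        a0, constants$initial_window[1], constants$initial_window[2]
      ))
    }
    t_hi <- crossing_time(tr, constants$upper_level)
    t_lo <- crossing_time(tr, constants$lower_level)
    dt_min <- (t_lo - t_hi) / 60
    if (dt_min <= 0) abort("non-positive level-crossing interval")
    tibble(
      sample_id = tr$sample_id[1],
      dilution_factor = dil,
      t_cross_045_s = t_hi,
      t_cross_040_s = t_lo,
      delta_t_min = dt_min,
      au_per_ml = constants$decomposed_umol * dil /
        (dt_min * constants$sample_volume_ml),
      warnings = paste(warns, collapse = "; ")
    )
  }
  traces |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(one) |>
    bind_rows()
}

#' Fit a BCA protein standard curve
#'
#' Ordinary least-squares straight line through the calibration points
#' (absorbance at 562 nm versus known concentration), the working model
#' for BCA quantification over its linear range.
#'
#' @param standards A data frame with columns `known_conc_ug_ml` and
#'   `absorbance`.
#' @return An object of class `bca_curve` wrapping the [stats::lm()]
#'   fit; supports [generics::tidy()] and [generics::glance()].
#' @export
bca_fit <- function(standards) {
  standards <- as_tibble(standards)
  if (!all(c("known_conc_ug_ml", "absorbance") %in% names(standards))) {
    abort("standards must have columns known_conc_ug_ml and absorbance")
  }
  if (length(unique(standards$known_conc_ug_ml)) < 2) {
    abort("at least 2 distinct calibration concentrations are required")
  }
  fit <- stats::lm(absorbance ~ known_conc_ug_ml, data = standards)
  # noise-free synthetic standards fit exactly; the perfect-fit warning is expected
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < 1e-12) abort("degenerate standard curve: slope is zero")
  structure(
    list(
      fit = fit,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = fit_summary$r.squared,
      conc_range = range(standards$known_conc_ug_ml),
      abs_range = range(standards$absorbance),
      standards = standards
    ),
    class = "bca_curve"
  )
}

#' @export
print.bca_curve <- function(x, ...) {
  cat(sprintf(
    "<bca_curve> A562 = %.4f + %.4f * conc (ug/mL), R^2 = %.4f, range %.3g-%.3g ug/mL\n",
    x$intercept, x$slope, x$r_squared, x$conc_range[1], x$conc_range[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bca_curve <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(cf[, 1]),
    std_error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p_value = unname(cf[, 4])
  )
}

#' @export
glance.bca_curve <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    n = nrow(x$standards)
  )
}

#' Quantify protein concentration from a BCA curve
#'
#' Inverts the standard curve: `conc = (absorbance - intercept) / slope
#' * dilution_factor`. Readings outside the calibrated absorbance range
#' are extrapolated with a warning.
#'
#' @param curve A [bca_fit()] object.
#' @param absorbance Numeric vector of sample A562 readings.
#' @param dilution_factor Numeric dilution factor(s) applied to the
#'   samples before reading (e.g. [hydrolysis_dilution_factor()] for
#'   base-hydrolysed nanoparticles).
#'
#' @return A tibble with columns `absorbance`, `dilution_factor`,
#'   `conc_ug_ml`.
#' @export
bca_quantify <- function(curve, absorbance, dilution_factor = 1) {
  if (!inherits(curve, "bca_curve")) abort("curve must be a bca_curve")
  out_of_range <- absorbance < curve$abs_range[1] | absorbance > curve$abs_range[2]
  if (any(out_of_range)) {
    warn(sprintf("%d absorbance reading(s) outside the calibrated range (%.3g, %.3g)",
                 sum(out_of_range), curve$abs_range[1], curve$abs_range[2]))
  }
  tibble(
    absorbance = absorbance,
    dilution_factor = dilution_factor,
    conc_ug_ml = (absorbance - curve$intercept) / curve$slope * dilution_factor
  )
}

#' Percent binding efficiency of ion-pair complexation
#'
#' The fraction of initially dissolved protein removed from the
#' supernatant by complexation:
#' `(initial - supernatant) / initial * 100`. Negative values
#' (supernatant above initial, i.e. measurement noise) are returned
#' as-is with a warning rather than clamped.
#'
#' @param initial Initial protein concentration (> 0).
#' @param supernatant Supernatant concentration after complexation,
#'   same units (>= 0).
#' @return Binding efficiency in percent (vectorized).
#' @export
binding_efficiency <- function(initial, supernatant) {
  if (any(initial <= 0)) abort("initial concentration must be positive")
  if (any(supernatant < 0)) abort("supernatant concentration must be non-negative")
  eff <- (initial - supernatant) / initial * 100
  if (any(eff < 0)) {
    warn("negative binding efficiency: supernatant exceeds initial (measurement noise?)")
  }
  eff
}

#' Specific activity of an enzyme loading
#'
#' Converts a formulation's activity loading (AU per mL suspension) and
#' mass loading (ug protein per mL suspension) into specific activity in
#' AU per mg: `activity / mass * 1000`.
#'
#' @param loading_activity_au_ml Activity loading, AU/mL (> 0).
#' @param loading_mass_ug_ml Mass loading, ug/mL (> 0).
#' @return Specific activity in AU/mg (vectorized).
#' @export
specific_activity <- function(loading_activity_au_ml, loading_mass_ug_ml) {
  if (any(loading_activity_au_ml <= 0) || any(loading_mass_ug_ml <= 0)) {
    abort("loadings must be positive")
  }
  loading_activity_au_ml / loading_mass_ug_ml * 1000
}

#' Percent deactivation relative to a reference specific activity
#'
#' `(1 - treated / reference) * 100`: how much specific activity a
#' process (e.g. emulsification) destroyed relative to the reference
#' state (e.g. as-supplied enzyme or a gentler process).
#'
#' @param reference_specific Reference specific activity, AU/mg (> 0).
#' @param treated_specific Post-process specific activity, AU/mg (>= 0).
#' @return Percent deactivation (vectorized).
#' @export
percent_deactivation <- function(reference_specific, treated_specific) {
  if (any(reference_specific <= 0)) abort("reference specific activity must be positive")
  if (any(treated_specific < 0)) abort("treated specific activity must be non-negative")
  (1 - treated_specific / reference_specific) * 100
}

#' Protease-protection retention course
#'
#' Normalizes a time course of activities measured during protease
#' challenge to the 0 h activity: `retention(t) = 100 * activity(t) /
#' activity(0)`.
#'
#' @param course A data frame with columns `time_h` and `au_per_ml`
#'   (optionally grouped by a `formulation` column).
#' @return The input with a `retention_percent` column added.
#' @export
protection_course <- function(course) {
  course <- as_tibble(course)
  if (!all(c("time_h", "au_per_ml") %in% names(course))) {
    abort("course must have columns time_h and au_per_ml")
  }
  grouping <- if ("formulation" %in% names(course)) "formulation" else character(0)
  course |>
    group_by(across(dplyr::all_of(grouping))) |>
    mutate(retention_percent = {
      i0 <- which(.data$time_h == 0)
      if (length(i0) == 0) abort("no 0 h timepoint in protection course")
      a0 <- .data$au_per_ml[i0[1]]
      if (!is.finite(a0) || a0 <= 0) abort("0 h activity must be positive")
      100 * .data$au_per_ml / a0
    }) |>
    ungroup()
}

#' Anionic-group inventory of an ion-pairing recipe
#'
#' Bookkeeping for hydrophobic ion pairing stoichiometry: the total
#' number of anionic sulfate/sulfonate groups offered per protein
#' molecule is `groups_per_molecule * mole_ratio`. Dextran sulfate is
#' modelled as a dodecamer bearing 24 sulfate groups (so mole ratio 5
#' offers 120 groups, comparable to 128 for SDS or taurocholate at mole
#' ratio 128); the per-molecule count is an argument so other polymer
#' models can be used. Supplying the protein net charge also reports the
#' ion-to-protein charge ratio.
#'
#' @param agent Agent label (e.g. `"DS"`, `"SDS"`, `"TA"`).
#' @param groups_per_molecule Anionic groups per agent molecule
#'   (integer >= 1; 24 for the dextran sulfate dodecamer model, 1 for
#'   SDS and taurocholic acid).
#' @param mole_ratio Agent-to-protein mole ratio (> 0).
#' @param protein_net_charge Optional protein net charge (absolute
#'   value used) for the charge-ratio column.
#'
#' @return A one-row tibble: `agent`, `groups_per_molecule`,
#'   `mole_ratio`, `total_anionic_groups`, `charge_ratio` (NA when no
#'   protein charge is given).
#' @export
ion_group_inventory <- function(agent, groups_per_molecule, mole_ratio,
                                protein_net_charge = NULL) {
  if (groups_per_molecule < 1 || groups_per_molecule != round(groups_per_molecule)) {
    abort("groups_per_molecule must be a positive integer")
  }
  if (mole_ratio <= 0) abort("mole_ratio must be positive")
  total <- groups_per_molecule * mole_ratio
  tibble(
    agent = agent,
    groups_per_molecule = as.integer(groups_per_molecule),
    mole_ratio = mole_ratio,
    total_anionic_groups = total,
    charge_ratio = if (is.null(protein_net_charge)) NA_real_ else
      total / abs(protein_net_charge)
  )
}

#' Per-molecule anionic group counts used in this work
#'
#' @return A tibble of the three ion-pairing agents with their modelled
#'   anionic group counts: dextran sulfate dodecamer (24), SDS (1),
#'   taurocholic acid (1).
#' @export
ion_pairing_agents <- function() {
  tibble(
    agent = c("DS", "SDS", "TA"),
    groups_per_molecule = c(24L, 1L, 1L)
  )
}
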