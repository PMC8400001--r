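#' @import ggplot2
NULL

#' Plot per-residue occupancy
#'
#' Bar plot of occupancy percent by residue index, coloured by residue
#' class, with the high-occupancy threshold drawn as a dashed line.
#'
#' @param occupancy Tibble from [compute_occupancy()].
#' @param threshold_percent Threshold line (default 95).
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occupancy, threshold_percent = 95) {
  ggplot(occupancy, aes(x = .data$residue_index, y = .data$occupancy_percent,
                        fill = .data$group)) +
    geom_col() +
    geom_hline(yintercept = threshold_percent, linetype = "dashed") +
    labs(x = "residue index", y = "occupancy (%)", fill = "class") +
    theme_minimal()
}

#' Plot residue-class fraction profiles
#'
#' @param profile Tibble from [group_fraction_profile()] or
#'   [surface_composition()]; several profiles can be compared by
#'   binding rows with a `label` column.
#' @return A ggplot object.
#' @export
plot_group_fractions <- function(profile) {
  p <- ggplot(profile, aes(x = factor(.data$group, residue_group_levels()),
                           y = .data$fraction))
  if ("label" %in% names(profile)) {
    p <- p + geom_col(aes(fill = .data$label), position = "dodge")
  } else {
    p <- p + geom_col()
  }
  p + labs(x = "residue class", y = "fraction of selected residues") +
    theme_minimal()
}

#' Plot RMSD time series
#'
#' @param rmsd Tibble from [rmsd_series()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(rmsd) {
  ggplot(rmsd, aes(x = .data$time_ns, y = .data$rmsd_nm,
                   colour = .data$selection)) +
    geom_line() +
    labs(x = "time (ns)", y = "backbone RMSD (nm)") +
    theme_minimal()
}

#' Plot kinetic A240 traces with assay levels
#'
#' @param traces Trace tibble (`time_s`, `a240`, optional `sample_id`).
#' @param constants An [assay_constants()] supplying the level lines.
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, constants = assay_constants()) {
  p <- ggplot(traces, aes(x = .data$time_s, y = .data$a240))
  if ("sample_id" %in% names(traces)) {
    p <- p + geom_line(aes(colour = .data$sample_id))
  } else {
    p <- p + geom_line()
  }
  p +
    geom_hline(yintercept = c(constants$upper_level, constants$lower_level),
               linetype = "dashed") +
    labs(x = "time (s)", y = "A240") +
    theme_minimal()
}

#' Plot a protease-protection retention course
#'
#' @param course Tibble from [protection_course()].
#' @return A ggplot object.
#' @export
plot_protection <- function(course) {
  p <- ggplot(course, aes(x = .data$time_h, y = .data$retention_percent))
  if ("formulation" %in% names(course)) {
    p <- p + geom_line(aes(colour = .data$formulation)) +
      geom_point(aes(colour = .data$formulation))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p + labs(x = "time (h)", y = "retained activity (% of 0 h)") +
    theme_minimal()
}

#' Plot cohort area loss by treatment group
#'
#' Box-and-jitter plot of per-subject percent area loss.
#'
#' @param cohort Cohort tibble (`group`, `ipsi_area`, `contra_area`).
#' @return A ggplot object.
#' @export
plot_area_loss <- function(cohort) {
  cohort$area_loss_percent <- suppressWarnings(
    area_loss(cohort$ipsi_area, cohort$contra_area)
  )
  ggplot(cohort, aes(x = .data$group, y = .data$area_loss_percent)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    labs(x = NULL, y = "area loss (%)") +
    theme_minimal()
}
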