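#' Default run configuration
#'
#' All analysis defaults in one list: the contact criterion (4.0 A
#' cutoff, >95% selection, heavy atoms only), the catalase assay
#' constants (3.45 umol, 0.1 mL, levels 0.45/0.40), the 0-4 score scale,
#' the serum-albumin domain boundaries, and statistics options. A config
#' round-trips through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    contacts = list(cutoff = 4.0, threshold_percent = 95.0,
                    heavy_atoms_only = TRUE, dt_ns = 1.0),
    assay = list(decomposed_umol = 3.45, sample_volume_ml = 0.1,
                 upper_level = 0.45, lower_level = 0.40,
                 initial_window = c(0.48, 0.52)),
    score = list(breaks = c(25, 50, 75)),
    domains = as.data.frame(albumin_domains()),
    stats = list(exact_max_n = 16, alpha = 0.05),
    seed = 1L
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  for (section in names(user)) {
    if (is.list(user[[section]]) && is.list(cfg[[section]])) {
      for (k in names(user[[section]])) cfg[[section]][[k]] <- user[[section]][[k]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_contact_params <- function(config) {
  contact_parameters(
    cutoff = config$contacts$cutoff,
    threshold_percent = config$contacts$threshold_percent,
    heavy_atoms_only = config$contacts$heavy_atoms_only
  )
}

config_assay_constants <- function(config) {
  assay_constants(
    decomposed_umol = config$assay$decomposed_umol,
    sample_volume_ml = config$assay$sample_volume_ml,
    upper_level = config$assay$upper_level,
    lower_level = config$assay$lower_level,
    initial_window = unlist(config$assay$initial_window)
  )
}

#' Write an occupancy table as CSV
#'
#' Columns, exactly: `residue_index,residue_name,chain,group,`
#' `contact_frames,total_frames,occupancy_percent`.
#'
#' @param occupancy Tibble from [compute_occupancy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  readr::write_csv(
    occupancy[, c("residue_index", "residue_name", "chain", "group",
                  "contact_frames", "total_frames", "occupancy_percent")],
    path
  )
  invisible(path)
}

#' Write a residue-class fraction profile as JSON
#'
#' Keys, exactly: `negative`, `positive`, `polar`, `hydrophobic`,
#' `aromatic`, `n_selected`, `threshold_percent`.
#'
#' @param profile Tibble from [group_fraction_profile()] or
#'   [surface_composition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_fractions_json <- function(profile, path) {
  x <- as.list(stats::setNames(profile$fraction, profile$group))
  x$n_selected <- attr(profile, "n_selected")
  x$threshold_percent <- attr(profile, "threshold_percent")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an RMSD series as CSV
#'
#' Columns, exactly: `frame,time_ns,selection,rmsd_nm`.
#'
#' @param rmsd Tibble from [rmsd_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_csv <- function(rmsd, path) {
  readr::write_csv(rmsd[, c("frame", "time_ns", "selection", "rmsd_nm")], path)
  invisible(path)
}

#' Run the trajectory contact/RMSD analysis end to end
#'
#' Reads a structure PDB (reference) and a multi-model trajectory PDB,
#' computes the occupancy table, the high-occupancy residue-class
#' profile and the backbone RMSD series (whole backbone plus any
#' configured domains), and writes
#' `occupancy.csv`, `group_fractions.json` and `rmsd.csv` into
#' `out_dir`.
#'
#' @param structure_path Reference-structure PDB.
#' @param trajectory_path Multi-model trajectory PDB.
#' @param out_dir Output directory (created if missing).
#' @param config A `run_config` (default [default_run_config()]).
#' @return Invisibly, a list with `occupancy`, `profile`, `rmsd` and the
#'   output paths.
#' @export
run_contacts <- function(structure_path, trajectory_path, out_dir,
                         config = default_run_config()) {
  ref <- read_structure(structure_path)
  tr <- read_trajectory_pdb(trajectory_path, dt_ns = config$contacts$dt_ns)
  if (tr$system$n_atoms != ref$system$n_atoms) {
    abort("structure and trajectory atom counts differ")
  }
  params <- config_contact_params(config)
  occupancy <- compute_occupancy(ref$system, tr$traj, params)
  profile <- group_fraction_profile(occupancy, params)
  domains <- NULL
  if (!is.null(config$domains)) {
    dom <- as_tibble(config$domains)
    dom <- dom[dom$start <= max(occupancy$residue_index), , drop = FALSE]
    if (nrow(dom) > 0) domains <- dom
  }
  rmsd <- rmsd_series(ref$system, tr$traj, ref$coords)
  if (!is.null(domains)) {
    rmsd <- bind_rows(rmsd, rmsd_series(ref$system, tr$traj, ref$coords,
                                        domains = domains))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    occupancy = file.path(out_dir, "occupancy.csv"),
    group_fractions = file.path(out_dir, "group_fractions.json"),
    rmsd = file.path(out_dir, "rmsd.csv")
  )
  write_occupancy_csv(occupancy, paths$occupancy)
  write_group_fractions_json(profile, paths$group_fractions)
  write_rmsd_csv(rmsd, paths$rmsd)
  invisible(list(occupancy = occupancy, profile = profile, rmsd = rmsd,
                 paths = paths))
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(paste0(path, " has no data rows"))
  df
}

#' Run the assay analytics end to end
#'
#' Computes per-sample catalase activities from a trace CSV
#' (`sample_id,time_s,a240`, optional `dilution_factor`), protein
#' concentrations from a plate CSV
#' (`sample_id,role,known_conc_ug_ml,absorbance,dilution_factor`), and,
#' when a loading table (`formulation,loading_activity_au_ml,`
#' `loading_mass_ug_ml`) is supplied, specific activities and percent
#' deactivation of every formulation relative to the highest specific
#' activity. Writes `activity.csv` and `loading.json` into `out_dir`.
#'
#' @param trace_path Kinetic trace CSV (or `NULL` to skip).
#' @param plate_path BCA plate CSV (or `NULL` to skip).
#' @param loading_path Loading table CSV (or `NULL` to skip).
#' @param out_dir Output directory.
#' @param config A `run_config`.
#' @return Invisibly, a list with `activity`, `bca`, `loading` tibbles
#'   (those computed) and output paths.
#' @export
run_assays <- function(trace_path = NULL, plate_path = NULL,
                       loading_path = NULL, out_dir,
                       config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = list())
  constants <- config_assay_constants(config)
  if (!is.null(trace_path)) {
    traces <- read_csv_strict(trace_path, c("sample_id", "time_s", "a240"))
    out$activity <- catalase_activity(traces, constants = constants)
    out$paths$activity <- file.path(out_dir, "activity.csv")
    readr::write_csv(out$activity, out$paths$activity)
  }
  if (!is.null(plate_path)) {
    plate <- read_csv_strict(
      plate_path,
      c("sample_id", "role", "known_conc_ug_ml", "absorbance", "dilution_factor")
    )
    curve <- bca_fit(plate[plate$role == "standard", ])
    unknowns <- plate[plate$role == "unknown", ]
    quant <- bca_quantify(curve, unknowns$absorbance, unknowns$dilution_factor)
    out$bca <- bind_rows(tibble(sample_id = unknowns$sample_id, quant))
    out$curve <- curve
    out$paths$bca <- file.path(out_dir, "bca.csv")
    readr::write_csv(out$bca, out$paths$bca)
  }
  if (!is.null(loading_path)) {
    loading <- read_csv_strict(
      loading_path,
      c("formulation", "loading_activity_au_ml", "loading_mass_ug_ml")
    )
    loading$specific_activity_au_mg <- specific_activity(
      loading$loading_activity_au_ml, loading$loading_mass_ug_ml
    )
    ref <- max(loading$specific_activity_au_mg)
    loading$percent_deactivation <- percent_deactivation(
      ref, loading$specific_activity_au_mg
    )
    out$loading <- loading
    out$paths$loading <- file.path(out_dir, "loading.json")
    jsonlite::write_json(
      stats::setNames(
        purrr::map(seq_len(nrow(loading)), function(i) as.list(loading[i, -1])),
        loading$formulation
      ),
      out$paths$loading, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}

#' Run the injury analysis end to end
#'
#' Reads a cohort CSV
#' (`subject_id,sex,group,gross_score,ipsi_area,contra_area`),
#' summarizes each group (n by sex; median/IQR of area loss and gross
#' score) and compares every treatment group against the control by the
#' two-tailed Wilcoxon-Mann-Whitney U test for both outcomes. With a
#' single group, summaries are returned with a warning and no tests.
#' Writes `injury_report.json` into `out_dir`.
#'
#' @param cohort_path Cohort CSV.
#' @param control Control group label (default `"saline"`).
#' @param out_dir Output directory.
#' @param config A `run_config`.
#' @param declared_groups Optional allowed group labels.
#' @return Invisibly, a list with `summary`, `tests` and the report
#'   path.
#' @export
run_injury <- function(cohort_path, control = "saline", out_dir,
                       config = default_run_config(),
                       declared_groups = NULL) {
  cohort <- read_csv_strict(
    cohort_path,
    c("subject_id", "sex", "group", "ipsi_area", "contra_area")
  )
  summ <- cohort_summary(cohort, declared_groups = declared_groups)
  tests <- NULL
  if (length(unique(cohort$group)) < 2) {
    warn("single-group cohort: summaries only, no tests")
  } else {
    tests <- bind_rows(
      injury_compare(cohort, control, "area_loss",
                     exact_max_n = config$stats$exact_max_n),
      if ("gross_score" %in% names(cohort) && any(!is.na(cohort$gross_score))) {
        injury_compare(cohort, control, "gross_score",
                       exact_max_n = config$stats$exact_max_n)
      }
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(out_dir, "injury_report.json")
  jsonlite::write_json(
    list(
      totals = as.list(summ$totals),
      counts = summ$counts,
      area_loss = summ$area_loss,
      gross_score = summ$gross_score,
      tests = tests
    ),
    report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(list(summary = summ, tests = tests, report = report_path))
}

#' Materialize a complete synthetic demo dataset
#'
#' Writes, into one directory, every input format the pipeline reads,
#' generated with known ground truth: a reference PDB + multi-model
#' trajectory with planted occupancies (`structure.pdb`,
#' `trajectory.pdb`), a kinetic trace CSV (`traces.csv`), a BCA plate
#' CSV (`plate.csv`), a loading table (`loading.csv`) and a cohort CSV
#' (`cohort.csv`), plus `ground_truth.json` recording the planted
#' values.
#'
#' @param dir Output directory.
#' @param seed Integer seed controlling every random choice.
#' @return Invisibly, a list of the written paths and the ground truth.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_system(
    sequence = c("ALA", "ASP", "PHE", "LYS", "SER", "GLU", "LEU", "TYR"),
    n_ligands = 8  # enough for the worst-case simultaneous plants below
  )
  targets <- c(100, 30, 0, 96, 50, 10, 80, 100)
  planted <- plant_contact_trajectory(toy$system, toy$coords, targets,
                                      n_frames = 10, seed = seed)
  write_system_pdb(toy$system, toy$coords, file.path(dir, "structure.pdb"))
  write_system_pdb(toy$system, planted$traj, file.path(dir, "trajectory.pdb"))

  tr <- gen_kinetic_trace(a0 = 0.50, k = 0.002, sigma = 0, sample_id = "cat_1")
  readr::write_csv(tr$trace, file.path(dir, "traces.csv"))

  plate <- gen_plate_readings(seed = seed)
  readr::write_csv(plate, file.path(dir, "plate.csv"))

  loading <- tibble(
    formulation = c("nanoprecipitation", "emulsion"),
    loading_activity_au_ml = c(383, 393),
    loading_mass_ug_ml = c(76, 298)
  )
  readr::write_csv(loading, file.path(dir, "loading.csv"))

  cohort <- gen_cohort(seed = seed)
  readr::write_csv(cohort$cohort, file.path(dir, "cohort.csv"))

  truth <- list(
    planted_counts = planted$planted_counts,
    trace = list(t_upper_s = tr$t_upper_s, t_lower_s = tr$t_lower_s,
                 delta_t_min = tr$delta_t_min),
    plate_truth = attr(plate, "truth"),
    cohort_truth = cohort$truth
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(dir = dir, truth = truth))
}
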