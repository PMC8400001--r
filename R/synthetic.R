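with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Build a toy linear-chain protein with parked ligands
#'
#' A minimal system for exercising the contact and RMSD analytics with
#' known geometry: residues laid out along x at 3.8 A CA-CA spacing,
#' each with backbone atoms N, CA, C plus one CB sidechain pseudo-atom;
#' ligands are single-carbon molecules parked far (>= 20 A) from every
#' residue so the baseline occupancy is zero.
#'
#' @param n_residues Number of residues (alanines) when `sequence` is
#'   not given.
#' @param sequence Character vector of 3-letter residue codes; must all
#'   be classifiable by [residue_group_table()].
#' @param n_ligands Number of single-atom ligand molecules (default 1).
#' @param chain Chain identifier for the protein (default `"A"`).
#'
#' @return A list with `system` (a [mol_system()]) and `coords`
#'   (reference coordinates, Angstrom).
#' @export
#' @examples
#' make_toy_system(sequence = c("ALA", "ASP", "PHE"))$system
make_toy_system <- function(n_residues = NULL, sequence = NULL, n_ligands = 1,
                            chain = "A") {
  if (is.null(sequence)) {
    if (is.null(n_residues) || n_residues < 1) abort("n_residues must be >= 1")
    sequence <- rep("ALA", n_residues)
  }
  classify_residue(sequence)  # errors on unknown codes
  n_res <- length(sequence)
  atom_names <- c("N", "CA", "C", "CB")
  offsets <- rbind(
    N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0), CB = c(0, -1.5, 0)
  )
  prot <- tidyr::expand_grid(res = seq_len(n_res), atom = seq_along(atom_names))
  prot_coords <- cbind((prot$res - 1) * 3.8, 0, 0) + offsets[prot$atom, ]
  atoms <- tibble(
    atom_index = seq_len(nrow(prot)),
    name = atom_names[prot$atom],
    element = ifelse(atom_names[prot$atom] == "N", "N", "C"),
    is_hydrogen = FALSE,
    residue_index = prot$res,
    residue_name = sequence[prot$res],
    chain = chain,
    entity = "protein",
    ligand_id = NA_integer_
  )
  coords <- prot_coords
  if (n_ligands > 0) {
    park <- toy_park_positions(prot_coords, n_ligands)
    lig <- tibble(
      atom_index = nrow(prot) + seq_len(n_ligands),
      name = "C1",
      element = "C",
      is_hydrogen = FALSE,
      residue_index = seq_len(n_ligands),
      residue_name = "LIG",
      chain = "L",
      entity = "ligand",
      ligand_id = seq_len(n_ligands)
    )
    atoms <- bind_rows(atoms, lig)
    coords <- rbind(coords, park)
  }
  list(system = mol_system(atoms), coords = unname(coords))
}

# parking spots well away from every protein atom (>= ~40 A)
toy_park_positions <- function(prot_coords, n_ligands) {
  y_max <- max(prot_coords[, 2])
  cbind(
    min(prot_coords[, 1]) + (seq_len(n_ligands) - 1) * 10,
    y_max + 40,
    0
  )
}

#' Plant known per-residue contact occupancies into a trajectory
#'
#' The counting oracle for occupancy analysis: for each protein residue
#' `i` with target occupancy `p_i` percent over `F` frames, a ligand
#' atom is placed exactly `plant_distance` Angstrom from the residue's
#' CA in `round(p_i * F / 100)` seeded-chosen frames; in all other
#' frames every ligand sits parked at least twice the cutoff from every
#' residue. Ligand motion is deliberately discontinuous — physically
#' unreal, but it makes the planted counts exact ground truth.
#'
#' The planted geometry is verified frame-by-frame: if a planted ligand
#' would also fall within the cutoff of a neighbouring residue (possible
#' for plant distances below ~2.9 A with the toy chain geometry), or if
#' a frame needs more simultaneous plants than there are ligand
#' molecules, the plan is infeasible and an error is raised.
#'
#' @param system A [mol_system()] from [make_toy_system()].
#' @param ref_coords Reference coordinates for the system.
#' @param target_percent Numeric vector of target occupancies in
#'   percent, one per protein residue (in residue order).
#' @param n_frames Number of frames.
#' @param plant_distance Contact placement distance in Angstrom, must be
#'   below `cutoff` (default 3.0).
#' @param cutoff Contact cutoff the trajectory is built for (default 4).
#' @param seed Integer seed; same seed, same trajectory.
#'
#' @return A list with `traj` (a [trajectory_frames()]) and
#'   `planted_counts` (tibble `residue_index`, `planted_frames`).
#' @export
plant_contact_trajectory <- function(system, ref_coords, target_percent,
                                     n_frames, plant_distance = 3.0,
                                     cutoff = 4.0, seed = NULL) {
  if (plant_distance >= cutoff) abort("plant_distance must be below the cutoff")
  if (any(target_percent < 0 | target_percent > 100)) {
    abort("target occupancies must lie in [0, 100]")
  }
  atoms <- system$atoms
  prot <- atoms[atoms$entity == "protein", ]
  res_idx <- unique(prot$residue_index)
  n_res <- length(res_idx)
  if (length(target_percent) != n_res) {
    abort("target_percent must have one entry per protein residue")
  }
  n_lig <- system$n_ligand_molecules
  if (n_lig == 0) abort("system has no ligand molecules to plant")
  counts <- round(target_percent * n_frames / 100)

  plan <- with_seed_if(seed, {
    lapply(seq_len(n_res), function(i) sort(sample(n_frames, counts[i])))
  })
  # residues planted in each frame
  by_frame <- vector("list", n_frames)
  for (i in seq_len(n_res)) {
    for (f in plan[[i]]) by_frame[[f]] <- c(by_frame[[f]], i)
  }
  too_many <- which(vapply(by_frame, length, integer(1)) > n_lig)
  if (length(too_many) > 0) {
    abort(sprintf(
      "infeasible simultaneous plants: frame %d needs %d ligand molecules but the system has %d",
      too_many[1], length(by_frame[[too_many[1]]]), n_lig
    ))
  }

  lig_atoms <- atoms[atoms$entity == "ligand", ]
  park <- ref_coords[lig_atoms$atom_index, , drop = FALSE]
  # parked ligands must stay at least twice the cutoff from every residue
  park_d2 <- outer(rowSums(park^2),
                   rowSums(ref_coords[atoms$atom_index[atoms$entity == "protein"], ,
                                      drop = FALSE]^2), "+") -
    2 * tcrossprod(park, ref_coords[atoms$atom_index[atoms$entity == "protein"], ,
                                    drop = FALSE])
  if (min(park_d2) < (2 * cutoff)^2) {
    abort("reference ligand positions are too close to the protein to serve as parking spots")
  }
  ca_rows <- prot$atom_index[prot$name == "CA"]
  prot_rows <- prot$atom_index
  prot_xyz <- ref_coords[prot_rows, , drop = FALSE]
  res_of_prot_atom <- match(prot$residue_index, res_idx)

  coords <- array(NA_real_, c(system$n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    xyz <- ref_coords
    xyz[lig_atoms$atom_index, ] <- park
    for (slot in seq_along(by_frame[[f]])) {
      i <- by_frame[[f]][slot]
      pos <- ref_coords[ca_rows[i], ] + c(0, 0, plant_distance)
      xyz[lig_atoms$atom_index[lig_atoms$ligand_id == slot], ] <-
        matrix(pos, nrow = sum(lig_atoms$ligand_id == slot), ncol = 3, byrow = TRUE)
      # verify the plant touches residue i and only residue i
      d2 <- rowSums(sweep(prot_xyz, 2, pos)^2)
      touched <- unique(res_of_prot_atom[d2 <= cutoff^2])
      if (!identical(sort(touched), i)) {
        abort(sprintf(
          "infeasible planting geometry: a ligand planted %.2f A from residue %d also contacts residue(s) %s",
          plant_distance, res_idx[i],
          paste(setdiff(res_idx[touched], res_idx[i]), collapse = ", ")
        ))
      }
    }
    coords[, , f] <- xyz
  }
  list(
    traj = trajectory_frames(coords, seq_len(n_frames) - 1),
    planted_counts = tibble(residue_index = res_idx,
                            planted_frames = as.integer(counts))
  )
}

#' Random proper rotation matrix
#'
#' Uniform random rotation via a normalized quaternion; determinant +1.
#'
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  q <- with_seed_if(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate frames as rigid motions of a reference plus noise
#'
#' Each frame applies a proper rigid transform (random per frame by
#' default, or a supplied schedule) to the reference coordinates and
#' adds independent Gaussian noise per coordinate. With `sigma = 0` the
#' frames are exact rigid motions, so any superposition-based RMSD must
#' vanish; with noise, the expected fitted RMSD of N >> 1 atoms
#' approaches `sigma * sqrt(3)`.
#'
#' @param reference `n_atoms` x 3 reference coordinates (Angstrom).
#' @param n_frames Number of frames (>= 1).
#' @param transforms Optional list of per-frame `list(rotation,
#'   translation)`; defaults to seeded random rigid transforms.
#' @param sigma Per-coordinate Gaussian noise standard deviation in
#'   Angstrom (default 0).
#' @param seed Integer seed.
#'
#' @return A [trajectory_frames()].
#' @export
perturb_frames <- function(reference, n_frames, transforms = NULL,
                           sigma = 0, seed = NULL) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (sigma < 0) abort("sigma must be non-negative")
  reference <- as.matrix(reference)
  n_atoms <- nrow(reference)
  with_seed_if(seed, {
    if (is.null(transforms)) {
      transforms <- lapply(seq_len(n_frames), function(f) {
        list(rotation = random_rotation(), translation = stats::rnorm(3, sd = 5))
      })
    }
    if (length(transforms) != n_frames) {
      abort("transforms must supply one rigid transform per frame")
    }
    coords <- array(NA_real_, c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      tr <- transforms[[f]]
      xyz <- reference %*% t(tr$rotation)
      xyz <- sweep(xyz, 2, tr$translation, "+")
      if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(3 * n_atoms, sd = sigma), n_atoms, 3)
      coords[, , f] <- xyz
    }
    trajectory_frames(coords, seq_len(n_frames) - 1)
  })
}

#' Generate a first-order kinetic absorbance trace
#'
#' Emulates a catalase assay readout: `A240(t) = a0 * exp(-k t)` sampled
#' at a fixed interval, with optional additive Gaussian noise. The
#' analytic level-crossing times `t(L) = ln(a0 / L) / k` are returned as
#' ground truth for the crossing-time assay.
#'
#' @param a0 Initial absorbance (> 0.40; values at or below 0.45 cannot
#'   produce a usable two-level trace and values at or below 0.40 are an
#'   error).
#' @param k First-order rate constant in 1/s (> 0).
#' @param interval_s Sampling interval in seconds (default 2).
#' @param duration_s Trace duration in seconds (default 180).
#' @param sigma Additive absorbance noise SD (default 0).
#' @param seed Integer seed.
#' @param sample_id Sample label on the trace (default `"synthetic"`).
#' @param upper_level,lower_level Levels whose analytic crossing times
#'   are reported (defaults 0.45 and 0.40).
#'
#' @return A list: `trace` (tibble `sample_id`, `time_s`, `a240`),
#'   `t_upper_s`, `t_lower_s`, `delta_t_min` (analytic values).
#' @export
gen_kinetic_trace <- function(a0 = 0.50, k = 0.002, interval_s = 2,
                              duration_s = 180, sigma = 0, seed = NULL,
                              sample_id = "synthetic",
                              upper_level = 0.45, lower_level = 0.40) {
  if (a0 <= lower_level) {
    abort("a0 must exceed the lower level for the trace to cross it from above")
  }
  if (a0 <= upper_level) {
    warn("a0 at or below the upper level: trace will not cross it from above")
  }
  if (k <= 0 || interval_s <= 0) abort("k and interval_s must be positive")
  t <- seq(0, duration_s, by = interval_s)
  a <- a0 * exp(-k * t)
  if (sigma > 0) {
    a <- a + with_seed_if(seed, stats::rnorm(length(t), sd = sigma))
    a <- pmax(a, 0)
  }
  list(
    trace = tibble(sample_id = sample_id, time_s = t, a240 = a),
    t_upper_s = log(a0 / upper_level) / k,
    t_lower_s = log(a0 / lower_level) / k,
    delta_t_min = log(upper_level / lower_level) / k / 60
  )
}

#' Generate BCA plate readings from a known standard line
#'
#' @param slope,intercept True line `A562 = intercept + slope * conc`.
#' @param standard_concs Calibration concentrations in ug/mL.
#' @param unknown_concs True concentrations of unknown samples.
#' @param unknown_dilutions Dilution factors of the unknowns.
#' @param sigma Additive absorbance noise SD (default 0).
#' @param seed Integer seed.
#'
#' @return A tibble in plate-CSV layout: `sample_id`, `role`
#'   (`standard` / `unknown`), `known_conc_ug_ml`, `absorbance`,
#'   `dilution_factor`; attribute `truth` carries the unknowns' true
#'   concentrations after dilution correction.
#' @export
gen_plate_readings <- function(slope = 0.05, intercept = 0.1,
                               standard_concs = c(0, 5, 10, 20, 40),
                               unknown_concs = c(8, 25),
                               unknown_dilutions = rep(1, length(unknown_concs)),
                               sigma = 0, seed = NULL) {
  if (length(unknown_dilutions) != length(unknown_concs)) {
    abort("unknown_dilutions must match unknown_concs in length")
  }
  n_s <- length(standard_concs); n_u <- length(unknown_concs)
  noise <- if (sigma > 0) with_seed_if(seed, stats::rnorm(n_s + n_u, sd = sigma)) else 0
  abs_all <- intercept + slope * c(standard_concs, unknown_concs / unknown_dilutions) + noise
  out <- tibble(
    sample_id = c(paste0("std_", seq_len(n_s)), paste0("unk_", seq_len(n_u))),
    role = c(rep("standard", n_s), rep("unknown", n_u)),
    known_conc_ug_ml = c(standard_concs, rep(NA_real_, n_u)),
    absorbance = abs_all,
    dilution_factor = c(rep(1, n_s), unknown_dilutions)
  )
  attr(out, "truth") <- tibble(
    sample_id = paste0("unk_", seq_len(n_u)),
    true_conc_ug_ml = unknown_concs
  )
  out
}

#' Default treatment-arm layout for synthetic cohorts
#'
#' Three arms sized like a typical neonatal hypoxia-ischemia efficacy
#' study (58 pups: saline 12 m + 11 f, blank nanoparticles 9 m + 7 f,
#' catalase nanoparticles 9 m + 10 f) with zero planted treatment
#' effect; edit `shift` to plant a location effect on lesion percent.
#'
#' @return A tibble with columns `group`, `n_male`, `n_female`, `shift`.
#' @export
default_cohort_groups <- function() {
  tibble(
    group = c("saline", "blank_np", "catalase_np"),
    n_male = c(12L, 9L, 9L),
    n_female = c(11L, 7L, 10L),
    shift = 0
  )
}

#' Generate a synthetic injury cohort with known group effects
#'
#' Lesion percent is drawn from a two-component mixture — a mild
#' component N(`mild_mean`, `mild_sd`) and a severe component
#' N(`severe_mean`, `severe_sd`) with weight `severe_weight` — clamped
#' to [0, 99.5], mirroring the bimodal, right-skewed injury
#' distributions characteristic of the unilateral hypoxia-ischemia
#' model. Each group's `shift` is added to its lesion draws before
#' clamping (the planted effect). Hemisphere areas are back-computed so
#' that [area_loss()] recovers the latent lesion percent exactly, and
#' gross scores come from [lesion_to_score()].
#'
#' @param groups Tibble of arms (`group`, `n_male`, `n_female`,
#'   `shift`); see [default_cohort_groups()].
#' @param mild_mean,mild_sd,severe_mean,severe_sd,severe_weight Mixture
#'   parameters on the lesion-percent scale.
#' @param contra_mean,contra_sd Contralateral-area distribution (mm^2).
#' @param seed Integer seed.
#'
#' @return A list with `cohort` (tibble `subject_id`, `sex`, `group`,
#'   `gross_score`, `ipsi_area`, `contra_area`) and `truth` (per-group
#'   planted shift and realized median lesion).
#' @export
gen_cohort <- function(groups = default_cohort_groups(),
                       mild_mean = 8, mild_sd = 5,
                       severe_mean = 60, severe_sd = 15,
                       severe_weight = 0.3,
                       contra_mean = 50, contra_sd = 2,
                       seed = NULL) {
  if (any(groups$n_male + groups$n_female < 1)) abort("each group needs >= 1 subject")
  if (severe_weight < 0 || severe_weight > 1) abort("severe_weight must lie in [0, 1]")
  with_seed_if(seed, {
    rows <- purrr::pmap(groups, function(group, n_male, n_female, shift) {
      n <- n_male + n_female
      severe <- stats::runif(n) < severe_weight
      lesion <- ifelse(
        severe,
        stats::rnorm(n, severe_mean, severe_sd),
        stats::rnorm(n, mild_mean, mild_sd)
      ) + shift
      lesion <- pmin(pmax(lesion, 0), 99.5)
      contra <- pmax(stats::rnorm(n, contra_mean, contra_sd), 1)
      tibble(
        sex = c(rep("male", n_male), rep("female", n_female)),
        group = group,
        lesion_percent = lesion,
        gross_score = lesion_to_score(lesion),
        ipsi_area = contra * (1 - lesion / 100),
        contra_area = contra
      )
    }) |> bind_rows()
    rows$subject_id <- sprintf("subj_%03d", seq_len(nrow(rows)))
    cohort <- select(rows, "subject_id", "sex", "group", "gross_score",
                     "ipsi_area", "contra_area")
    truth <- rows |>
      group_by(.data$group) |>
      summarise(median_lesion = stats::median(.data$lesion_percent),
                .groups = "drop") |>
      left_join(select(groups, "group", "shift"), by = "group")
    list(cohort = cohort, truth = truth)
  })
}
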