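#' Default contact parameters
#'
#' Contacts are counted between protein residues and ion-pairing agent
#' molecules using a heavy-atom minimum-distance criterion: a residue is
#' in contact in a frame when any ligand molecule has an atom within
#' `cutoff` Angstrom of any of the residue's atoms (boundary inclusive).
#'
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0).
#' @param threshold_percent High-occupancy selection threshold in percent
#'   (default 95; selection is strictly greater than the threshold).
#' @param heavy_atoms_only Exclude hydrogens from the distance test
#'   (default `TRUE`).
#'
#' @return A list of class `contact_parameters`.
#' @export
contact_parameters <- function(cutoff = 4.0, threshold_percent = 95.0,
                               heavy_atoms_only = TRUE) {
  if (cutoff <= 0) abort("cutoff must be positive")
  if (threshold_percent < 0 || threshold_percent > 100) {
    abort("threshold_percent must lie in [0, 100]")
  }
  structure(
    list(cutoff = cutoff, threshold_percent = threshold_percent,
         heavy_atoms_only = heavy_atoms_only),
    class = "contact_parameters"
  )
}

#' Minimum residue-ligand distance in one frame
#'
#' The primitive behind occupancy counting: the minimum Euclidean
#' distance over all (residue atom, ligand atom) pairs, optionally after
#' dropping hydrogens from both sets.
#'
#' @param coords `n_atoms` x 3 coordinate matrix for the frame (Angstrom).
#' @param residue_atoms Integer atom indices of the residue.
#' @param ligand_atoms Integer atom indices of the ligand molecule.
#' @param is_hydrogen Logical vector over all atoms.
#' @param heavy_atoms_only Drop hydrogens before measuring.
#'
#' @return Minimum distance in Angstrom.
#' @export
residue_ligand_min_distance <- function(coords, residue_atoms, ligand_atoms,
                                        is_hydrogen = rep(FALSE, nrow(coords)),
                                        heavy_atoms_only = TRUE) {
  if (heavy_atoms_only) {
    residue_atoms <- residue_atoms[!is_hydrogen[residue_atoms]]
    ligand_atoms <- ligand_atoms[!is_hydrogen[ligand_atoms]]
  }
  if (length(residue_atoms) == 0 || length(ligand_atoms) == 0) {
    abort("empty atom set after hydrogen filtering")
  }
  a <- coords[residue_atoms, , drop = FALSE]
  b <- coords[ligand_atoms, , drop = FALSE]
  # squared cross-distance matrix via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Per-residue ligand-contact occupancy over a trajectory
#'
#' For each protein residue, counts the frames in which any ligand
#' molecule lies within the contact cutoff and converts the count to a
#' percent occupancy (100 x contact frames / total frames).
#'
#' @param system A [mol_system()] with at least one protein residue and
#'   one ligand molecule.
#' @param traj A [trajectory_frames()] over the same atoms.
#' @param params A [contact_parameters()].
#' @param groups Residue-class mapping used to label rows; see
#'   [residue_group_table()].
#' @param per_molecule If `TRUE`, additionally attach a per-ligand-molecule
#'   occupancy table as attribute `"per_molecule"`.
#'
#' @return A tibble with columns `residue_index`, `residue_name`, `chain`,
#'   `group`, `contact_frames`, `total_frames`, `occupancy_percent` —
#'   one row per protein residue.
#' @export
#' @examples
#' toy <- make_toy_system(sequence = c("ALA", "ASP", "PHE"), n_ligands = 2)
#' pl <- plant_contact_trajectory(toy$system, toy$coords,
#'   target_percent = c(100, 30, 0), n_frames = 10, seed = 1)
#' compute_occupancy(toy$system, pl$traj)
compute_occupancy <- function(system, traj, params = contact_parameters(),
                              groups = residue_group_table(),
                              per_molecule = FALSE) {
  atoms <- system$atoms
  if (traj$n_atoms != system$n_atoms) {
    abort("trajectory atom count does not match system")
  }
  prot <- atoms[atoms$entity == "protein", ]
  lig <- atoms[atoms$entity == "ligand", ]
  if (nrow(lig) == 0) abort("no ligand molecules in system")
  if (nrow(prot) == 0) abort("no protein residues in system")
  if (params$heavy_atoms_only) {
    prot <- prot[!prot$is_hydrogen, ]
    lig <- lig[!lig$is_hydrogen, ]
    if (nrow(lig) == 0) abort("no ligand heavy atoms after hydrogen filtering")
    if (nrow(prot) == 0) abort("no protein heavy atoms after hydrogen filtering")
  }
  res_key <- paste(prot$chain, prot$residue_index)
  res_levels <- unique(res_key)
  res_of_atom <- match(res_key, res_levels)
  n_res <- length(res_levels)
  cut2 <- params$cutoff^2
  n_frames <- traj$n_frames
  mol_ids <- sort(unique(lig$ligand_id))

  counts <- integer(n_res)
  mol_counts <- matrix(0L, n_res, length(mol_ids))
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[, , f]
    a <- xyz[prot$atom_index, , drop = FALSE]
    b <- xyz[lig$atom_index, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    hit_atom_any <- matrixStats_rowMins(d2) <= cut2
    in_contact <- as.logical(tapply(hit_atom_any, res_of_atom, any))
    counts <- counts + in_contact
    if (per_molecule) {
      for (j in seq_along(mol_ids)) {
        cols <- which(lig$ligand_id == mol_ids[j])
        hit <- matrixStats_rowMins(d2[, cols, drop = FALSE]) <= cut2
        mol_counts[, j] <- mol_counts[, j] + as.integer(tapply(hit, res_of_atom, any))
      }
    }
  }

  first_atom <- match(res_levels, res_key)
  out <- tibble(
    residue_index = prot$residue_index[first_atom],
    residue_name = prot$residue_name[first_atom],
    chain = prot$chain[first_atom],
    group = classify_residue(prot$residue_name[first_atom], groups),
    contact_frames = as.integer(counts),
    total_frames = n_frames,
    occupancy_percent = 100 * counts / n_frames
  )
  if (per_molecule) {
    pm <- tidyr::expand_grid(residue = seq_len(n_res), ligand_id = seq_along(mol_ids))
    attr(out, "per_molecule") <- tibble(
      residue_index = out$residue_index[pm$residue],
      chain = out$chain[pm$residue],
      ligand_id = mol_ids[pm$ligand_id],
      contact_frames = as.integer(mol_counts[cbind(pm$residue, pm$ligand_id)]),
      total_frames = n_frames,
      occupancy_percent = 100 * mol_counts[cbind(pm$residue, pm$ligand_id)] / n_frames
    )
  }
  out
}

# row-wise minimum without a matrixStats dependency
matrixStats_rowMins <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  do.call(pmin, c(asplit(m, 2), list(na.rm = FALSE)))
}

#' Select residues above an occupancy threshold
#'
#' Returns the rows of an occupancy table whose occupancy is strictly
#' greater than the threshold (the sub-selection applied before
#' residue-class profiling).
#'
#' @param occupancy Occupancy tibble from [compute_occupancy()].
#' @param threshold_percent Selection threshold in percent (default 95).
#' @return The selected rows, a tibble (possibly empty).
#' @export
select_high_occupancy <- function(occupancy, threshold_percent = 95) {
  filter(occupancy, .data$occupancy_percent > threshold_percent)
}

#' Default five-class residue grouping
#'
#' Every standard amino acid maps to exactly one of five chemical
#' classes: negative, positive, polar, hydrophobic, aromatic. Histidine
#' is placed with the positives because the complexation chemistry of
#' interest happens at acidic pH (3.7-4.7), where His is protonated.
#' The mapping is a plain tibble so an alternative scheme (e.g. TYR as
#' polar) can be substituted.
#'
#' @return A tibble with columns `residue_name` and `group`.
#' @export
residue_group_table <- function() {
  tibble(
    residue_name = c(
      "ASP", "GLU",
      "ARG", "LYS", "HIS",
      "PHE", "TRP", "TYR",
      "SER", "THR", "ASN", "GLN", "CYS", "GLY",
      "ALA", "VAL", "LEU", "ILE", "MET", "PRO"
    ),
    group = c(
      rep("negative", 2), rep("positive", 3), rep("aromatic", 3),
      rep("polar", 6), rep("hydrophobic", 6)
    )
  )
}

#' Residue classes in canonical order
#' @return Character vector of the five class labels.
#' @export
residue_group_levels <- function() {
  c("negative", "positive", "polar", "hydrophobic", "aromatic")
}

#' Classify residues into the five chemical classes
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @param groups Mapping tibble; see [residue_group_table()].
#' @return Character vector of group labels.
#' @export
classify_residue <- function(residue_name, groups = residue_group_table()) {
  idx <- match(toupper(residue_name), groups$residue_name)
  if (anyNA(idx)) {
    abort(paste0("unknown residue code(s): ",
                 paste(unique(residue_name[is.na(idx)]), collapse = ", ")))
  }
  groups$group[idx]
}

#' Residue-class fraction profile of high-occupancy residues
#'
#' Sub-selects residues whose occupancy exceeds the threshold, counts
#' them per chemical class, and normalizes by the number selected so
#' profiles are comparable across ligands. An empty selection yields an
#' all-zero profile with `n_selected = 0`.
#'
#' @param occupancy Occupancy tibble from [compute_occupancy()].
#' @param params A [contact_parameters()] supplying the threshold.
#' @param groups Residue-class mapping (used if `occupancy` lacks a
#'   `group` column).
#'
#' @return A tibble with one row per class: `group`, `n`, `fraction`;
#'   attributes `n_selected` and `threshold_percent`.
#' @export
group_fraction_profile <- function(occupancy, params = contact_parameters(),
                                   groups = residue_group_table()) {
  sel <- select_high_occupancy(occupancy, params$threshold_percent)
  if (!"group" %in% names(sel)) {
    sel$group <- classify_residue(sel$residue_name, groups)
  }
  lev <- residue_group_levels()
  counts <- table(factor(sel$group, levels = lev))
  n_sel <- nrow(sel)
  out <- tibble(
    group = lev,
    n = as.integer(counts),
    fraction = if (n_sel > 0) as.numeric(counts) / n_sel else rep(0, length(lev))
  )
  attr(out, "n_selected") <- n_sel
  attr(out, "threshold_percent") <- params$threshold_percent
  out
}
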