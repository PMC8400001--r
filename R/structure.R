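#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n distinct pull across if_else case_when first
NULL

# Residue codes treated as protein when partitioning a PDB.
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Solvent / counter-ion codes: neither protein nor ligand.
SOLVENT_CODES <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "NA", "CL", "K", "NA+", "CL-")

#' Construct a molecular system from an atom table
#'
#' A molecular system pairs an atom table (identity, residue and chain
#' assignment, entity tag) with nothing else: coordinates live in
#' [trajectory_frames()] so that one topology can serve many frames.
#'
#' @param atoms A data frame with columns `atom_index` (1-based integer),
#'   `name`, `element`, `is_hydrogen`, `residue_index` (1-based),
#'   `residue_name` (3-letter code), `chain`, `entity`
#'   (one of `"protein"`, `"ligand"`, `"other"`) and `ligand_id`
#'   (integer molecule id for ligand atoms, `NA` otherwise).
#'
#' @return An object of class `mol_system`: a list with element `atoms`
#'   (a tibble) plus convenience counts.
#' @export
mol_system <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c(
    "atom_index", "name", "element", "is_hydrogen", "residue_index",
    "residue_name", "chain", "entity", "ligand_id"
  )
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atoms is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("zero atoms in system")
  if (!all(atoms$entity %in% c("protein", "ligand", "other"))) {
    abort("entity must be one of protein, ligand, other")
  }
  lig <- atoms[atoms$entity == "ligand", ]
  if (nrow(lig) > 0 && anyNA(lig$ligand_id)) {
    abort("every ligand atom must carry a ligand_id")
  }
  # residue indices must increase (not necessarily by 1) within a chain
  for (ch in unique(atoms$chain[atoms$entity == "protein"])) {
    idx <- atoms$residue_index[atoms$entity == "protein" & atoms$chain == ch]
    if (is.unsorted(idx)) abort(paste0("residue indices not increasing in chain ", ch))
  }
  structure(
    list(
      atoms = atoms,
      n_atoms = nrow(atoms),
      n_protein_residues = nrow(distinct(
        atoms[atoms$entity == "protein", c("chain", "residue_index")]
      )),
      n_ligand_molecules = length(unique(stats::na.omit(atoms$ligand_id)))
    ),
    class = "mol_system"
  )
}

#' @export
print.mol_system <- function(x, ...) {
  cat(
    "<mol_system> ", x$n_atoms, " atoms, ",
    x$n_protein_residues, " protein residues, ",
    x$n_ligand_molecules, " ligand molecule(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a trajectory-frames container
#'
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`,
#'   coordinates in Angstrom, atom order matching the system.
#' @param times_ns Numeric vector of per-frame times in nanoseconds,
#'   strictly increasing and non-negative.
#'
#' @return An object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(coords, times_ns = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    abort("coords must be an n_atoms x 3 x n_frames array")
  }
  n_frames <- dim(coords)[3]
  if (n_frames < 1) abort("empty trajectory")
  if (is.null(times_ns)) times_ns <- seq_len(n_frames) - 1
  if (length(times_ns) != n_frames) abort("times_ns length must equal frame count")
  if (any(times_ns < 0) || is.unsorted(times_ns, strictly = TRUE)) {
    abort("frame times must be non-negative and strictly increasing")
  }
  if (!all(is.finite(coords))) abort("non-finite coordinates in trajectory")
  structure(
    list(coords = coords, times_ns = as.numeric(times_ns),
         n_frames = n_frames, n_atoms = dim(coords)[1]),
    class = "trajectory_frames"
  )
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat("<trajectory_frames> ", x$n_frames, " frames x ", x$n_atoms, " atoms, t = ",
      format(x$times_ns[1]), " .. ", format(x$times_ns[x$n_frames]), " ns\n", sep = "")
  invisible(x)
}

infer_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy %||% ""))
  el[is.na(el)] <- ""
  need <- el == ""
  if (any(need)) {
    # fall back to the atom-name convention: strip digits, take leading letters
    nm <- gsub("[0-9']", "", toupper(elety[need]))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    el[need] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two, one)
  }
  el
}

bio3d_to_atoms <- function(atom_df) {
  if (nrow(atom_df) == 0) abort("zero atoms")
  if (any(!is.na(atom_df$insert) & nzchar(atom_df$insert))) {
    abort("PDB insertion codes are not supported; renumber the structure first")
  }
  element <- infer_element(atom_df$elesy, atom_df$elety)
  chain <- ifelse(is.na(atom_df$chain), "A", atom_df$chain)
  resname <- toupper(atom_df$resid)
  entity <- case_when(
    resname %in% STANDARD_AA ~ "protein",
    resname %in% SOLVENT_CODES ~ "other",
    TRUE ~ "ligand"
  )
  # ligand molecules: one per (residue number, chain) among ligand atoms
  lig_key <- ifelse(entity == "ligand", paste(chain, atom_df$resno, resname), NA)
  ligand_id <- match(lig_key, unique(stats::na.omit(lig_key)))
  tibble(
    atom_index = seq_len(nrow(atom_df)),
    name = atom_df$elety,
    element = element,
    is_hydrogen = element %in% c("H", "D"),
    residue_index = as.integer(atom_df$resno),
    residue_name = resname,
    chain = chain,
    entity = entity,
    ligand_id = as.integer(ligand_id)
  )
}

#' Read a molecular system from a PDB file
#'
#' Atoms with standard amino-acid residue codes are tagged `protein`;
#' water and simple counter-ions are tagged `other`; all remaining
#' HETATM/ATOM records are tagged `ligand` and grouped into molecules by
#' (chain, residue number). Hydrogens are flagged from the element column
#' when present, else from the atom name.
#'
#' @param path Path to a PDB file. Only the first MODEL is used for the
#'   topology; see [read_trajectory_pdb()] for multi-model coordinates.
#'
#' @return A list with elements `system` (a [mol_system()]) and `coords`
#'   (an `n_atoms` x 3 matrix of the first model's coordinates, Angstrom).
#' @export
#' @examples
#' demo <- tempfile(fileext = ".pdb")
#' toy <- make_toy_system(sequence = c("ALA", "ASP"), n_ligands = 1)
#' write_system_pdb(toy$system, toy$coords, demo)
#' read_structure(demo)$system
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("unreadable PDB file ", path, ": ", conditionMessage(e)))
  )
  atoms <- bio3d_to_atoms(pdb$atom)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (!all(is.finite(xyz))) abort("unparseable coordinates in PDB")
  list(system = mol_system(atoms), coords = xyz)
}

#' Read trajectory frames from a multi-model PDB
#'
#' Each MODEL/ENDMDL block becomes one frame. Frame times are assigned as
#' `t0_ns + (frame - 1) * dt_ns` because the PDB format carries no time
#' field. DCD trajectories are accepted through [read_trajectory_dcd()];
#' XTC is not supported.
#'
#' @param path Multi-model PDB path.
#' @param dt_ns Frame spacing in nanoseconds (default 1).
#' @param t0_ns Time of the first frame (default 0).
#'
#' @return A list with elements `system` and `traj`
#'   (a [trajectory_frames()]).
#' @export
read_trajectory_pdb <- function(path, dt_ns = 1, t0_ns = 0) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("unreadable PDB file ", path, ": ", conditionMessage(e)))
  )
  atoms <- bio3d_to_atoms(pdb$atom)
  n_atoms <- nrow(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  times <- t0_ns + (seq_len(n_frames) - 1) * dt_ns
  list(system = mol_system(atoms), traj = trajectory_frames(coords, times))
}

#' Read trajectory frames from a DCD file
#'
#' Adapter over [bio3d::read.dcd()]; the topology must be supplied
#' separately as a PDB via [read_structure()].
#'
#' @param path DCD trajectory path.
#' @param system A [mol_system()] giving the atom order.
#' @param dt_ns,t0_ns Frame time assignment as in [read_trajectory_pdb()].
#'
#' @return A [trajectory_frames()].
#' @export
read_trajectory_dcd <- function(path, system, dt_ns = 1, t0_ns = 0) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (ncol(xyz) != 3 * system$n_atoms) {
    abort("DCD atom count does not match the supplied system")
  }
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(system$n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory_frames(coords, t0_ns + (seq_len(n_frames) - 1) * dt_ns)
}

#' Write a system + coordinates as a (possibly multi-model) PDB
#'
#' Emits plain ATOM/HETATM records that round-trip through
#' [read_structure()] / [read_trajectory_pdb()].
#'
#' @param system A [mol_system()].
#' @param coords Either an `n_atoms` x 3 matrix (single model) or a
#'   [trajectory_frames()] (one MODEL per frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_pdb <- function(system, coords, path) {
  atoms <- system$atoms
  fmt_model <- function(xyz) {
    rec <- ifelse(atoms$entity == "protein", "ATOM  ", "HETATM")
    sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, atoms$atom_index,
      ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
      " ", atoms$residue_name, atoms$chain, atoms$residue_index, " ",
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element
    )
  }
  lines <- character(0)
  if (inherits(coords, "trajectory_frames")) {
    for (f in seq_len(coords$n_frames)) {
      lines <- c(lines, sprintf("MODEL     %4d", f),
                 fmt_model(coords$coords[, , f]), "ENDMDL")
    }
  } else {
    lines <- fmt_model(coords)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
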