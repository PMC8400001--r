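#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' a mobile and a reference point set (SVD solution with determinant
#' correction, so reflections are never returned).
#'
#' @param mobile,reference `n` x 3 coordinate matrices, `n >= 3`, in the
#'   same atom order.
#'
#' @return A list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), `rmsd` (Angstrom if inputs are Angstrom), and `fitted`
#'   (the transformed mobile coordinates). The transform maps mobile `x`
#'   to `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) abort("coordinate sets differ in size")
  if (ncol(mobile) != 3) abort("coordinates must be n x 3")
  n <- nrow(mobile)
  if (n < 3) abort("at least 3 points are required for superposition")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- crossprod(a, b)           # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  s <- diag(c(1, 1, d))
  rot <- sv$v %*% s %*% t(sv$u)  # maps centred mobile onto centred reference
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  fitted <- sweep(fitted, 2, cr, "+")
  list(
    rotation = rot,
    translation = as.numeric(cr - rot %*% cm),
    rmsd = rmsd,
    fitted = fitted
  )
}

#' Default serum-albumin domain boundaries
#'
#' The canonical three-domain decomposition of serum albumin by residue
#' index: I = 1-183, II = 184-376, III = 377-583. Adjust or replace to
#' analyse other proteins or conventions.
#'
#' @return A tibble with columns `domain`, `start`, `end` (1-based,
#'   inclusive).
#' @export
albumin_domains <- function() {
  tibble(
    domain = c("domain_I", "domain_II", "domain_III"),
    start = c(1L, 184L, 377L),
    end = c(183L, 376L, 583L)
  )
}

backbone_atom_names <- c("N", "CA", "C")

select_backbone <- function(system, domain = NULL) {
  atoms <- system$atoms
  keep <- atoms$entity == "protein" & atoms$name %in% backbone_atom_names
  if (!is.null(domain)) {
    keep <- keep & atoms$residue_index >= domain$start & atoms$residue_index <= domain$end
  }
  atoms$atom_index[keep]
}

#' Per-frame backbone RMSD versus a reference
#'
#' For every frame, the selected atoms (backbone N, CA, C by default,
#' optionally restricted to residue-range domains) are least-squares
#' superposed onto the same selection in the reference, and the RMSD of
#' that selection after the fit is reported in nanometers. Fitting and
#' measurement use the same selection, matching the behaviour of
#' standard trajectory-analysis tools when fit and output groups
#' coincide.
#'
#' @param system A [mol_system()].
#' @param traj A [trajectory_frames()].
#' @param reference `n_atoms` x 3 reference coordinates (Angstrom),
#'   typically the crystal structure.
#' @param domains Optional tibble of residue ranges (`domain`, `start`,
#'   `end`), e.g. [albumin_domains()]; when supplied, one series per
#'   domain is returned in addition to nothing else (use
#'   `domains = NULL` for the whole backbone).
#' @param selection_label Label for the whole-selection series.
#'
#' @return A tibble with columns `frame`, `time_ns`, `selection`,
#'   `rmsd_nm`.
#' @export
#' @examples
#' toy <- make_toy_system(n_residues = 5)
#' traj <- perturb_frames(toy$coords, n_frames = 3, sigma = 0.1, seed = 1)
#' rmsd_series(toy$system, traj, toy$coords)
rmsd_series <- function(system, traj, reference, domains = NULL,
                        selection_label = "backbone") {
  reference <- as.matrix(reference)
  if (nrow(reference) != system$n_atoms) {
    abort("reference coordinates do not match the system atom count")
  }
  if (traj$n_atoms != system$n_atoms) {
    abort("trajectory atom count does not match the system")
  }
  sel_list <- list()
  if (is.null(domains)) {
    sel_list[[selection_label]] <- select_backbone(system)
  } else {
    for (i in seq_len(nrow(domains))) {
      sel_list[[domains$domain[i]]] <- select_backbone(system, domains[i, ])
    }
  }
  out <- purrr::imap(sel_list, function(sel, label) {
    if (length(sel) == 0) abort(paste0("empty atom selection: ", label))
    ref_sel <- reference[sel, , drop = FALSE]
    rmsd_a <- vapply(seq_len(traj$n_frames), function(f) {
      kabsch_superpose(traj$coords[sel, , f], ref_sel)$rmsd
    }, numeric(1))
    tibble(
      frame = seq_len(traj$n_frames),
      time_ns = traj$times_ns,
      selection = label,
      rmsd_nm = rmsd_a / 10  # Angstrom -> nm
    )
  })
  bind_rows(out)
}
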