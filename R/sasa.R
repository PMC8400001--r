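#' Bondi-type van der Waals radii (Angstrom)
#'
#' Radii used for solvent-accessible surface area; elements not listed
#' fall back to carbon (1.70 A).
#'
#' @return Named numeric vector of radii by element symbol.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)
}

# Theoretical maximum accessible surface areas (A^2) of residue X in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column),
# used to normalize per-residue SASA into relative accessibility.
MAX_ASA_GXG <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

# deterministic quasi-uniform points on the unit sphere (golden-spiral
# construction; same point set for every atom, as in the classic
# numerical SASA algorithm)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom is inflated by the probe radius and covered
#' with a fixed quasi-uniform point set; points falling inside any
#' neighbouring inflated sphere are occluded, and the accessible
#' fraction scales the sphere area `4*pi*(r+p)^2`.
#'
#' @param coords `n` x 3 coordinate matrix (Angstrom).
#' @param elements Character vector of element symbols (length `n`).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4,
#'   a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Named radius lookup; see [vdw_radii()].
#'
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @export
atom_sasa <- function(coords, elements, probe_radius = 1.4, n_points = 960,
                      radii = vdw_radii()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  r <- unname(radii[toupper(elements)])
  r[is.na(r)] <- radii[["C"]]
  rp <- r + probe_radius
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # pairwise squared distances once, to find each atom's neighbours
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rp[i] + rp)^2 & seq_len(n) != i)
    p_i <- sweep(pts * rp[i], 2, coords[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(occluded)) break
        dj <- p_i[!occluded, , drop = FALSE]
        dj <- (dj[, 1] - coords[j, 1])^2 + (dj[, 2] - coords[j, 2])^2 +
          (dj[, 3] - coords[j, 3])^2
        hit <- dj < rp[j]^2
        occluded[!occluded][hit] <- TRUE
      }
      acc <- sum(!occluded)
    }
    out[i] <- 4 * pi * rp[i]^2 * acc / n_points
  }
  out
}

#' Per-residue SASA and relative accessibility
#'
#' Sums atomic SASA over each protein residue and divides by the
#' residue's theoretical maximum accessibility (extended Gly-X-Gly
#' reference) to obtain relative SASA.
#'
#' @param system A [mol_system()].
#' @param coords `n_atoms` x 3 coordinates for one frame (Angstrom).
#' @inheritParams atom_sasa
#' @return A tibble with `residue_index`, `residue_name`, `chain`,
#'   `sasa_a2`, `relative_sasa`.
#' @export
residue_sasa <- function(system, coords, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii()) {
  atoms <- system$atoms
  if (nrow(coords) != system$n_atoms) abort("coords do not match system atom count")
  prot <- atoms$entity == "protein"
  if (!any(prot)) abort("no protein residues in system")
  sasa <- atom_sasa(coords[prot, , drop = FALSE], atoms$element[prot],
                    probe_radius = probe_radius, n_points = n_points,
                    radii = radii)
  tibble(
    residue_index = atoms$residue_index[prot],
    residue_name = atoms$residue_name[prot],
    chain = atoms$chain[prot],
    sasa_a2 = sasa
  ) |>
    group_by(.data$chain, .data$residue_index, .data$residue_name) |>
    summarise(sasa_a2 = sum(.data$sasa_a2), .groups = "drop") |>
    mutate(
      relative_sasa = .data$sasa_a2 /
        unname(MAX_ASA_GXG[.data$residue_name])
    ) |>
    select("residue_index", "residue_name", "chain", "sasa_a2", "relative_sasa")
}

#' Residue-class composition of the protein surface
#'
#' Marks residues whose relative SASA meets a threshold as surface
#' residues and returns the normalized five-class fraction profile of
#' that surface set — the quantity used to compare the surfaces of two
#' proteins (e.g. serum albumin vs catalase) for transferability of
#' ion-pairing behaviour.
#'
#' @inheritParams residue_sasa
#' @param relative_threshold Relative-SASA cutoff for calling a residue
#'   "surface" (default 0.20).
#' @param groups Residue-class mapping; see [residue_group_table()].
#' @return A tibble as from [group_fraction_profile()] (`group`, `n`,
#'   `fraction`; attributes `n_selected`, `threshold_percent`), plus
#'   attribute `residue_sasa` carrying the per-residue table.
#' @export
surface_composition <- function(system, coords, probe_radius = 1.4,
                                relative_threshold = 0.20, n_points = 960,
                                groups = residue_group_table()) {
  rs <- residue_sasa(system, coords, probe_radius = probe_radius,
                     n_points = n_points)
  surf <- filter(rs, .data$relative_sasa >= relative_threshold)
  lev <- residue_group_levels()
  counts <- table(factor(classify_residue(surf$residue_name, groups), levels = lev))
  n_sel <- nrow(surf)
  out <- tibble(
    group = lev,
    n = as.integer(counts),
    fraction = if (n_sel > 0) as.numeric(counts) / n_sel else rep(0, length(lev))
  )
  attr(out, "n_selected") <- n_sel
  attr(out, "threshold_percent") <- 100 * relative_threshold
  attr(out, "residue_sasa") <- rs
  out
}
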