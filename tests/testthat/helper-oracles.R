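# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's vectorized code paths: plain
# loops and direct formulas only.

# Brute-force occupancy recount: all atom pairs, all frames, sqrt
# distances, no linear-algebra shortcuts.
brute_force_occupancy <- function(system, traj, cutoff = 4, heavy_only = TRUE) {
  atoms <- system$atoms
  prot <- atoms[atoms$entity == "protein", ]
  lig <- atoms[atoms$entity == "ligand", ]
  if (heavy_only) {
    prot <- prot[!prot$is_hydrogen, ]
    lig <- lig[!lig$is_hydrogen, ]
  }
  res_ids <- unique(prot$residue_index)
  counts <- stats::setNames(integer(length(res_ids)), res_ids)
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    for (ri in seq_along(res_ids)) {
      r_atoms <- prot$atom_index[prot$residue_index == res_ids[ri]]
      hit <- FALSE
      for (pa in r_atoms) {
        for (la in lig$atom_index) {
          d <- sqrt(sum((xyz[pa, ] - xyz[la, ])^2))
          if (d <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      counts[ri] <- counts[ri] + hit
    }
  }
  counts
}

# Exact two-tailed Mann-Whitney p by full enumeration of group
# assignments, mirroring the standard two-sided exact definition
# p = min(1, 2 * min(P(W <= w), P(W >= w))).
enum_mw <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  u_of <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yi in ys) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  w_obs <- u_of(x, y)
  w_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  list(u = min(w_obs, nx * ny - w_obs), p = p)
}

# Welch t and Satterthwaite df by direct formula.
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Random toy system + random-ligand trajectory for recount sweeps:
# ligand atoms bounce uniformly around the protein so contacts occur by
# chance at a workable rate.
random_contact_case <- function(seed) {
  withr::with_seed(seed, {
    n_res <- sample(3:10, 1)
    seqs <- sample(residue_group_table()$residue_name, n_res, replace = TRUE)
    n_lig <- sample(1:3, 1)
    toy <- make_toy_system(sequence = seqs, n_ligands = n_lig)
    n_frames <- sample(3:20, 1)
    n_atoms <- toy$system$n_atoms
    coords <- array(NA_real_, c(n_atoms, 3, n_frames))
    lig_rows <- toy$system$atoms$atom_index[toy$system$atoms$entity == "ligand"]
    span <- range(toy$coords[, 1])
    for (f in seq_len(n_frames)) {
      xyz <- toy$coords
      xyz[lig_rows, ] <- cbind(
        stats::runif(n_lig, span[1] - 6, span[2] + 6),
        stats::runif(n_lig, -8, 8),
        stats::runif(n_lig, -8, 8)
      )
      coords[, , f] <- xyz
    }
    list(system = toy$system,
         traj = trajectory_frames(coords, seq_len(n_frames) - 1))
  })
}

# Minimal hand-authored PDB fixtures.
write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

ala_ligand_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.800   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.200   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.400   0.800   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       3.400   0.200   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.200  -1.500   0.000  1.00  0.00           C",
  "HETATM    6  S1  SDS B   1      10.000   0.000   0.000  1.00  0.00           S",
  "END"
)
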