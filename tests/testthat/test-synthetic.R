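test_that("toy systems have the promised geometry and classes", {
  one <- make_toy_system(n_residues = 1, n_ligands = 0)
  expect_equal(one$system$n_atoms, 4)  # N, CA, C, CB

  toy <- make_toy_system(sequence = c("ALA", "ASP", "PHE"), n_ligands = 2)
  occ_groups <- classify_residue(c("ALA", "ASP", "PHE"))
  expect_equal(occ_groups, c("hydrophobic", "negative", "aromatic"))
  ca <- toy$coords[toy$system$atoms$name == "CA", ]
  expect_equal(diff(ca[, 1]), rep(3.8, 2))
  # ligands parked at least 20 A from every protein atom
  prot_rows <- toy$system$atoms$entity == "protein"
  for (lr in which(toy$system$atoms$entity == "ligand")) {
    d <- sqrt(rowSums(sweep(toy$coords[prot_rows, , drop = FALSE], 2,
                            toy$coords[lr, ])^2))
    expect_gt(min(d), 20)
  }
  expect_error(make_toy_system(sequence = "ZZZ"), "unknown residue")
})

test_that("planted occupancies are recovered exactly, with determinism", {
  toy <- make_toy_system(sequence = rep("ALA", 5), n_ligands = 5)
  targets <- c(100, 80, 30, 10, 0)
  pl1 <- plant_contact_trajectory(toy$system, toy$coords, targets,
                                  n_frames = 10, seed = 9)
  expect_equal(pl1$planted_counts$planted_frames, c(10L, 8L, 3L, 1L, 0L))
  occ <- compute_occupancy(toy$system, pl1$traj)
  expect_equal(occ$contact_frames, pl1$planted_counts$planted_frames)

  pl2 <- plant_contact_trajectory(toy$system, toy$coords, targets,
                                  n_frames = 10, seed = 9)
  expect_identical(pl1$traj$coords, pl2$traj$coords)
  pl3 <- plant_contact_trajectory(toy$system, toy$coords, targets,
                                  n_frames = 10, seed = 10)
  expect_false(identical(pl1$traj$coords, pl3$traj$coords))
  occ3 <- compute_occupancy(toy$system, pl3$traj)
  expect_equal(occ3$contact_frames, pl1$planted_counts$planted_frames)
})

test_that("planted recovery holds across cutoff / plant-distance pairs", {
  toy <- make_toy_system(sequence = rep("GLY", 4), n_ligands = 4)
  # plant distances chosen so a planted ligand cannot also graze the
  # neighbouring residue's backbone (the generator refuses such plans)
  for (case in list(c(3.0, 4.0), c(3.5, 4.0), c(4.5, 5.0), c(5.5, 6.0))) {
    pl <- plant_contact_trajectory(toy$system, toy$coords, c(50, 25, 75, 0),
                                   n_frames = 8, plant_distance = case[1],
                                   cutoff = case[2], seed = 17)
    occ <- compute_occupancy(toy$system, pl$traj,
                             contact_parameters(cutoff = case[2]))
    expect_equal(occ$contact_frames, pl$planted_counts$planted_frames,
                 info = paste(case, collapse = "/"))
  }
})

test_that("infeasible planting plans are rejected", {
  toy <- make_toy_system(sequence = rep("ALA", 3), n_ligands = 1)
  expect_error(
    plant_contact_trajectory(toy$system, toy$coords, c(100, 100, 0),
                             n_frames = 5, seed = 1),
    "infeasible simultaneous plants"
  )
  expect_error(
    plant_contact_trajectory(toy$system, toy$coords, c(10, 0, 0),
                             n_frames = 5, plant_distance = 4.5, seed = 1),
    "below the cutoff"
  )
  # plants too close spill onto neighbouring residues and are refused
  expect_error(
    plant_contact_trajectory(toy$system, toy$coords, c(0, 50, 0),
                             n_frames = 4, plant_distance = 1.0, seed = 1),
    "infeasible planting geometry"
  )
})

test_that("perturb_frames is seed-deterministic and noise-calibrated", {
  toy <- make_toy_system(n_residues = 4)
  t1 <- perturb_frames(toy$coords, 3, sigma = 0.2, seed = 5)
  t2 <- perturb_frames(toy$coords, 3, sigma = 0.2, seed = 5)
  expect_identical(t1$coords, t2$coords)
  t3 <- perturb_frames(toy$coords, 3, sigma = 0.2, seed = 6)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("kinetic traces match the first-order closed form", {
  gen <- gen_kinetic_trace(a0 = 0.50, k = 0.002, sigma = 0)
  expect_equal(gen$t_upper_s, log(0.50 / 0.45) / 0.002)
  expect_equal(gen$delta_t_min, log(0.45 / 0.40) / 0.002 / 60)
  act <- catalase_activity(gen$trace)
  expect_equal(act$au_per_ml, 3.45 / (gen$delta_t_min * 0.1), tolerance = 1e-3)

  # doubling k halves delta-t and doubles activity
  gen2 <- gen_kinetic_trace(a0 = 0.50, k = 0.004, sigma = 0)
  expect_equal(gen2$delta_t_min, gen$delta_t_min / 2)
  act2 <- catalase_activity(gen2$trace)
  expect_equal(act2$au_per_ml, 2 * act$au_per_ml, tolerance = 2e-3)

  n1 <- gen_kinetic_trace(a0 = 0.50, k = 0.002, sigma = 0.002, seed = 3)
  n2 <- gen_kinetic_trace(a0 = 0.50, k = 0.002, sigma = 0.002, seed = 3)
  expect_identical(n1$trace$a240, n2$trace$a240)

  expect_error(gen_kinetic_trace(a0 = 0.35), "lower level")
  expect_warning(gen_kinetic_trace(a0 = 0.44), "upper level")
})

test_that("noise-free activity stays within 0.1% of closed form across rates", {
  for (k in c(5e-4, 2e-3, 1e-2, 5e-2)) {
    gen <- gen_kinetic_trace(a0 = 0.50, k = k, duration_s = max(180, 500 / k * 1e-3 * 600))
    act <- catalase_activity(gen$trace)
    analytic <- 3.45 / (gen$delta_t_min * 0.1)
    expect_lt(abs(act$au_per_ml - analytic) / analytic, 1e-3)
  }
})

test_that("plate generator encodes a recoverable known line", {
  plate <- gen_plate_readings(slope = 0.04, intercept = 0.08,
                              unknown_concs = c(12, 30),
                              unknown_dilutions = c(1, 2), sigma = 0)
  curve <- bca_fit(plate[plate$role == "standard", ])
  unk <- plate[plate$role == "unknown", ]
  quant <- bca_quantify(curve, unk$absorbance, unk$dilution_factor)
  expect_equal(quant$conc_ug_ml, attr(plate, "truth")$true_conc_ug_ml,
               tolerance = 1e-9)
})

test_that("generated cohorts satisfy the record invariants across a seed sweep", {
  for (seed in 1:100) {
    co <- gen_cohort(groups = tibble::tibble(group = c("x", "y"),
                                             n_male = 3L, n_female = 2L,
                                             shift = c(0, 5)),
                     seed = seed)$cohort
    expect_true(all(co$ipsi_area > 0 | co$ipsi_area == 0))
    expect_true(all(co$contra_area > 0))
    expect_true(all(co$gross_score %in% 0:4))
    expect_true(all(co$sex %in% c("male", "female")))
    expect_equal(nrow(co), 10)
  }
  c1 <- gen_cohort(seed = 77)$cohort
  c2 <- gen_cohort(seed = 77)$cohort
  expect_identical(c1, c2)
})

test_that("cohort areas reproduce the latent lesion percent through area_loss", {
  co <- gen_cohort(seed = 12)
  loss <- suppressWarnings(area_loss(co$cohort$ipsi_area, co$cohort$contra_area))
  expect_equal(co$cohort$gross_score, lesion_to_score(loss))
})
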