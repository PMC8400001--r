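linear_trace <- function(a0 = 0.50, slope = 0.001, interval = 2, duration = 180) {
  t <- seq(0, duration, by = interval)
  tibble::tibble(time_s = t, a240 = a0 - slope * t)
}

test_that("crossing_time interpolates the first downward crossing", {
  tr <- tibble::tibble(time_s = c(48, 50, 52), a240 = c(0.46, 0.45, 0.44))
  expect_equal(crossing_time(tr, 0.45), 50)

  # A(t) = 0.50 - 0.001 t sampled every 2 s: closed-form crossings
  tr2 <- linear_trace()
  expect_equal(crossing_time(tr2, 0.45), 50)
  expect_equal(crossing_time(tr2, 0.40), 100)

  rising <- tibble::tibble(time_s = c(0, 2, 4), a240 = c(0.5, 0.6, 0.7))
  expect_error(crossing_time(rising, 0.45), "not crossed")
})

test_that("catalase activity follows the crossing-time formula", {
  # delta-t exactly 1 min at dilution 1 forces 3.45 / (1 * 0.1)
  tr <- tibble::tibble(time_s = c(0, 30, 90, 120),
                       a240 = c(0.50, 0.45, 0.40, 0.38))
  res <- catalase_activity(tr)
  expect_equal(res$delta_t_min, 1)
  expect_equal(res$au_per_ml, 34.5)
  expect_equal(res$warnings, "")

  # linear trace: crossings at 50 s and 100 s, so 41.4 AU/mL
  res2 <- catalase_activity(linear_trace())
  expect_equal(res2$t_cross_045_s, 50)
  expect_equal(res2$t_cross_040_s, 100)
  expect_equal(res2$au_per_ml, 41.4)

  # first-order trace at dilution 10: within 0.1% of the closed form
  gen <- gen_kinetic_trace(a0 = 0.50, k = 0.002)
  res3 <- catalase_activity(gen$trace, dilution_factor = 10)
  analytic <- 3.45 * 10 / (gen$delta_t_min * 0.1)
  expect_equal(res3$au_per_ml, analytic, tolerance = 1e-3)
})

test_that("activity scales linearly with dilution and inversely with delta-t", {
  # both traces hit the levels exactly on 2 s samples, so delta-t doubles exactly
  a1 <- catalase_activity(linear_trace(slope = 0.001))$au_per_ml
  a_half <- catalase_activity(linear_trace(slope = 0.0005, duration = 400))$au_per_ml
  expect_equal(a1, 2 * a_half, tolerance = 1e-12)
  d1 <- catalase_activity(linear_trace(), dilution_factor = 1)$au_per_ml
  d5 <- catalase_activity(linear_trace(), dilution_factor = 5)$au_per_ml
  expect_equal(d5, 5 * d1, tolerance = 1e-12)
})

test_that("out-of-window starts are flagged, short traces rejected", {
  low_start <- linear_trace(a0 = 0.47)
  res <- catalase_activity(low_start)
  expect_match(res$warnings, "outside substrate window")
  never <- linear_trace(duration = 40)  # never reaches 0.40
  expect_error(catalase_activity(never), "not crossed")
})

test_that("BCA quantification inverts an exact line and applies dilution", {
  standards <- tibble::tibble(known_conc_ug_ml = c(0, 10, 20),
                              absorbance = c(0.1, 0.6, 1.1))
  curve <- bca_fit(standards)
  expect_equal(curve$slope, 0.05, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.1, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)

  expect_equal(bca_quantify(curve, 0.6)$conc_ug_ml, 10)
  expect_equal(bca_quantify(curve, 0.1)$conc_ug_ml, 0)
  # the hydrolysis release protocol is a fixed 2x dilution
  expect_equal(
    bca_quantify(curve, 0.6, hydrolysis_dilution_factor())$conc_ug_ml, 20
  )
  expect_warning(bca_quantify(curve, 2.0), "outside the calibrated range")
  expect_error(bca_fit(standards[1, ]), "at least 2")
})

test_that("bca_curve tidiers report the fitted line", {
  curve <- bca_fit(tibble::tibble(known_conc_ug_ml = c(0, 5, 10, 20),
                                  absorbance = c(0.11, 0.34, 0.62, 1.08)))
  td <- generics::tidy(curve)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], curve$slope)
  gl <- generics::glance(curve)
  expect_equal(gl$n, 4)
  expect_gt(gl$r_squared, 0.99)
})

test_that("binding efficiency is the supernatant depletion percentage", {
  expect_equal(binding_efficiency(10, 10), 0)
  expect_equal(binding_efficiency(10, 0), 100)
  expect_equal(binding_efficiency(10, 5.8), 42)
  expect_true(all(diff(binding_efficiency(10, c(1, 4, 9))) < 0))
  expect_warning(binding_efficiency(10, 12), "negative binding efficiency")
  expect_error(binding_efficiency(0, 1), "positive")
})

test_that("specific activity and deactivation reproduce the published loadings", {
  # emulsion: 393 AU/mL over 298 ug/mL -> 1320 AU/mg at 3 significant figures
  emulsion <- specific_activity(393, 298)
  expect_equal(signif(emulsion, 3), 1320)
  # nanoprecipitation: 383 AU/mL over 76 ug/mL -> 5000 AU/mg at 2 significant figures
  nanoprec <- specific_activity(383, 76)
  expect_equal(signif(nanoprec, 2), 5000)
  expect_equal(specific_activity(1, 1000), 1)

  # round-trip identity
  expect_equal(specific_activity(383, 76) * 76 / 1000, 383, tolerance = 1e-12)

  expect_equal(percent_deactivation(100, 100), 0)
  expect_equal(percent_deactivation(100, 0), 100)
  expect_equal(round(percent_deactivation(nanoprec, emulsion)), 74)
})

test_that("protection retention normalizes to the 0 h activity", {
  course <- tibble::tibble(time_h = c(0, 1, 4, 24),
                           au_per_ml = c(400, 300, 200, 80))
  out <- protection_course(course)
  expect_equal(out$retention_percent, c(100, 75, 50, 20))
  # invariant to uniform rescaling
  out2 <- protection_course(dplyr::mutate(course, au_per_ml = au_per_ml * 3.7))
  expect_equal(out2$retention_percent, out$retention_percent)
  flat <- protection_course(tibble::tibble(time_h = 0:2, au_per_ml = 5))
  expect_equal(flat$retention_percent, rep(100, 3))
  expect_error(protection_course(tibble::tibble(time_h = 1:2, au_per_ml = 1:2)),
               "no 0 h")
})

test_that("ion-group inventory reproduces the pairing stoichiometries", {
  agents <- ion_pairing_agents()
  ds <- ion_group_inventory("DS", agents$groups_per_molecule[agents$agent == "DS"], 5,
                            protein_net_charge = 120)
  expect_equal(ds$total_anionic_groups, 120)
  expect_equal(ds$charge_ratio, 1)
  sds <- ion_group_inventory("SDS", 1, 128)
  expect_equal(sds$total_anionic_groups, 128)
  expect_error(ion_group_inventory("TA", 1, 0), "positive")
  expect_error(ion_group_inventory("DS", 0, 5), "positive integer")
})
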