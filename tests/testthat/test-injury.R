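test_that("area loss is the normalized ipsilateral deficit", {
  expect_equal(area_loss(50, 50), 0)
  expect_equal(area_loss(0, 50), 100)
  expect_equal(area_loss(43.5, 50), 13)
  # scale invariance and antitonicity
  expect_equal(area_loss(43.5 * 3, 50 * 3), 13)
  expect_true(all(diff(area_loss(c(10, 20, 30), 50)) < 0))
  expect_warning(area_loss(60, 50), "negative area loss")
  expect_error(area_loss(10, 0), "positive")
})

test_that("lesion percent maps onto the 0-4 ordinal scale", {
  probes <- c(0, 10, 25, 50, 75, 100)
  expect_equal(lesion_to_score(probes), c(0L, 1L, 2L, 2L, 4L, 4L))
  expect_equal(lesion_to_score(30), 2L)
  expect_equal(lesion_to_score(80), 4L)
  # monotone, total over [0, 100]
  grid <- seq(0, 100, by = 0.25)
  scores <- lesion_to_score(grid)
  expect_true(all(diff(scores) >= 0))
  expect_true(all(scores %in% 0:4))
  expect_error(lesion_to_score(101), "lesion percent")
  expect_error(lesion_to_score(-1), "lesion percent")
})

test_that("median_iqr uses linear interpolation of order statistics", {
  expect_equal(median_iqr(5), tibble::tibble(n = 1L, median = 5, q25 = 5, q75 = 5))
  s <- median_iqr(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q25, 1.75)
  expect_equal(s$q75, 3.25)
  # order invariance
  withr::with_seed(4, {
    x <- stats::rnorm(11)
    expect_equal(median_iqr(sample(x)), median_iqr(x))
  })
})

test_that("Mann-Whitney matches the exact enumeration oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  expect_equal(mann_whitney_u(1, 1)$p_value, 1)

  # sweep all shapes with combined n <= 10 on seeded tie-free data
  withr::with_seed(31, {
    for (na in 2:5) for (nb in 2:(10 - na)) {
      x <- stats::rnorm(na); y <- stats::rnorm(nb, mean = 0.5)
      ours <- mann_whitney_u(x, y)
      oracle <- enum_mw(x, y)
      expect_equal(ours$statistic, oracle$u, info = paste(na, nb))
      expect_equal(ours$p_value, oracle$p, tolerance = 1e-12,
                   info = paste(na, nb))
      expect_equal(ours$method, "exact")
    }
  })
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  withr::with_seed(32, {
    x <- stats::rlnorm(8); y <- stats::rlnorm(8, meanlog = 0.4)
    base <- mann_whitney_u(x, y)
    logged <- mann_whitney_u(log(x), log(y))
    cubed <- mann_whitney_u(x^3, y^3)
    expect_equal(logged$p_value, base$p_value)
    expect_equal(cubed$p_value, base$p_value)
  })
})

test_that("large or tied samples switch to the corrected normal approximation", {
  withr::with_seed(33, {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    expect_equal(mann_whitney_u(x, y)$method, "approximate")
    tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4))
    expect_equal(tied$method, "approximate")
    expect_true(tied$p_value >= 0 && tied$p_value <= 1)
  })
})

test_that("Welch t matches the hand formulas and the pooled t when variances match", {
  res <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res$statistic, -1.095, tolerance = 1e-3)
  expect_equal(res$df, 6.0)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  withr::with_seed(34, {
    x <- stats::rnorm(10); y <- stats::rnorm(10, 1)
    ours <- welch_t(x, y)
    oracle <- welch_oracle(x, y)
    expect_equal(ours$statistic, oracle$t, tolerance = 1e-12)
    expect_equal(ours$df, oracle$df, tolerance = 1e-12)
    expect_equal(ours$p_value, oracle$p, tolerance = 1e-12)
    # scale invariance
    expect_equal(welch_t(2 * x, 2 * y)$statistic, ours$statistic, tolerance = 1e-12)
    # equal-n equal-variance agreement with the pooled statistic
    pooled <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(pooled$statistic), tolerance = 1e-12)
  })
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("cohort summaries reproduce group x sex bookkeeping", {
  co <- gen_cohort(seed = 60)$cohort
  s <- cohort_summary(co)
  expect_equal(s$totals$n, 58)
  expect_equal(s$totals$males, 30)
  expect_equal(s$totals$females, 28)
  expect_equal(sum(s$counts$total), 58)
  expect_true(all(s$area_loss$q25 <= s$area_loss$median))
  expect_true(all(s$area_loss$median <= s$area_loss$q75))
  expect_true(!is.null(s$gross_score))

  single <- co[1, ]
  s1 <- cohort_summary(single)
  expect_equal(s1$totals$n, 1)
  expect_equal(s1$area_loss$median, area_loss(single$ipsi_area, single$contra_area))

  expect_error(cohort_summary(co[0, ]), "empty cohort")
  expect_error(cohort_summary(co, declared_groups = "saline"), "undeclared group")
})

test_that("both tests control type-I error on null cohorts", {
  n_rep <- 2000
  groups <- tibble::tibble(group = c("a", "b"), n_male = 10L, n_female = 10L,
                           shift = 0)
  rej_mw <- logical(n_rep); rej_t <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- gen_cohort(groups = groups, seed = 100000 + r)$cohort
    loss <- suppressWarnings(area_loss(co$ipsi_area, co$contra_area))
    a <- loss[co$group == "a"]; b <- loss[co$group == "b"]
    rej_mw[r] <- mann_whitney_u(a, b)$p_value < 0.05
    rej_t[r] <- welch_t(a, b)$p_value < 0.05
  }
  expect_lte(mean(rej_mw), 0.06)
  expect_lte(mean(rej_t), 0.06)
})

test_that("planted group shifts are detected more often than null ones", {
  n_rep <- 200
  groups <- tibble::tibble(group = c("control", "treated"),
                           n_male = 10L, n_female = 10L, shift = c(0, 15))
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- gen_cohort(groups = groups, seed = 200000 + r)$cohort
    loss <- suppressWarnings(area_loss(co$ipsi_area, co$contra_area))
    rej[r] <- mann_whitney_u(loss[co$group == "treated"],
                             loss[co$group == "control"])$p_value < 0.05
  }
  expect_gt(mean(rej), 0.3)  # far above the nominal 5% null rate
})
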