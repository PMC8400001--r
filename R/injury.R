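#' Percent area loss of the injured hemisphere
#'
#' Healthy-tissue area in the hemisphere ipsilateral to the insult,
#' normalized to the contralateral hemisphere:
#' `(1 - ipsilateral / contralateral) * 100`. A larger ipsilateral area
#' (negative loss, e.g. oedema or tracing noise) is returned as-is with
#' a warning.
#'
#' @param ipsilateral Healthy-tissue area of the ipsilateral hemisphere
#'   (>= 0, any consistent unit).
#' @param contralateral Contralateral hemisphere area (> 0, same unit).
#' @return Percent area loss (vectorized).
#' @export
area_loss <- function(ipsilateral, contralateral) {
  if (any(contralateral <= 0)) abort("contralateral area must be positive")
  if (any(ipsilateral < 0)) abort("ipsilateral area must be non-negative")
  loss <- (1 - ipsilateral / contralateral) * 100
  if (any(loss < 0)) {
    warn("negative area loss: ipsilateral area exceeds contralateral")
  }
  loss
}

#' Default gross-injury score scale
#'
#' The five-point ordinal scale binning percent lesion of the
#' ipsilateral hemisphere: 0 = no injury, 1 = mild (< 25% lesion),
#' 2 = 25-50%, 3 = 51-75%, 4 = >= 75%. The printed bin edges leave two
#' ambiguities that are resolved deterministically here: exactly 50%
#' stays in bin 2 (bins taken as closed on the side they name), and
#' exactly 75% scores 4 (the ">= 75" clause wins over "51-75").
#'
#' @param breaks Inner bin edges as percent lesion (default
#'   `c(25, 50, 75)`).
#' @return A list of class `score_scale`.
#' @export
score_scale <- function(breaks = c(25, 50, 75)) {
  if (length(breaks) != 3 || is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be three strictly increasing percent values")
  }
  structure(list(breaks = breaks), class = "score_scale")
}

#' Map percent lesion to the 0-4 ordinal gross-injury score
#'
#' @param lesion_percent Numeric vector of percent lesion values in
#'   `[0, 100]`.
#' @param scale A [score_scale()].
#' @return Integer scores 0-4 (vectorized).
#' @export
#' @examples
#' lesion_to_score(c(0, 10, 25, 50, 75, 100))
lesion_to_score <- function(lesion_percent, scale = score_scale()) {
  if (any(lesion_percent < 0 | lesion_percent > 100)) {
    abort("lesion percent must lie in [0, 100]")
  }
  b <- scale$breaks
  dplyr::case_when(
    lesion_percent == 0 ~ 0L,
    lesion_percent >= b[3] ~ 4L,
    lesion_percent > b[2] ~ 3L,
    lesion_percent >= b[1] ~ 2L,
    TRUE ~ 1L
  )
}

#' Median and interquartile range of a sample
#'
#' Quartiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7, the common default of mainstream
#' statistics software), so summaries are reproducible across tools.
#'
#' @param values Numeric vector (>= 1 value).
#' @return A one-row tibble: `n`, `median`, `q25`, `q75`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(n = length(values), median = q[2], q25 = q[1], q75 = q[3])
}

#' Two-tailed Wilcoxon-Mann-Whitney U test
#'
#' Reports the U statistic as the minimum of the two one-sided U's and a
#' two-tailed p value: exact (full null enumeration) when the combined
#' sample size is at most `exact_max_n` and the pooled data carry no
#' ties, otherwise the normal approximation with tie correction and a
#' 0.5 continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max_n Combined-size limit for the exact branch
#'   (default 16).
#' @return A one-row tibble: `test`, `statistic` (U), `p_value`,
#'   `method` (`"exact"` or `"approximate"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, exact_max_n = 16) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (nx + ny) <= exact_max_n && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided",
    exact = use_exact, correct = TRUE
  ))
  u_x <- unname(wt$statistic)       # one-sided U for x over y
  u <- min(u_x, nx * ny - u_x)
  p <- wt$p.value
  # fully tied micro-samples have zero rank variance; no evidence either way
  if (!is.finite(p)) p <- 1
  tibble(
    test = "mann_whitney_u",
    statistic = u,
    p_value = min(1, p),
    method = if (use_exact) "exact" else "approximate"
  )
}

#' Welch two-sample t test
#'
#' Unpaired t test with Welch-Satterthwaite degrees of freedom (no
#' equal-variance assumption); two-tailed.
#'
#' @param x,y Numeric vectors with at least 2 values each; at least one
#'   group must have nonzero variance.
#' @return A one-row tibble: `test`, `statistic` (t), `df`, `p_value`,
#'   `method`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("both groups need at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    abort("both groups have zero variance")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  tibble(
    test = "welch_t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = "welch"
  )
}

check_cohort <- function(cohort, declared_groups = NULL) {
  cohort <- as_tibble(cohort)
  required <- c("subject_id", "sex", "group", "ipsi_area", "contra_area")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0) abort("empty cohort")
  if (!all(cohort$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  if (!is.null(declared_groups)) {
    extra <- setdiff(unique(cohort$group), declared_groups)
    if (length(extra) > 0) {
      abort(paste0("undeclared group label(s): ", paste(extra, collapse = ", ")))
    }
  }
  if ("gross_score" %in% names(cohort)) {
    sc <- cohort$gross_score[!is.na(cohort$gross_score)]
    if (!all(sc %in% 0:4)) abort("gross_score must be an integer in 0..4")
  }
  if (any(cohort$ipsi_area < 0) || any(cohort$contra_area <= 0)) {
    abort("areas must be positive (ipsilateral may be zero)")
  }
  cohort
}

#' Summarize an injury cohort
#'
#' Counts subjects per treatment group and sex and summarizes area loss
#' and gross scores per group as median with IQR.
#'
#' @param cohort A data frame with columns `subject_id`, `sex`, `group`,
#'   `ipsi_area`, `contra_area` and optionally `gross_score`.
#' @param declared_groups Optional character vector of allowed group
#'   labels; any record outside it is an error.
#' @param by_sex Also return sex-stratified outcome summaries
#'   (default `FALSE`).
#'
#' @return A list of class `cohort_summary`: `counts` (per group x sex),
#'   `totals` (one row: `n`, `males`, `females`), `area_loss` and
#'   `gross_score` (per-group median/IQR tibbles; the latter `NULL` when
#'   scores are absent), and `by_sex` when requested.
#' @export
cohort_summary <- function(cohort, declared_groups = NULL, by_sex = FALSE) {
  cohort <- check_cohort(cohort, declared_groups)
  cohort$area_loss <- suppressWarnings(
    area_loss(cohort$ipsi_area, cohort$contra_area)
  )
  counts <- cohort |>
    dplyr::count(.data$group, .data$sex, name = "n") |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n", values_fill = 0L)
  for (col in c("male", "female")) if (!col %in% names(counts)) counts[[col]] <- 0L
  counts <- counts |>
    mutate(total = .data$male + .data$female) |>
    select("group", "male", "female", "total")
  totals <- tibble(
    n = nrow(cohort),
    males = sum(cohort$sex == "male"),
    females = sum(cohort$sex == "female")
  )
  sum_by <- function(df, var, extra = character(0)) {
    df |>
      group_by(across(dplyr::all_of(c("group", extra)))) |>
      summarise(median_iqr(.data[[var]]), .groups = "drop")
  }
  out <- list(
    counts = counts,
    totals = totals,
    area_loss = sum_by(cohort, "area_loss"),
    gross_score = if ("gross_score" %in% names(cohort) &&
                      any(!is.na(cohort$gross_score))) {
      sum_by(cohort[!is.na(cohort$gross_score), ], "gross_score")
    }
  )
  if (by_sex) {
    out$by_sex <- sum_by(cohort, "area_loss", extra = "sex")
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$totals$n, " subjects (",
      x$totals$males, " male, ", x$totals$females, " female)\n", sep = "")
  print(x$counts)
  cat("area loss (median, IQR):\n"); print(x$area_loss)
  if (!is.null(x$gross_score)) { cat("gross score (median, IQR):\n"); print(x$gross_score) }
  invisible(x)
}

#' @export
glance.cohort_summary <- function(x, ...) x$totals

#' Pairwise outcome comparisons against a control group
#'
#' Runs the two-tailed Wilcoxon-Mann-Whitney U test of each treatment
#' group against the designated control for the chosen outcome
#' (`"area_loss"` computed from the areas, or `"gross_score"`).
#' No multiplicity adjustment is applied; p values are reported as-is.
#'
#' @inheritParams cohort_summary
#' @param control Label of the control group.
#' @param outcome `"area_loss"` or `"gross_score"`.
#' @param exact_max_n Passed to [mann_whitney_u()].
#' @return A tibble with one row per comparison: `outcome`, `group`,
#'   `control`, `n_group`, `n_control`, `statistic`, `p_value`,
#'   `method`.
#' @export
injury_compare <- function(cohort, control, outcome = c("area_loss", "gross_score"),
                           declared_groups = NULL, exact_max_n = 16) {
  outcome <- match.arg(outcome)
  cohort <- check_cohort(cohort, declared_groups)
  if (!control %in% cohort$group) {
    abort(paste0("control group not present in cohort: ", control))
  }
  vals <- if (outcome == "area_loss") {
    suppressWarnings(area_loss(cohort$ipsi_area, cohort$contra_area))
  } else {
    if (!"gross_score" %in% names(cohort)) abort("cohort has no gross_score column")
    cohort$gross_score
  }
  keep <- !is.na(vals)
  vals <- vals[keep]; grp <- cohort$group[keep]
  ctrl_vals <- vals[grp == control]
  others <- setdiff(unique(grp), control)
  purrr::map(others, function(g) {
    gv <- vals[grp == g]
    res <- mann_whitney_u(gv, ctrl_vals, exact_max_n = exact_max_n)
    tibble(
      outcome = outcome, group = g, control = control,
      n_group = length(gv), n_control = length(ctrl_vals),
      statistic = res$statistic, p_value = res$p_value, method = res$method
    )
  }) |>
    bind_rows()
}
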