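#' Pearson correlation with significance
#'
#' Product-moment correlation between two columns of a data frame, with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param data A data frame.
#' @param x,y Columns to correlate (tidy evaluation).
#' @return A tibble with `r`, `p`, `n`.
#' @examples
#' pearson_cor(data.frame(a = 1:5, b = c(2, 1, 4, 3, 6)), a, b)
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) stop_cvo("`x` and `y` must have equal length", "length_mismatch")
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) stop_cvo("Pearson correlation needs at least 3 complete pairs", "too_few")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop_cvo("correlation is undefined: one of the variables has zero variance", "zero_variance")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Intraclass correlation coefficient from ANOVA mean squares
#'
#' Single-measure ICC for a complete subjects-by-raters table in long
#' format, computed from the one- or two-way ANOVA mean squares (fitted with
#' [stats::aov()]).  Supported forms, in the usual Shrout-Fleiss naming:
#'
#' * `"oneway"` — ICC(1,1), one-way random: `(MSB - MSW) / (MSB + (k-1) MSW)`.
#'   The conventional choice for intra-rater (test-retest) agreement.
#' * `"two_way_random_absolute"` — ICC(2,1), two-way random effects,
#'   absolute agreement: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'   The conventional choice for inter-rater agreement.
#' * `"two_way_mixed_consistency"` — ICC(3,1), two-way mixed, consistency:
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' @param data Long data frame: one row per (subject, rater) measurement.
#' @param subject,rater,rating Columns identifying the subject, the rater
#'   (or repeat), and the measured value (tidy evaluation).
#' @param form ICC form (see above).
#' @return A tibble with `icc`, `form`, `n_subjects`, `n_raters`.
#' @export
icc <- function(data, subject, rater, rating,
                form = c("two_way_random_absolute", "two_way_mixed_consistency", "oneway")) {
  form <- match.arg(form)
  subj <- factor(dplyr::pull(data, {{ subject }}))
  rat <- factor(dplyr::pull(data, {{ rater }}))
  val <- dplyr::pull(data, {{ rating }})
  check_finite(val, "rating")
  n <- nlevels(subj)
  k <- nlevels(rat)
  if (k < 2) stop_cvo("ICC needs at least 2 raters/repeats", "too_few")
  tab <- table(subj, rat)
  if (any(tab != 1)) {
    stop_cvo("ICC requires a complete table: every subject measured exactly once by every rater",
             "incomplete_table")
  }
  if (n < 5) {
    warn_cvo(sprintf("ICC on only %d subjects is unstable; 5 or more are recommended", n),
             "few_subjects")
  }
  d <- data.frame(subj = subj, rat = rat, val = val)
  if (form == "oneway") {
    ms <- summary(stats::aov(val ~ subj, data = d))[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    val_icc <- (msb - msw) / (msb + (k - 1) * msw)
  } else {
    ms <- summary(stats::aov(val ~ subj + rat, data = d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    val_icc <- if (form == "two_way_random_absolute") {
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    } else {
      (msr - mse) / (msr + (k - 1) * mse)
    }
  }
  tibble(icc = val_icc, form = form, n_subjects = n, n_raters = k)
}

#' Cohort summary of measurement records
#'
#' Mean, minimum and maximum of the clinically reported variables (varus
#' angle, offsets, actual and predicted changes, LHI), plus the count and
#' proportion of hips whose actual shortening reaches `threshold` (default
#' 5 mm, the usual cut-off for a clinically relevant discrepancy).
#'
#' @param records A measurement-record tibble from [measure_cohort()] (any
#'   data frame with the summarized columns present works).
#' @param threshold Shortening threshold in mm.
#' @return An object of class `cvo_summary`; `tidy()` returns the
#'   per-variable table, `glance()` the counts.
#' @export
cohort_summary <- function(records, threshold = 5) {
  if (nrow(records) == 0) stop_cvo("`records` is empty", "empty")
  vars <- intersect(
    c("theta", "A", "B", "actual_shortening", "predicted_shortening",
      "actual_lateralization", "predicted_lateralization", "lhi_pre", "lhi_post"),
    names(records)
  )
  stats_tbl <- tidyr::pivot_longer(records[vars], dplyr::all_of(vars),
                                   names_to = "variable", values_to = "value")
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(stats_tbl, .data$variable),
    mean = mean(.data$value), min = min(.data$value), max = max(.data$value),
    .groups = "drop"
  )
  stats_tbl <- stats_tbl[match(vars, stats_tbl$variable), ]
  n_ge <- if ("actual_shortening" %in% names(records)) {
    sum(records$actual_shortening >= threshold)
  } else NA_integer_
  structure(
    list(
      variables = stats_tbl,
      n = nrow(records),
      threshold = threshold,
      n_shortening_ge = n_ge,
      prop_shortening_ge = n_ge / nrow(records)
    ),
    class = "cvo_summary"
  )
}

#' @export
print.cvo_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d hips; %d (%.0f%%) with actual shortening >= %g mm\n",
              x$n, x$n_shortening_ge, 100 * x$prop_shortening_ge, x$threshold))
  print(x$variables)
  invisible(x)
}

#' @rdname cohort_summary
#' @param x A `cvo_summary` object.
#' @param ... Unused.
#' @method tidy cvo_summary
#' @export
tidy.cvo_summary <- function(x, ...) x$variables

#' @rdname cohort_summary
#' @method glance cvo_summary
#' @export
glance.cvo_summary <- function(x, ...) {
  tibble(n = x$n, threshold = x$threshold,
         n_shortening_ge = x$n_shortening_ge,
         prop_shortening_ge = x$prop_shortening_ge)
}

.cor_safe <- function(records, x, y, label) {
  res <- tryCatch(
    pearson_cor(records, {{ x }}, {{ y }}),
    cvoplan_error_zero_variance = function(e) NULL
  )
  if (is.null(res)) {
    tibble(comparison = label, r = NA_real_, p = NA_real_,
           n = nrow(records), note = "undefined: zero variance")
  } else {
    dplyr::mutate(res, comparison = label, note = "",
                  .before = 1)
  }
}

#' Validate a measured cohort against the rotation model
#'
#' Computes the four model-validation correlations: predicted vs actual
#' shortening, predicted vs actual lateralization, varus angle vs actual
#' shortening, and lateral shift `A` vs actual shortening.  Correlations
#' that are undefined (a zero-variance variable, e.g. a constant-angle
#' cohort) are flagged in the `note` column rather than failing the run.
#' Also attaches the per-hip scatter data behind the correlations and a
#' [cohort_summary()].
#'
#' @param records A measurement-record tibble from [measure_cohort()], at
#'   least 3 rows.
#' @param threshold Shortening threshold passed to [cohort_summary()].
#' @return An object of class `cvo_validation`; `tidy()` returns the
#'   correlation table, `glance()` a one-row overview, `autoplot()` the
#'   predicted-vs-actual scatter.
#' @export
validate_cohort <- function(records, threshold = 5) {
  if (nrow(records) < 3) stop_cvo("validation needs at least 3 hips", "too_few")
  correlations <- dplyr::bind_rows(
    .cor_safe(records, predicted_shortening, actual_shortening,
              "predicted vs actual shortening"),
    .cor_safe(records, predicted_lateralization, actual_lateralization,
              "predicted vs actual lateralization"),
    .cor_safe(records, theta, actual_shortening,
              "varus angle vs actual shortening"),
    .cor_safe(records, A, actual_shortening,
              "lateral shift vs actual shortening")
  )
  scatter <- records[intersect(
    c("hip_id", "theta", "A", "B",
      "predicted_shortening", "actual_shortening",
      "predicted_lateralization", "actual_lateralization"),
    names(records)
  )]
  structure(
    list(
      correlations = correlations,
      scatter = scatter,
      summary = cohort_summary(records, threshold = threshold),
      n = nrow(records)
    ),
    class = "cvo_validation"
  )
}

#' @export
print.cvo_validation <- function(x, ...) {
  cat(sprintf("Rotation-model validation on %d hips\n", x$n))
  print(x$correlations)
  invisible(x)
}

#' @rdname validate_cohort
#' @param x A `cvo_validation` object.
#' @param ... Unused.
#' @method tidy cvo_validation
#' @export
tidy.cvo_validation <- function(x, ...) x$correlations

#' @rdname validate_cohort
#' @method glance cvo_validation
#' @export
glance.cvo_validation <- function(x, ...) {
  cs <- x$correlations
  short <- cs[cs$comparison == "predicted vs actual shortening", ]
  lat <- cs[cs$comparison == "predicted vs actual lateralization", ]
  tibble(
    n = x$n,
    r_shortening = short$r, p_shortening = short$p,
    r_lateralization = lat$r, p_lateralization = lat$p,
    prop_shortening_ge = x$summary$prop_shortening_ge
  )
}
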