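#' Forward plan: predicted changes for a candidate osteotomy
#'
#' Evaluates the rotation model for planning inputs: the arc-center offsets
#' `(A, B)` and an intended varus angle `theta >= 0` (valgus angles are not
#' planned and raise an error).  Vectorized, so a grid of candidate plans
#' can be evaluated in one call.
#'
#' @inheritParams predict_shortening
#' @return A tibble with `A`, `B`, `theta`, `shortening`, `lateralization`,
#'   `head_post_x`, `head_post_y` (mm / degrees).
#' @examples
#' plan_forward(3.3, 9.3, 21.7)
#' @export
plan_forward <- function(A, B, theta) {
  check_finite(A, "A"); check_finite(B, "B"); check_finite(theta, "theta")
  if (any(theta < 0)) {
    stop_cvo("planning requires a varus angle theta >= 0 (valgus is not planned)", "valgus_plan")
  }
  hp <- head_post(A, B, theta)
  tibble(
    A = A, B = B, theta = theta,
    shortening = predict_shortening(A, B, theta),
    lateralization = predict_lateralization(A, B, theta),
    head_post_x = hp$x, head_post_y = hp$y
  )
}

#' Largest lateral shift within a shortening budget
#'
#' Inverts the shortening formula in `A`: the largest lateral shift of the
#' arc center that keeps predicted shortening at or below `s_max` is
#' `A_max = (s_max - B (1 - cos(theta))) / sin(theta)`.  A negative result
#' means the arc center must sit medial to the head center to respect the
#' budget.  The default budget of 5 mm is the usual clinical threshold for a
#' relevant leg-length discrepancy after this osteotomy.
#'
#' @param B Distal shift of the arc center, mm. Vectorized.
#' @param theta Varus angle in degrees, strictly inside (0, 90).
#' @param s_max Shortening budget in mm (default 5).
#' @return `A_max` in mm.
#' @examples
#' max_lateral_shift(10, 20, 5)
#' @export
max_lateral_shift <- function(B, theta, s_max = 5) {
  check_finite(B, "B"); check_finite(theta, "theta"); check_finite(s_max, "s_max")
  if (any(theta <= 0 | theta >= 90)) {
    stop_cvo("`theta` must lie strictly inside (0, 90) degrees", "bad_theta")
  }
  th <- deg2rad(theta)
  (s_max - B * (1 - cos(th))) / sin(th)
}

#' Sensitivity of predicted shortening to its inputs
#'
#' Analytic partial derivatives of the shortening formula: `sin(theta)` per
#' mm of lateral shift `A`, `1 - cos(theta)` per mm of distal shift `B`, and
#' `(A cos(theta) + B sin(theta)) * pi / 180` per degree of varus.  Useful
#' for judging which measurement errors matter at a given plan.
#'
#' @inheritParams predict_shortening
#' @return A tibble with `dS_dA`, `dS_dB` (mm/mm) and `dS_dtheta` (mm/degree).
#' @examples
#' shortening_sensitivity(3.3, 9.3, 21.7)
#' @export
shortening_sensitivity <- function(A, B, theta) {
  check_finite(A, "A"); check_finite(B, "B"); check_finite(theta, "theta")
  th <- deg2rad(theta)
  tibble(
    dS_dA = sin(th),
    dS_dB = 1 - cos(th),
    dS_dtheta = (A * cos(th) + B * sin(th)) * pi / 180
  )
}

#' Smallest varus angle reaching a target LHI
#'
#' Searches `theta` in `[0, theta_max]` for the smallest varus angle whose
#' post-rotation lateral head index (see [lhi_after_varus()]) reaches
#' `target_lhi`.  The LHI profile is first evaluated on a `grid_step` grid;
#' if it is monotone non-decreasing the crossing is refined by bisection to
#' 0.005 degrees, otherwise the smallest feasible grid angle is returned
#' with a warning.  A warning is also raised when the answer falls outside
#' `theta_range`, the band of varus angles this osteotomy normally uses.
#'
#' @param landmarks Pre-operative canonical landmark tibble with head
#'   borders and necrosis margin.
#' @param arc Pre-operative osteotomy-arc center (length-2 numeric, 1-row
#'   data frame, or [fit_circle()] result).
#' @param target_lhi Target lateral head index, percent (default 25, the
#'   usual indication threshold).
#' @param theta_range Varus angles considered typical, degrees (default
#'   `c(15, 38)`).
#' @param theta_max Search cap in degrees (default 45).
#' @param grid_step Grid resolution for the bracketing pass, degrees.
#' @return A one-row tibble with `theta` (degrees), `lhi` (percent achieved
#'   at `theta`), and `within_range` (logical).
#' @export
required_varus_for_lhi <- function(landmarks, arc, target_lhi = 25,
                                   theta_range = c(15, 38), theta_max = 45,
                                   grid_step = 0.5) {
  if (target_lhi <= 0 || target_lhi > 100) {
    stop_cvo("`target_lhi` must lie in (0, 100]", "bad_target")
  }
  lhi_at <- function(th) lhi_after_varus(landmarks, arc, th)$lhi
  grid <- seq(0, theta_max, by = grid_step)
  if (grid[length(grid)] < theta_max) grid <- c(grid, theta_max)
  vals <- vapply(grid, lhi_at, numeric(1))

  finish <- function(theta) {
    within <- theta >= theta_range[1] && theta <= theta_range[2]
    if (!within && theta > 0) {
      warn_cvo(sprintf("required varus angle %.2f deg is outside the typical range [%g, %g]",
                       theta, theta_range[1], theta_range[2]), "theta_out_of_range")
    }
    tibble(theta = theta, lhi = lhi_at(theta), within_range = within)
  }

  if (vals[1] >= target_lhi) return(finish(0))
  feasible <- which(vals >= target_lhi)
  if (length(feasible) == 0) {
    stop_cvo(sprintf("target LHI %.1f%% is unreachable with varus up to %g deg (max %.1f%%)",
                     target_lhi, theta_max, max(vals)), "infeasible")
  }
  monotone <- all(diff(vals) >= -1e-9)
  if (!monotone) {
    warn_cvo("LHI is not monotone in theta over the search grid; returning the smallest feasible grid angle",
             "non_monotone_lhi")
    return(finish(grid[feasible[1]]))
  }
  lo <- grid[feasible[1] - 1]
  hi <- grid[feasible[1]]
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (lhi_at(mid) >= target_lhi) hi <- mid else lo <- mid
  }
  finish(hi)
}

#' Assemble a planning report
#'
#' Bundles the forward prediction, the lateral-shift budget, and the
#' sensitivities for one candidate plan into a named list ready for JSON
#' serialization (used by the command-line `plan` subcommand).
#'
#' @inheritParams predict_shortening
#' @param s_max Shortening budget in mm.
#' @param theta_range Typical varus-angle band, degrees.
#' @return A list with elements `inputs`, `prediction`, `A_max`,
#'   `sensitivity`, and `warnings` (character vector).
#' @export
plan_report <- function(A, B, theta, s_max = 5, theta_range = c(15, 38)) {
  pf <- plan_forward(A, B, theta)
  warnings <- character()
  if (theta > 0 && (theta < theta_range[1] || theta > theta_range[2])) {
    warnings <- c(warnings, sprintf("varus angle %.1f deg outside typical range [%g, %g]",
                                    theta, theta_range[1], theta_range[2]))
  }
  if (pf$shortening > s_max) {
    warnings <- c(warnings, sprintf("predicted shortening %.2f mm exceeds the %.1f mm budget",
                                    pf$shortening, s_max))
  }
  a_max <- if (theta > 0 && theta < 90) max_lateral_shift(B, theta, s_max) else NA_real_
  list(
    inputs = list(A = A, B = B, theta = theta, s_max = s_max),
    prediction = as.list(pf),
    A_max = a_max,
    sensitivity = as.list(shortening_sensitivity(A, B, theta)),
    warnings = warnings
  )
}
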