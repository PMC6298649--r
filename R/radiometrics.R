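# Radiographic measurements from canonical landmark sets.  The exported
# functions take tidy landmark tibbles; small internal helpers work on the
# named point matrices produced by ls_points()/canonical_transform() so the
# batch pipeline stays fast.

.nsa_points <- function(P) {
  shaft <- P["shaft_axis_2", ] - P["shaft_axis_1", ] # toward the knee (distal)
  neck <- P["neck_axis_2", ] - P["neck_axis_1", ]    # toward the head
  ls2 <- sqrt(sum(shaft^2)); ln2 <- sqrt(sum(neck^2))
  if (ls2 < 1e-9 || ln2 < 1e-9) stop_cvo("zero-length shaft or neck axis", "degenerate_axis")
  cosv <- sum(shaft * neck) / (ls2 * ln2)
  rad2deg(acos(min(1, max(-1, cosv))))
}

.vd_ld_points <- function(P) {
  c(vd = unname(P["gt_tip", 2]), ld = unname(P["gt_lateral", 1]))
}

.lhi_extents <- function(x_medial, x_lateral, x_margin) {
  head_width <- x_lateral - x_medial
  if (head_width <= 0) {
    stop_cvo("head width is not positive: head_lateral must lie lateral to head_medial",
             "degenerate_geometry")
  }
  intact <- if (is.na(x_margin)) head_width else min(max(x_lateral - x_margin, 0), head_width)
  tibble(intact_width = intact, head_width = head_width,
         lhi = 100 * intact / head_width)
}

.require_canonical <- function(P, what) {
  if (!is_canonical_points(P)) {
    stop_cvo(sprintf("%s requires canonical-frame landmarks; run canonicalize() first", what),
             "not_canonical")
  }
  invisible(P)
}

#' Neck-shaft angle of one landmark set
#'
#' Angle, in degrees, between the femoral neck axis (direction
#' `neck_axis_1 -> neck_axis_2`, i.e. toward the head) and the shaft axis
#' (direction `shaft_axis_1 -> shaft_axis_2`, i.e. toward the knee).  The
#' result lies in (0, 180]; a normal adult hip is around 125-140 degrees.
#' Unsigned angles are preserved by rigid transforms and mirroring, so any
#' frame is accepted.
#'
#' @param landmarks A single hip/stage landmark tibble.
#' @return Angle in degrees.
#' @export
neck_shaft_angle <- function(landmarks) {
  .nsa_points(ls_points(validate_landmarks(landmarks)))
}

#' Varus angulation from neck-shaft angles
#'
#' The varus angle produced by the osteotomy: pre-operative minus
#' post-operative neck-shaft angle (positive = varus, negative = valgus).
#'
#' @param nsa_pre,nsa_post Neck-shaft angles in degrees, in (0, 180).
#'   Vectorized.
#' @return Degrees of varus angulation.
#' @examples
#' varus_angulation(135, 113.3)
#' @export
varus_angulation <- function(nsa_pre, nsa_post) {
  check_finite(nsa_pre, "nsa_pre"); check_finite(nsa_post, "nsa_post")
  if (any(nsa_pre <= 0 | nsa_pre >= 180 | nsa_post <= 0 | nsa_post >= 180)) {
    stop_cvo("neck-shaft angles must lie in (0, 180) degrees", "bad_angle")
  }
  nsa_pre - nsa_post
}

#' Teardrop-referenced trochanter distances
#'
#' In the canonical frame the vertical distance VD from the
#' greater-trochanter tip to the tear-drop line is simply the y-coordinate
#' of `gt_tip`, and the lateral distance LD of the lateral trochanteric
#' border from the teardrop reference is the x-coordinate of `gt_lateral`.
#' Pre-to-post differences of VD and LD define the actual leg shortening and
#' femoral lateralization.
#'
#' @param landmarks A single hip/stage landmark tibble in the canonical
#'   frame (see [canonicalize()]).
#' @return A tibble with columns `vd`, `ld` (mm).
#' @export
measure_vd_ld <- function(landmarks) {
  P <- ls_points(validate_landmarks(landmarks))
  .require_canonical(P, "measure_vd_ld()")
  v <- .vd_ld_points(P)
  tibble(vd = v[["vd"]], ld = v[["ld"]])
}

#' Actual pre-to-post changes from VD/LD measurements
#'
#' Actual leg shortening is the post-operative minus pre-operative vertical
#' distance VD (the femur rides proximally when the leg shortens); actual
#' femoral lateralization is the change in the lateral distance LD.
#'
#' @param pre,post Data frames with columns `hip_id`, `vd`, `ld` for the
#'   same hips (e.g. built from [measure_vd_ld()]).
#' @return A tibble with `hip_id`, `actual_shortening`, `actual_lateralization` (mm).
#' @export
actual_changes <- function(pre, post) {
  for (df in list(pre, post)) {
    if (!all(c("hip_id", "vd", "ld") %in% names(df))) {
      stop_cvo("`pre` and `post` need columns hip_id, vd, ld", "schema")
    }
  }
  if (!setequal(pre$hip_id, post$hip_id) || anyDuplicated(pre$hip_id) || anyDuplicated(post$hip_id)) {
    stop_cvo("`pre` and `post` must cover the same hip_ids exactly once", "hip_mismatch")
  }
  m <- dplyr::inner_join(
    dplyr::rename(as_tibble(pre), vd_pre = "vd", ld_pre = "ld"),
    dplyr::rename(as_tibble(post), vd_post = "vd", ld_post = "ld"),
    by = "hip_id"
  )
  tibble(
    hip_id = m$hip_id,
    actual_shortening = m$vd_post - m$vd_pre,
    actual_lateralization = m$ld_post - m$ld_pre
  )
}

#' Lateral head index (LHI)
#'
#' Percentage of the femoral-head width that is intact (free of necrosis) on
#' the lateral side: `100 * intact_width / head_width`, with widths measured
#' as horizontal extents (parallel to the tear-drop line) in the canonical
#' frame.  `head_width` runs from `head_medial` to `head_lateral`;
#' `intact_width` from `necrosis_lateral_margin` to `head_lateral`, clamped
#' to `[0, head_width]`.  A missing necrosis margin means a fully intact
#' head (LHI 100).
#'
#' @param landmarks A single hip/stage landmark tibble in the canonical frame.
#' @return A tibble with `intact_width`, `head_width` (mm) and `lhi` (percent).
#' @export
compute_lhi <- function(landmarks) {
  P <- ls_points(validate_landmarks(landmarks))
  .require_canonical(P, "compute_lhi()")
  xm <- if (.necrosis_name %in% rownames(P)) P[.necrosis_name, 1] else NA_real_
  .lhi_extents(P["head_medial", 1], P["head_lateral", 1], xm)
}

#' LHI after a simulated varus rotation
#'
#' Rotates the head borders and the necrosis margin of a pre-operative
#' canonical landmark set about the osteotomy-arc center by the varus angle
#' `theta` (the proximal-fragment motion) and recomputes the lateral head
#' index from the rotated horizontal extents.  This is the geometric
#' operationalization used for inverse planning: it answers "how much intact
#' lateral width does a given varus angle buy".
#'
#' @param landmarks Pre-operative single hip/stage landmark tibble, canonical
#'   frame, with head borders (and normally a necrosis margin) present.
#' @param arc Osteotomy-arc center: length-2 numeric, 1-row data frame, or
#'   [fit_circle()] result (pre-operative arc position).
#' @param theta Varus angle in degrees.
#' @return A tibble as in [compute_lhi()].
#' @export
lhi_after_varus <- function(landmarks, arc, theta) {
  P <- ls_points(validate_landmarks(landmarks))
  .require_canonical(P, "lhi_after_varus()")
  ctr <- as_xy(arc, "arc")
  nm <- c("head_medial", "head_lateral",
          if (.necrosis_name %in% rownames(P)) .necrosis_name)
  R <- rotate_points(P[nm, , drop = FALSE], theta, ctr)
  xm <- if (.necrosis_name %in% nm) R$x[3] else NA_real_
  .lhi_extents(R$x[1], R$x[2], xm)
}

# de-rotate post-operatively measured head->arc offsets back to the
# pre-osteotomy pair (A, B): the post-op film shows the rotated head center
# H' = R(theta) (-A, B) relative to the arc center, so undoing the measured
# varus rotation recovers (-A, B).
derotate_offsets <- function(A_post, B_post, theta) {
  th <- deg2rad(-theta)
  hx <- -A_post; hy <- B_post
  x0 <- hx * cos(th) - hy * sin(th)
  y0 <- hx * sin(th) + hy * cos(th)
  tibble(A = -x0, B = y0)
}

#' Measure one hip (pre + post landmark sets)
#'
#' The full per-hip measurement pipeline: canonicalize both stages; fit the
#' head circle (rim points) and the arc circle (arc points, post-operative
#' set); measure neck-shaft angles and the varus angulation `theta`; read
#' off VD/LD and their pre-to-post changes (actual shortening and
#' lateralization); de-rotate the post-operatively measured head-to-arc
#' offsets by `theta` to the pre-osteotomy planning pair `(A, B)`; compute
#' the pre-operative LHI and the post-operative LHI (head extents rotated
#' about the arc center); and evaluate the closed-form predictions and their
#' residuals against the actual changes.
#'
#' When arc points are also digitized pre-operatively, the distance between
#' the directly fitted pre-operative arc center and the position implied by
#' the post-operative fit is reported as `arc_center_discrepancy` (a
#' measurement-quality metric); otherwise it is `NA`.
#'
#' @param pre,post Landmark tibbles for the same `hip_id`, stages `pre` and
#'   `post`, any frame.
#' @return A one-row tibble (a measurement record) with columns `hip_id`,
#'   `side`, `nsa_pre`, `nsa_post`, `theta`, `vd_pre`, `vd_post`, `ld_pre`,
#'   `ld_post`, `actual_shortening`, `actual_lateralization`, `A`, `B`,
#'   `predicted_shortening`, `predicted_lateralization`, `head_post_x`,
#'   `head_post_y`, `residual_shortening`, `residual_lateralization`,
#'   `lhi_pre`, `lhi_post`, `arc_center_discrepancy`, `valgus_flag`.
#' @export
measure_hip <- function(pre, post) {
  pre <- validate_landmarks(pre)
  post <- validate_landmarks(post)
  if (length(unique(pre$hip_id)) != 1 || length(unique(post$hip_id)) != 1) {
    stop_cvo("measure_hip() takes exactly one hip per argument", "hip_mismatch")
  }
  if (pre$hip_id[1] != post$hip_id[1]) {
    stop_cvo(sprintf("hip_id mismatch: '%s' (pre) vs '%s' (post)", pre$hip_id[1], post$hip_id[1]),
             "hip_mismatch")
  }
  if (pre$stage[1] != "pre" || post$stage[1] != "post") {
    stop_cvo("arguments must be the pre- and post-operative stages, in that order", "bad_stage")
  }
  Ppre <- canonical_transform(ls_points(pre))
  Ppost <- canonical_transform(ls_points(post))

  nsa_pre <- .nsa_points(Ppre)
  nsa_post <- .nsa_points(Ppost)
  theta <- varus_angulation(nsa_pre, nsa_post)
  valgus <- theta < 0
  if (valgus) {
    warn_cvo(sprintf("hip '%s': negative varus angulation (%.2f deg, valgus)", pre$hip_id[1], theta),
             "valgus")
  }

  rim <- c("head_rim_1", "head_rim_2", "head_rim_3")
  head_pre <- fit_circle(Ppre[rim, ])
  head_post_fit <- fit_circle(Ppost[rim, ])
  arc_names_post <- grep(.arc_pattern, rownames(Ppost), value = TRUE)
  arc_post_fit <- fit_circle(Ppost[arc_names_post, , drop = FALSE])

  off_post <- head_offsets(head_post_fit, arc_post_fit)
  off <- derotate_offsets(off_post$A, off_post$B, theta)

  # pre-op arc-center position implied by the post-op measurement
  arc_pre_implied <- c(head_pre$center[1] + off$A, head_pre$center[2] - off$B)
  arc_names_pre <- grep(.arc_pattern, rownames(Ppre), value = TRUE)
  arc_disc <- NA_real_
  if (length(arc_names_pre) >= 3) {
    arc_pre_fit <- fit_circle(Ppre[arc_names_pre, , drop = FALSE])
    arc_disc <- sqrt(sum((arc_pre_fit$center - arc_pre_implied)^2))
  }

  v_pre <- .vd_ld_points(Ppre)
  v_post <- .vd_ld_points(Ppost)
  actual_short <- v_post[["vd"]] - v_pre[["vd"]]
  actual_lat <- v_post[["ld"]] - v_pre[["ld"]]

  xm_pre <- if (.necrosis_name %in% rownames(Ppre)) Ppre[.necrosis_name, 1] else NA_real_
  lhi_pre <- .lhi_extents(Ppre["head_medial", 1], Ppre["head_lateral", 1], xm_pre)$lhi
  nm <- c("head_medial", "head_lateral", if (!is.na(xm_pre)) .necrosis_name)
  Rr <- rotate_points(Ppre[nm, , drop = FALSE], theta, arc_pre_implied)
  lhi_post <- .lhi_extents(Rr$x[1], Rr$x[2], if (!is.na(xm_pre)) Rr$x[3] else NA_real_)$lhi

  hp <- head_post(off$A, off$B, theta)
  pred_short <- predict_shortening(off$A, off$B, theta)
  pred_lat <- predict_lateralization(off$A, off$B, theta)

  tibble(
    hip_id = pre$hip_id[1],
    side = pre$side[1],
    nsa_pre = nsa_pre, nsa_post = nsa_post, theta = theta,
    vd_pre = v_pre[["vd"]], vd_post = v_post[["vd"]],
    ld_pre = v_pre[["ld"]], ld_post = v_post[["ld"]],
    actual_shortening = actual_short,
    actual_lateralization = actual_lat,
    A = off$A, B = off$B,
    predicted_shortening = pred_short,
    predicted_lateralization = pred_lat,
    head_post_x = hp$x, head_post_y = hp$y,
    residual_shortening = actual_short - pred_short,
    residual_lateralization = actual_lat - pred_lat,
    lhi_pre = lhi_pre, lhi_post = lhi_post,
    arc_center_discrepancy = arc_disc,
    valgus_flag = valgus
  )
}

#' Measure every hip in a landmark table
#'
#' Runs [measure_hip()] on each hip with both a `pre` and a `post` landmark
#' set.  Hips whose measurement fails raise a warning naming the hip and are
#' dropped from the result; an error is raised only when no hip can be
#' measured.
#'
#' @param landmarks A landmark tibble containing pre and post sets for one
#'   or more hips.
#' @return A tibble of measurement records, one row per hip (see
#'   [measure_hip()]).
#' @export
measure_cohort <- function(landmarks) {
  # column checks up front; per-set completeness is checked hip by hip so a
  # single malformed hip does not abort the batch
  landmarks <- validate_landmark_columns(landmarks)
  hips <- unique(landmarks$hip_id)
  rows <- lapply(hips, function(h) {
    tryCatch(
      measure_hip(extract_set(landmarks, h, "pre"), extract_set(landmarks, h, "post")),
      cvoplan_error = function(e) {
        warn_cvo(sprintf("hip '%s' skipped: %s", h, conditionMessage(e)), "hip_skipped")
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop_cvo("no hip could be measured", "all_failed")
  }
  out
}
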