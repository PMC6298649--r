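#' Rotate points about a center
#'
#' Applies the 2D rotation `x' = x cos(theta) - y sin(theta)`,
#' `y' = x sin(theta) + y cos(theta)` (counter-clockwise for positive
#' `theta` in the canonical hip frame, +x lateral, +y proximal) about an
#' arbitrary center.  This is the rigid motion of the proximal fragment in a
#' curved varus osteotomy: a rotation by the varus angle about the center of
#' the osteotomy arc.
#'
#' @param points A data frame with columns `x`/`y` (or `x_mm`/`y_mm`), or a
#'   2-column matrix. Coordinates in mm.
#' @param theta Rotation angle in degrees (positive = varus in the canonical
#'   frame).
#' @param center Rotation center: length-2 numeric `c(x, y)`, a 1-row data
#'   frame, or a [fit_circle()] result.
#' @return A tibble with columns `x`, `y`, one row per input point.
#' @examples
#' rotate_points(data.frame(x = -5, y = 10), theta = 90)
#' @export
rotate_points <- function(points, theta, center = c(0, 0)) {
  P <- as_xy_matrix(points)
  check_finite(theta, "theta")
  if (length(theta) != 1) stop_cvo("`theta` must be a single angle", "bad_theta")
  ctr <- as_xy(center, "center")
  th <- deg2rad(theta)
  dx <- unname(P[, 1] - ctr[1])
  dy <- unname(P[, 2] - ctr[2])
  tibble(
    x = ctr[1] + dx * cos(th) - dy * sin(th),
    y = ctr[2] + dx * sin(th) + dy * cos(th)
  )
}

#' Arc-center offsets of the femoral head
#'
#' Expresses the relative position of the femoral-head center and the
#' osteotomy-arc center as the planning offsets `(A, B)`: `A` is the lateral
#' shift of the arc center from the head center (positive = arc center
#' lateral to the head center) and `B` its distal shift (positive = arc
#' center distal to the head center).  Equivalently the head center sits at
#' `(-A, B)` in a frame whose origin is the arc center.
#'
#' @param head Femoral-head center (length-2 numeric, 1-row data frame, or
#'   [fit_circle()] result), canonical frame, mm.
#' @param arc_center Osteotomy-arc center, same frame.
#' @return A tibble with columns `A`, `B` (mm).
#' @examples
#' head_offsets(c(0, 9.3), c(3.3, 0))
#' @export
head_offsets <- function(head, arc_center) {
  h <- as_xy(head, "head")
  o <- as_xy(arc_center, "arc_center")
  tibble(A = o[1] - h[1], B = h[2] - o[2])
}

#' Predicted leg shortening after varus osteotomy
#'
#' Closed form of the rotation model: rotating the proximal fragment by the
#' varus angle `theta` about the arc center moves the head center from
#' `(-A, B)` to `(-A cos(theta) - B sin(theta), -A sin(theta) + B cos(theta))`;
#' the drop in its vertical coordinate is the leg shortening
#' `A sin(theta) + B (1 - cos(theta))`.
#'
#' @param A Lateral shift of the arc center from the head center, mm
#'   (positive = lateral). Vectorized.
#' @param B Distal shift of the arc center from the head center, mm
#'   (positive = distal). Vectorized.
#' @param theta Varus angle, degrees. Vectorized.
#' @return Predicted shortening in mm (positive = leg shortened).
#' @examples
#' predict_shortening(3.3, 9.3, 21.7)
#' @export
predict_shortening <- function(A, B, theta) {
  check_finite(A, "A"); check_finite(B, "B"); check_finite(theta, "theta")
  th <- deg2rad(theta)
  A * sin(th) + B * (1 - cos(th))
}

#' Predicted femoral lateralization after varus osteotomy
#'
#' Companion closed form to [predict_shortening()]: the lateral displacement
#' of the femoral shaft is `-A (1 - cos(theta)) + B sin(theta)` (positive =
#' shaft displaced laterally).
#'
#' @inheritParams predict_shortening
#' @return Predicted lateralization in mm.
#' @examples
#' predict_lateralization(3.3, 9.3, 21.7)
#' @export
predict_lateralization <- function(A, B, theta) {
  check_finite(A, "A"); check_finite(B, "B"); check_finite(theta, "theta")
  th <- deg2rad(theta)
  -A * (1 - cos(th)) + B * sin(th)
}

#' Post-rotation position of the femoral-head center
#'
#' Head center after a varus rotation by `theta`, in the arc-center frame
#' (arc center at the origin, head pre-operatively at `(-A, B)`).
#'
#' @inheritParams predict_shortening
#' @return A tibble with columns `x`, `y` (mm, arc-center frame).
#' @examples
#' head_post(5, 10, 90) # (-10, -5)
#' @export
head_post <- function(A, B, theta) {
  check_finite(A, "A"); check_finite(B, "B"); check_finite(theta, "theta")
  th <- deg2rad(theta)
  tibble(
    x = -A * cos(th) - B * sin(th),
    y = -A * sin(th) + B * cos(th)
  )
}

#' Fit a circle to digitized points
#'
#' For exactly three non-collinear points returns the exact circumcircle; for
#' more points the algebraic (Kasa) least-squares circle, i.e. the linear
#' least-squares solution of `x^2 + y^2 = 2 a x + 2 b y + c`.  Used to locate
#' the femoral-head center from rim points and the osteotomy-arc center from
#' points digitized along the cut.
#'
#' @param points Data frame with `x`/`y` (or `x_mm`/`y_mm`) columns, or a
#'   2-column matrix; at least 3 points, not all collinear.
#' @return An object of class `cvo_circle`: a list with `center` (named
#'   length-2 numeric), `radius` (mm), `residuals` (signed radial distances of
#'   each point from the fitted circle), `rms_residual`, and `n`.
#' @examples
#' fit_circle(data.frame(x = c(0, 4, 0), y = c(0, 0, 3)))
#' @export
fit_circle <- function(points) {
  P <- as_xy_matrix(points)
  n <- nrow(P)
  if (n < 3) {
    stop_cvo(sprintf("circle fit needs at least 3 points (got %d)", n), "degenerate_geometry")
  }
  ctr0 <- colMeans(P)
  C <- sweep(P, 2, ctr0)
  sv <- svd(C, nu = 0, nv = 0)$d
  if (sv[1] <= 0 || sv[2] <= 1e-9 * sv[1]) {
    stop_cvo("circle fit is degenerate: points are collinear (or coincident) within tolerance",
             "degenerate_geometry")
  }
  # Kasa formulation, solved about the centroid for conditioning
  x <- C[, 1]; y <- C[, 2]
  M <- cbind(x, y, 1)
  z <- x^2 + y^2
  beta <- qr.solve(M, z)
  center <- ctr0 + beta[1:2] / 2
  radius <- sqrt(max(beta[3] + sum((beta[1:2] / 2)^2), 0))
  resid <- sqrt((P[, 1] - center[1])^2 + (P[, 2] - center[2])^2) - radius
  structure(
    list(
      center = c(x = unname(center[1]), y = unname(center[2])),
      radius = radius,
      residuals = unname(resid),
      rms_residual = sqrt(mean(resid^2)),
      n = n
    ),
    class = "cvo_circle"
  )
}

#' @export
print.cvo_circle <- function(x, ...) {
  cat(sprintf("<cvo_circle> center (%.3f, %.3f) mm, radius %.3f mm, n = %d, rms residual %.2g mm\n",
              x$center[1], x$center[2], x$radius, x$n, x$rms_residual))
  invisible(x)
}

#' @rdname fit_circle
#' @param x A `cvo_circle` object.
#' @param ... Unused.
#' @method tidy cvo_circle
#' @export
tidy.cvo_circle <- function(x, ...) {
  tibble(
    center_x = unname(x$center[1]),
    center_y = unname(x$center[2]),
    radius = x$radius,
    rms_residual = x$rms_residual,
    n = x$n
  )
}

#' @rdname fit_circle
#' @method glance cvo_circle
#' @export
glance.cvo_circle <- function(x, ...) {
  tibble(radius = x$radius, rms_residual = x$rms_residual, n = x$n)
}
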