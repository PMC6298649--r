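# Synthetic-cohort simulator.  Builds ground-truth hip geometries whose
# kinematics follow the rotation model exactly, renders them as pre/post
# landmark tables in the CSV schema of the radiometrics module, and adds
# digitization noise, so the whole measurement pipeline is testable without
# patient radiographs.

#' Cohort simulation parameters
#'
#' Defaults reproduce the published cohort conditions: 42 hips; lateral
#' shift `A` ~ truncated normal, mean 3.3 mm on \[-8, 21\]; distal shift `B`
#' ~ truncated normal, mean 9.3 mm on \[1, 21\]; varus angle ~ truncated
#' normal, mean 21.7 degrees on \[15, 38\]; osteotomy-arc radius 22.5 mm
#' (the middle of the 40/45/50 mm guide diameters); femoral-head radius
#' 25 mm; pre-operative neck-shaft angle 135 degrees; necrotic fraction of
#' the head width uniform on \[0.6, 0.95\]; and 0.5 mm of independent
#' Gaussian digitization noise per landmark coordinate.  The truncated-normal
#' standard deviations (5, 4 and 5) are generator choices consistent with
#' the published ranges; `family = "uniform"` samples uniformly over the
#' bounds instead.
#'
#' @param n Number of hips.
#' @param seed Integer seed recorded in the configuration; required by
#'   [simulate_cohort()] for reproducible cohorts.
#' @param dist_A,dist_B,dist_theta Lists `list(mean, sd, min, max)` for the
#'   sampled lateral shift (mm), distal shift (mm) and varus angle (degrees).
#' @param family `"truncnorm"` (default) or `"uniform"`.
#' @param noise_sd Digitization noise, mm per landmark coordinate.
#' @param arc_radius,head_radius Osteotomy-arc and femoral-head radii, mm.
#' @param nsa_pre Pre-operative neck-shaft angle, degrees.
#' @param necrosis_extent Length-2 range of the necrotic fraction of the
#'   head width (sampled uniformly).
#' @return A list of class `cvo_params`.
#' @export
cohort_params <- function(n = 42, seed = NULL,
                          dist_A = list(mean = 3.3, sd = 5, min = -8, max = 21),
                          dist_B = list(mean = 9.3, sd = 4, min = 1, max = 21),
                          dist_theta = list(mean = 21.7, sd = 5, min = 15, max = 38),
                          family = c("truncnorm", "uniform"),
                          noise_sd = 0.5,
                          arc_radius = 22.5, head_radius = 25,
                          nsa_pre = 135,
                          necrosis_extent = c(0.6, 0.95)) {
  family <- match.arg(family)
  if (n < 1) stop_cvo("`n` must be at least 1", "bad_params")
  if (noise_sd < 0) stop_cvo("`noise_sd` must be non-negative", "bad_params")
  if (arc_radius <= 0 || head_radius <= 0) stop_cvo("radii must be positive", "bad_params")
  for (d in list(dist_A, dist_B, dist_theta)) {
    if (!all(c("mean", "sd", "min", "max") %in% names(d)) || d$min >= d$max || d$sd < 0) {
      stop_cvo("each distribution needs mean, sd >= 0 and ordered min < max", "bad_params")
    }
  }
  if (length(necrosis_extent) != 2 || necrosis_extent[1] > necrosis_extent[2] ||
      necrosis_extent[1] < 0 || necrosis_extent[2] > 1) {
    stop_cvo("`necrosis_extent` must be an ordered range inside [0, 1]", "bad_params")
  }
  structure(
    list(n = n, seed = seed, dist_A = dist_A, dist_B = dist_B,
         dist_theta = dist_theta, family = family, noise_sd = noise_sd,
         arc_radius = arc_radius, head_radius = head_radius,
         nsa_pre = nsa_pre, necrosis_extent = necrosis_extent),
    class = "cvo_params"
  )
}

# truncated-normal sampling by rejection (bounds are mild, so acceptance is
# high and the draw count is data-dependent but deterministic given the seed)
rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd == 0) return(rep(pmin(pmax(mean, min), max), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= min & x <= max])
  }
  out[seq_len(n)]
}

sample_dist <- function(n, d, family) {
  if (family == "uniform") runif(n, d$min, d$max) else rtruncnorm(n, d$mean, d$sd, d$min, d$max)
}

#' Sample a ground-truth cohort
#'
#' Draws `(A, B, theta)` for each hip from the configured distributions and
#' records the exact closed-form shortening and lateralization as ground
#' truth.  Sides alternate right/left.  Deterministic given the seed.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A tibble with `hip_id`, `side`, `A`, `B`, `theta`,
#'   `true_shortening`, `true_lateralization`.
#' @export
sample_cohort <- function(params = cohort_params(), seed = params$seed) {
  if (is.null(seed)) stop_cvo("a seed is required for reproducible cohorts", "no_seed")
  withr::with_seed(seed, {
    n <- params$n
    A <- sample_dist(n, params$dist_A, params$family)
    B <- sample_dist(n, params$dist_B, params$family)
    theta <- sample_dist(n, params$dist_theta, params$family)
    tibble(
      hip_id = sprintf("hip_%03d", seq_len(n)),
      side = rep_len(c("right", "left"), n),
      A = A, B = B, theta = theta,
      true_shortening = predict_shortening(A, B, theta),
      true_lateralization = predict_lateralization(A, B, theta)
    )
  })
}

# Scene constants for one synthetic AP hip radiograph, in the canonical
# frame of a right hip (teardrop origin, +x lateral, +y proximal), mm.
# Chosen once as anatomically plausible adult values; only relative
# geometry matters to the measurements.
.scene <- list(
  teardrop_contra_x = -115,      # inter-teardrop distance
  head_center = c(32, 58),       # femoral-head center above/lateral to the teardrop
  rim_angles = c(40, 95, 150),   # head-rim digitization points, superior half (deg)
  arc_angles = c(200, 235, 270, 305, 340), # digitized points along the cut (deg)
  shaft_dx = 6,                  # shaft axis x-offset from the arc center
  shaft_y = c(-5, -65),          # proximal/distal shaft-axis points
  neck_len = c(45, 5),           # neck-axis points, distances from head center
  gt_tip_off = c(38, 2),         # trochanter tip relative to head center
  gt_lat_off = c(44, -22)        # lateral trochanteric border relative to head center
)

# proximal-fragment landmark names (rotate with the head); everything else
# femoral translates with the distal fragment
.proximal_names <- c("head_rim_1", "head_rim_2", "head_rim_3",
                     "head_medial", "head_lateral",
                     "neck_axis_1", "neck_axis_2", .necrosis_name)
.pelvic_names <- c("teardrop_ipsi", "teardrop_contra")

# Build the noiseless pre-operative scene for one hip as a named matrix.
build_pre_scene <- function(A, B, necrosis_frac, params) {
  hc <- .scene$head_center
  rh <- params$head_radius
  O <- hc + c(A, -B)
  rim <- t(vapply(.scene$rim_angles, function(a) {
    hc + rh * c(cos(deg2rad(a)), sin(deg2rad(a)))
  }, numeric(2)))
  arc <- t(vapply(.scene$arc_angles, function(a) {
    O + params$arc_radius * c(cos(deg2rad(a)), sin(deg2rad(a)))
  }, numeric(2)))
  sx <- O[1] + .scene$shaft_dx
  neck_dir <- c(cos(deg2rad(270 - params$nsa_pre)), sin(deg2rad(270 - params$nsa_pre)))
  x_med <- hc[1] - rh
  x_marg <- x_med + necrosis_frac * 2 * rh
  y_marg <- hc[2] + sqrt(max(rh^2 - (x_marg - hc[1])^2, 0))
  P <- rbind(
    teardrop_ipsi = c(0, 0),
    teardrop_contra = c(.scene$teardrop_contra_x, 0),
    gt_tip = hc + .scene$gt_tip_off,
    gt_lateral = hc + .scene$gt_lat_off,
    shaft_axis_1 = c(sx, .scene$shaft_y[1]),
    shaft_axis_2 = c(sx, .scene$shaft_y[2]),
    neck_axis_1 = hc - .scene$neck_len[1] * neck_dir,
    neck_axis_2 = hc - .scene$neck_len[2] * neck_dir,
    head_rim_1 = rim[1, ], head_rim_2 = rim[2, ], head_rim_3 = rim[3, ],
    head_medial = c(x_med, hc[2]),
    head_lateral = c(hc[1] + rh, hc[2]),
    necrosis_lateral_margin = c(x_marg, y_marg),
    arc_1 = arc[1, ], arc_2 = arc[2, ], arc_3 = arc[3, ],
    arc_4 = arc[4, ], arc_5 = arc[5, ]
  )
  colnames(P) <- c("x", "y")
  P
}

# Post-operative scene: rotate the proximal fragment about the arc center by
# theta, then translate every femoral landmark so the head center returns to
# its pre-operative (acetabular) position; the pelvic teardrops stay put.
build_post_scene <- function(P_pre, A, B, theta, params) {
  hc <- .scene$head_center
  O <- hc + c(A, -B)
  P <- P_pre
  prox <- rownames(P) %in% .proximal_names
  rot <- rotate_points(P[prox, , drop = FALSE], theta, O)
  P[prox, 1] <- rot$x
  P[prox, 2] <- rot$y
  hc_rot <- O + c(
    (hc[1] - O[1]) * cos(deg2rad(theta)) - (hc[2] - O[2]) * sin(deg2rad(theta)),
    (hc[1] - O[1]) * sin(deg2rad(theta)) + (hc[2] - O[2]) * cos(deg2rad(theta))
  )
  shift <- hc - hc_rot  # equals (lateralization, shortening)
  femoral <- !rownames(P) %in% .pelvic_names
  P[femoral, 1] <- P[femoral, 1] + shift[1]
  P[femoral, 2] <- P[femoral, 2] + shift[2]
  P
}

# random raw-image frame: mirror left hips, then rotate/translate; mimics
# per-radiograph positioning differences that canonicalize() must undo
raw_frame_transform <- function(P, side) {
  if (side == "left") P[, 1] <- -P[, 1]
  ang <- deg2rad(runif(1, -8, 8))
  tr <- runif(2, -15, 15)
  Q <- cbind(
    P[, 1] * cos(ang) - P[, 2] * sin(ang) + tr[1],
    P[, 2] * cos(ang) + P[, 1] * sin(ang) + tr[2]
  )
  rownames(Q) <- rownames(P)
  Q
}

scene_to_rows <- function(P, hip_id, stage, side) {
  tibble(
    hip_id = hip_id, stage = stage, side = side,
    name = rownames(P), x_mm = unname(P[, 1]), y_mm = unname(P[, 2])
  )
}

#' Render landmark files for ground-truth hips
#'
#' Builds the pre-operative scene of each hip in its canonical frame (head
#' and arc circles, neck/shaft axes at the configured neck-shaft angle,
#' trochanter and teardrop landmarks, necrosis margin), applies the varus
#' rotation of the proximal fragment about the arc center followed by the
#' femoral translation that keeps the head seated in the acetabulum, maps
#' both stages through a random raw-image frame (rotation, translation, and
#' an x-mirror for left hips), and finally adds independent zero-mean
#' Gaussian noise to every landmark coordinate.
#'
#' @param truth A ground-truth tibble from [sample_cohort()] (any subset of
#'   its rows).
#' @param params A [cohort_params()] object.
#' @param noise_sd Noise per coordinate in mm (defaults to `params$noise_sd`).
#' @param seed Integer seed for the frame jitter, noise and necrosis
#'   fractions.
#' @return A landmark tibble (pre and post rows for every hip).
#' @export
render_landmarks <- function(truth, params = cohort_params(),
                             noise_sd = params$noise_sd, seed = params$seed) {
  if (is.null(seed)) stop_cvo("a seed is required for reproducible rendering", "no_seed")
  withr::with_seed(seed, {
    rows <- vector("list", 2L * nrow(truth))
    for (i in seq_len(nrow(truth))) {
      h <- truth[i, ]
      nec <- runif(1, params$necrosis_extent[1], params$necrosis_extent[2])
      P_pre <- build_pre_scene(h$A, h$B, nec, params)
      P_post <- build_post_scene(P_pre, h$A, h$B, h$theta, params)
      Q_pre <- raw_frame_transform(P_pre, h$side)
      Q_post <- raw_frame_transform(P_post, h$side)
      if (noise_sd > 0) {
        Q_pre <- Q_pre + rnorm(length(Q_pre), 0, noise_sd)
        Q_post <- Q_post + rnorm(length(Q_post), 0, noise_sd)
      }
      rows[[2 * i - 1]] <- scene_to_rows(Q_pre, h$hip_id, "pre", h$side)
      rows[[2 * i]] <- scene_to_rows(Q_post, h$hip_id, "post", h$side)
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a full synthetic cohort
#'
#' [sample_cohort()] followed by [render_landmarks()], bundled with the
#' parameters and seed used.
#'
#' @inheritParams render_landmarks
#' @param params A [cohort_params()] object.
#' @param seed Integer seed (defaults to `params$seed`; required).
#' @return An object of class `cvo_cohort`: a list with `landmarks` (tibble),
#'   `truth` (tibble), `params`, `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_params(n = 3, noise_sd = 0), seed = 1)
#' measure_cohort(coh$landmarks)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = params$seed,
                            noise_sd = params$noise_sd) {
  if (is.null(seed)) stop_cvo("a seed is required for reproducible cohorts", "no_seed")
  truth <- sample_cohort(params, seed = seed)
  landmarks <- render_landmarks(truth, params, noise_sd = noise_sd, seed = seed + 1L)
  structure(list(landmarks = landmarks, truth = truth, params = params, seed = seed),
            class = "cvo_cohort")
}

#' @export
print.cvo_cohort <- function(x, ...) {
  cat(sprintf("<cvo_cohort> %d hips, noise sd %.2g mm, seed %d\n",
              nrow(x$truth), x$params$noise_sd, x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `landmarks.csv` (radiometrics schema), `truth.csv` (per-hip ground
#' truth), and `config.json` (parameters + seed) into `dir`.  Re-running
#' with the same configuration reproduces the files byte for byte.
#'
#' @param cohort A `cvo_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The paths of the written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    landmarks = file.path(dir, "landmarks.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.json")
  )
  write_landmarks(cohort$landmarks, paths[["landmarks"]])
  readr::write_csv(cohort$truth, paths[["truth"]])
  cfg <- cohort$params
  cfg$seed <- cohort$seed
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate repeat digitizations of the same radiographs
#'
#' Produces `k` independent noisy re-digitizations of a landmark table (the
#' same underlying truth re-measured), for intra-/inter-rater agreement
#' studies: measure each replicate, then feed the per-rater values to
#' [icc()].
#'
#' @param landmarks A landmark tibble (treated as the underlying truth).
#' @param sd Re-digitization noise per coordinate, mm.
#' @param k Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return A landmark tibble with an added integer `rater` column.
#' @export
rater_replicates <- function(landmarks, sd = 0.5, k = 2, seed = NULL) {
  if (k < 2) stop_cvo("`k` must be at least 2", "bad_params")
  if (sd < 0) stop_cvo("`sd` must be non-negative", "bad_params")
  if (is.null(seed)) stop_cvo("a seed is required for reproducible replicates", "no_seed")
  landmarks <- validate_landmarks(landmarks)
  withr::with_seed(seed, {
    reps <- lapply(seq_len(k), function(r) {
      d <- landmarks
      if (sd > 0) {
        d$x_mm <- d$x_mm + rnorm(nrow(d), 0, sd)
        d$y_mm <- d$y_mm + rnorm(nrow(d), 0, sd)
      }
      d$rater <- r
      d
    })
    dplyr::bind_rows(reps)
  })
}
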