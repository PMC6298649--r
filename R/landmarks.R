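# Landmark naming scheme shared by the reader, the measurement pipeline and
# the simulator.  One row per landmark: hip_id, stage (pre|post), side
# (left|right), name, x_mm, y_mm.  Coordinates are in mm in the raw image
# frame of that radiograph (any origin/rotation; left hips may be mirrored).

landmark_base_names <- c(
  "teardrop_ipsi", "teardrop_contra",
  "gt_tip", "gt_lateral",
  "shaft_axis_1", "shaft_axis_2",
  "neck_axis_1", "neck_axis_2",
  "head_rim_1", "head_rim_2", "head_rim_3",
  "head_medial", "head_lateral"
)
.arc_pattern <- "^arc_[0-9]+$"
.necrosis_name <- "necrosis_lateral_margin"

#' Read and write landmark annotation files
#'
#' Landmark files are plain CSV with one row per digitized point and columns
#' `hip_id`, `stage` (`pre`/`post`), `side` (`left`/`right`), `name`, `x_mm`,
#' `y_mm`.  Required names per hip/stage: both teardrops (`teardrop_ipsi`,
#' `teardrop_contra`), greater-trochanter tip and lateral border (`gt_tip`,
#' `gt_lateral`), two shaft-axis points (`shaft_axis_1` proximal,
#' `shaft_axis_2` distal), two neck-axis points (`neck_axis_2` toward the
#' head), three head-rim points (`head_rim_1..3`), and the medial/lateral
#' head borders.  Post-operative sets additionally need at least three
#' points on the osteotomy arc (`arc_1`, `arc_2`, ...; optional
#' pre-operatively).  `necrosis_lateral_margin` is optional; when absent the
#' head is treated as fully intact.
#'
#' @param path File path.
#' @return `read_landmarks()`: a validated tibble in the schema above.
#' @export
read_landmarks <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      hip_id = readr::col_character(),
      stage = readr::col_character(),
      side = readr::col_character(),
      name = readr::col_character(),
      x_mm = readr::col_double(),
      y_mm = readr::col_double()
    )
  )
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop_cvo(sprintf("parse error in '%s' at row %d: expected %s, got '%s'",
                     path, prob$row[1], prob$expected[1], prob$actual[1]),
             "parse")
  }
  validate_landmarks(df)
}

#' @rdname read_landmarks
#' @param landmarks A landmark tibble (schema above).
#' @return `write_landmarks()`: the input, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmarks(landmarks)
  readr::write_csv(landmarks, path)
  invisible(landmarks)
}

#' Validate a landmark table
#'
#' Checks the schema: required columns, known `stage`/`side` values, finite
#' coordinates, no duplicated landmark names within a hip/stage, all required
#' landmark names present, and at least three arc points post-operatively.
#'
#' @param landmarks A landmark data frame.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_landmarks <- function(landmarks) {
  landmarks <- validate_landmark_columns(landmarks)
  sets <- split(landmarks, paste(landmarks$hip_id, landmarks$stage, sep = "/"))
  for (key in names(sets)) {
    s <- sets[[key]]
    dup <- unique(s$name[duplicated(s$name)])
    if (length(dup) > 0) {
      stop_cvo(sprintf("duplicated landmark '%s' for %s", dup[1], key), "schema")
    }
    miss <- setdiff(landmark_base_names, s$name)
    if (length(miss) > 0) {
      stop_cvo(sprintf("missing landmark '%s' for %s", miss[1], key), "schema")
    }
    if (length(unique(s$side)) != 1) {
      stop_cvo(sprintf("inconsistent side within %s", key), "schema")
    }
    n_arc <- sum(grepl(.arc_pattern, s$name))
    if (s$stage[1] == "post" && n_arc < 3) {
      stop_cvo(sprintf("post-operative set %s needs at least 3 arc points (got %d)", key, n_arc),
               "schema")
    }
  }
  landmarks
}

# column-level checks only (per-set completeness is checked by
# validate_landmarks, or per hip inside measure_cohort)
validate_landmark_columns <- function(landmarks) {
  req_cols <- c("hip_id", "stage", "side", "name", "x_mm", "y_mm")
  missing_cols <- setdiff(req_cols, names(landmarks))
  if (length(missing_cols) > 0) {
    stop_cvo(paste0("landmark table is missing column(s): ",
                    paste(missing_cols, collapse = ", ")), "schema")
  }
  landmarks <- as_tibble(landmarks)[req_cols]
  bad_stage <- setdiff(unique(landmarks$stage), c("pre", "post"))
  if (length(bad_stage) > 0) {
    stop_cvo(paste0("unknown stage: ", paste(bad_stage, collapse = ", ")), "schema")
  }
  bad_side <- setdiff(unique(landmarks$side), c("left", "right"))
  if (length(bad_side) > 0) {
    stop_cvo(paste0("unknown side: ", paste(bad_side, collapse = ", ")), "schema")
  }
  bad_coord <- which(!is.finite(landmarks$x_mm) | !is.finite(landmarks$y_mm))
  if (length(bad_coord) > 0) {
    stop_cvo(sprintf("non-numeric or non-finite coordinate at row %d (hip '%s', landmark '%s')",
                     bad_coord[1], landmarks$hip_id[bad_coord[1]], landmarks$name[bad_coord[1]]),
             "schema")
  }
  landmarks
}

# single (hip_id, stage) landmark set -> named n x 2 matrix
ls_points <- function(ls) {
  m <- cbind(x = ls$x_mm, y = ls$y_mm)
  rownames(m) <- ls$name
  m
}

# one landmark set from a table, with existence check
extract_set <- function(landmarks, hip_id, stage) {
  s <- landmarks[landmarks$hip_id == hip_id & landmarks$stage == stage, , drop = FALSE]
  if (nrow(s) == 0) {
    stop_cvo(sprintf("no '%s' landmarks for hip '%s'", stage, hip_id), "missing_stage")
  }
  s
}

# Rigid(+mirror) map of one point matrix into the canonical frame:
# teardrop_ipsi at the origin, the tear-drop line along the x-axis with +x
# toward the hip under study (ipsilateral = lateral), +y proximal.  The
# lateral direction comes from teardrop_contra -> teardrop_ipsi, so left
# hips are mirrored automatically and `side` is metadata only.
canonical_transform <- function(P) {
  for (nm in c("teardrop_ipsi", "teardrop_contra")) {
    if (!nm %in% rownames(P)) stop_cvo(sprintf("missing landmark '%s'", nm), "schema")
  }
  ti <- P["teardrop_ipsi", ]
  tc <- P["teardrop_contra", ]
  d <- ti - tc
  L <- sqrt(sum(d^2))
  if (L < 1e-9) {
    stop_cvo("teardrop landmarks coincide: canonical frame is degenerate", "degenerate_frame")
  }
  ux <- d / L
  uy <- c(-ux[2], ux[1])
  Q <- cbind(
    (P[, 1] - ti[1]) * ux[1] + (P[, 2] - ti[2]) * ux[2],
    (P[, 1] - ti[1]) * uy[1] + (P[, 2] - ti[2]) * uy[2]
  )
  # orient +y proximal: the trochanter tip lies above the tear-drop line
  ref <- if ("gt_tip" %in% rownames(P)) Q[rownames(P) == "gt_tip", 2][1] else mean(Q[, 2])
  if (abs(ref) < 1e-12) ref <- mean(Q[, 2])
  if (ref < 0) Q[, 2] <- -Q[, 2]
  rownames(Q) <- rownames(P)
  colnames(Q) <- c("x", "y")
  Q
}

is_canonical_points <- function(P, tol = 1e-6) {
  all(c("teardrop_ipsi", "teardrop_contra") %in% rownames(P)) &&
    all(abs(P["teardrop_ipsi", ]) <= tol) &&
    abs(P["teardrop_contra", 2]) <= tol &&
    P["teardrop_contra", 1] < 0 &&
    (!"gt_tip" %in% rownames(P) || P[rownames(P) == "gt_tip", 2][1] >= -tol)
}

#' Map landmarks into the canonical hip frame
#'
#' Applies, per hip and stage, the rigid transform (rotation + translation,
#' with an x-mirror where needed) that puts the ipsilateral teardrop at the
#' origin, the tear-drop line along the x-axis with +x lateral for the hip
#' under study, and +y proximal.  All distances are preserved, so every
#' derived measurement is invariant to the raw digitization frame.  The
#' lateral direction is taken from `teardrop_contra -> teardrop_ipsi`, which
#' makes left- and right-hip (mirror-image) files land on identical
#' canonical coordinates.
#'
#' @param landmarks A landmark tibble (full table or a single hip/stage).
#' @return A tibble in the same schema with canonical coordinates.
#' @export
canonicalize <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  key <- paste(landmarks$hip_id, landmarks$stage, sep = "/")
  parts <- split(landmarks, key)
  out <- lapply(parts, function(s) {
    Q <- canonical_transform(ls_points(s))
    s$x_mm <- unname(Q[, 1])
    s$y_mm <- unname(Q[, 2])
    s
  })
  dplyr::bind_rows(out[unique(key)])
}
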