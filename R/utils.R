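deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_cvo <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("cvoplan_error_", class), "cvoplan_error"), ...)
}

warn_cvo <- function(message, class, ...) {
  rlang::warn(message, class = c(paste0("cvoplan_warning_", class), "cvoplan_warning"), ...)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_cvo(sprintf("`%s` must be finite numeric (got %s)", what,
                     paste(utils::head(format(x), 4), collapse = ", ")),
             "nonfinite")
  }
  invisible(x)
}

# Accept a 2-column matrix, or a data frame with columns x/y or x_mm/y_mm.
# Returns an n x 2 matrix, row names preserved.
as_xy_matrix <- function(points, what = "points") {
  if (is.matrix(points)) {
    if (ncol(points) != 2) stop_cvo(sprintf("`%s` matrix must have 2 columns", what), "bad_points")
    m <- points
  } else if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      m <- cbind(points$x, points$y)
    } else if (all(c("x_mm", "y_mm") %in% names(points))) {
      m <- cbind(points$x_mm, points$y_mm)
    } else {
      stop_cvo(sprintf("`%s` must have columns x/y or x_mm/y_mm", what), "bad_points")
    }
    if ("name" %in% names(points)) rownames(m) <- points$name
  } else if (is.numeric(points) && length(points) == 2) {
    m <- matrix(points, nrow = 1)
  } else {
    stop_cvo(sprintf("`%s` must be a 2-column matrix or data frame", what), "bad_points")
  }
  storage.mode(m) <- "double"
  check_finite(m, what)
  colnames(m) <- c("x", "y")
  m
}

# length-2 numeric from point-like input (vector, 1-row df, circle fit)
as_xy <- function(p, what = "point") {
  if (inherits(p, "cvo_circle")) return(unname(p$center))
  m <- as_xy_matrix(p, what)
  if (nrow(m) != 1) stop_cvo(sprintf("`%s` must be a single point", what), "bad_points")
  unname(c(m[1, 1], m[1, 2]))
}
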