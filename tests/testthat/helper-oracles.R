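# Independent oracles, deliberately implemented with different machinery
# than the package (complex arithmetic, direct summation) so they cross-check
# rather than mirror the implementation.

# rotation via complex multiplication
oracle_rotate <- function(p, center, theta_deg) {
  z <- complex(real = p[1], imaginary = p[2])
  c0 <- complex(real = center[1], imaginary = center[2])
  w <- (z - c0) * exp(1i * theta_deg * pi / 180) + c0
  c(Re(w), Im(w))
}

# angle between two vectors via atan2 of cross/dot
oracle_angle <- function(u, v) {
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  abs(atan2(cross, dot)) * 180 / pi
}

# Pearson r by the direct covariance summation formula; p via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# ICC from explicitly summed ANOVA mean squares on a subjects x raters matrix
oracle_icc <- function(mat, form) {
  n <- nrow(mat); k <- ncol(mat)
  m <- mean(mat)
  mi <- rowMeans(mat); mj <- colMeans(mat)
  msr <- k * sum((mi - m)^2) / (n - 1)
  msc <- n * sum((mj - m)^2) / (k - 1)
  sst <- sum((mat - m)^2)
  mse <- (sst - k * sum((mi - m)^2) - n * sum((mj - m)^2)) / ((n - 1) * (k - 1))
  msw <- sum((mat - mi)^2) / (n * (k - 1))
  switch(form,
    oneway = (msr - msw) / (msr + (k - 1) * msw),
    two_way_random_absolute = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    two_way_mixed_consistency = (msr - mse) / (msr + (k - 1) * mse)
  )
}

# apply a rigid transform (+ optional mirror) to a raw landmark table
transform_landmarks <- function(landmarks, angle_deg = 0, tx = 0, ty = 0, mirror = FALSE) {
  x <- landmarks$x_mm
  if (mirror) x <- -x
  th <- angle_deg * pi / 180
  out <- landmarks
  out$x_mm <- x * cos(th) - landmarks$y_mm * sin(th) + tx
  out$y_mm <- x * sin(th) + landmarks$y_mm * cos(th) + ty
  out
}

# small noiseless test cohort, memoised per session
noiseless_cohort <- local({
  cache <- NULL
  function(n = 6, seed = 42) {
    key <- paste(n, seed)
    if (is.null(cache) || cache$key != key) {
      coh <- simulate_cohort(cohort_params(n = n, noise_sd = 0), seed = seed)
      cache <<- list(key = key, coh = coh)
    }
    cache$coh
  }
})
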