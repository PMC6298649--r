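test_that("sampled cohorts respect bounds and are reproducible", {
  params <- cohort_params(n = 42)
  t1 <- sample_cohort(params, seed = 9)
  t2 <- sample_cohort(params, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(t1$A >= -8 & t1$A <= 21))
  expect_true(all(t1$B >= 1 & t1$B <= 21))
  expect_true(all(t1$theta >= 15 & t1$theta <= 38))
  expect_identical(t1$side, rep_len(c("right", "left"), 42))
  expect_equal(t1$true_shortening, predict_shortening(t1$A, t1$B, t1$theta))
  expect_error(sample_cohort(params), class = "cvoplan_error_no_seed")
})

test_that("truncated-normal sample means match the analytic truncated mean", {
  big <- sample_cohort(cohort_params(n = 10000), seed = 17)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  # closed-form expectation of a truncated normal (independent oracle);
  # asymmetric bounds shift it away from the center parameter
  tmean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  expect_lt(abs(mean(big$A) - tmean(3.3, 5, -8, 21)), 3 * se(big$A))
  expect_lt(abs(mean(big$B) - tmean(9.3, 4, 1, 21)), 3 * se(big$B))
  expect_lt(abs(mean(big$theta) - tmean(21.7, 5, 15, 38)), 3 * se(big$theta))
  # uniform family spans the bounds instead
  u <- sample_cohort(cohort_params(n = 2000, family = "uniform"), seed = 18)
  expect_lt(abs(mean(u$A) - (21 - 8) / 2), 0.5)
})

test_that("rendering is deterministic and parameter validation bites", {
  params <- cohort_params(n = 3)
  c1 <- simulate_cohort(params, seed = 4)
  c2 <- simulate_cohort(params, seed = 4)
  expect_identical(c1$landmarks, c2$landmarks)
  c3 <- simulate_cohort(params, seed = 5)
  expect_false(identical(c1$landmarks$x_mm, c3$landmarks$x_mm))
  expect_error(cohort_params(n = 0), class = "cvoplan_error_bad_params")
  expect_error(cohort_params(noise_sd = -1), class = "cvoplan_error_bad_params")
  expect_error(cohort_params(dist_A = list(mean = 0, sd = 1, min = 5, max = -5)),
               class = "cvoplan_error_bad_params")
  expect_error(cohort_params(necrosis_extent = c(0.9, 0.2)),
               class = "cvoplan_error_bad_params")
})

test_that("distal-fragment geometry is rigid across stages at zero noise", {
  coh <- noiseless_cohort()
  distal <- c("gt_tip", "gt_lateral", "shaft_axis_1", "shaft_axis_2",
              "arc_1", "arc_2", "arc_3", "arc_4", "arc_5")
  for (h in unique(coh$truth$hip_id)[1:3]) {
    pre <- canonicalize(coh$landmarks[coh$landmarks$hip_id == h &
                                        coh$landmarks$stage == "pre", ])
    post <- canonicalize(coh$landmarks[coh$landmarks$hip_id == h &
                                         coh$landmarks$stage == "post", ])
    Ppre <- cbind(pre$x_mm, pre$y_mm)[match(distal, pre$name), ]
    Ppost <- cbind(post$x_mm, post$y_mm)[match(distal, post$name), ]
    expect_equal(as.vector(dist(Ppre)), as.vector(dist(Ppost)), tolerance = 1e-9)
    # pure translation: all displacement vectors identical
    disp <- Ppost - Ppre
    expect_lt(max(abs(sweep(disp, 2, disp[1, ]))), 1e-9)
  }
})

test_that("written cohorts are byte-identical on re-run and re-readable", {
  params <- cohort_params(n = 2, seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(params), d1)
  write_cohort(simulate_cohort(params), d2)
  for (f in c("landmarks.csv", "truth.csv", "config.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_landmarks(file.path(d1, "landmarks.csv"))
  expect_equal(nrow(back), nrow(simulate_cohort(params)$landmarks))
  cfg <- jsonlite::read_json(file.path(d1, "config.json"))
  expect_equal(cfg$seed, 6)
})

test_that("rater replicates degrade agreement as re-digitization noise grows", {
  coh <- noiseless_cohort(n = 12, seed = 23)
  # post-operative VD varies across hips (it carries the true shortening),
  # so it is a sensible agreement target
  vd_by_rater <- function(reps) {
    reps <- reps[reps$stage == "post", ]
    parts <- split(reps, reps$rater)
    dplyr::bind_rows(lapply(parts, function(d) {
      canon <- canonicalize(d[names(d) != "rater"])
      hips <- split(canon, canon$hip_id)
      out <- dplyr::bind_rows(lapply(hips, measure_vd_ld))
      out$hip_id <- names(hips)
      out$rater <- d$rater[1]
      out
    }))
  }
  reps0 <- rater_replicates(coh$landmarks, sd = 0, k = 2, seed = 1)
  expect_identical(reps0$x_mm[reps0$rater == 1], reps0$x_mm[reps0$rater == 2])
  v0 <- vd_by_rater(reps0)
  expect_equal(icc(v0, hip_id, rater, vd, form = "oneway")$icc, 1)

  mean_icc <- function(sd) {
    mean(vapply(1:8, function(s) {
      v <- vd_by_rater(rater_replicates(coh$landmarks, sd = sd, k = 2, seed = 100 + s))
      icc(v, hip_id, rater, vd, form = "two_way_random_absolute")$icc
    }, numeric(1)))
  }
  i_small <- mean_icc(0.3)
  i_big <- mean_icc(3)
  expect_gt(i_small, i_big)
  expect_gt(i_small, 0.9) # 0.3 mm noise barely dents agreement on ~15 mm spread
  expect_true(i_big < 1 && i_big > -1)
})
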