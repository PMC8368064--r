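test_that("baseline flattening removes drift but preserves pulses", {
  expect_equal(flatten_baseline(rep(5, 50), 3), rep(0, 50))
  ramp <- seq(0, 10, length.out = 50)
  expect_lt(max(abs(flatten_baseline(ramp, 1))), 1e-9 * diff(range(ramp)))
  # cubic drift + planted 20-frame pulse of amplitude 8
  tt <- 1:200
  drift <- 100 + 0.05 * tt - 2e-4 * tt^2
  pulse <- numeric(200)
  pulse[90:109] <- 8 * sin(seq(0, pi, length.out = 20))
  res <- flatten_baseline(drift + pulse, 3)
  expect_lt(abs(max(res[90:109]) / 8 - 1), 0.1)
  expect_error(flatten_baseline(1:4, 3), "exceed")
})

test_that("profile skewness is the population third standardised moment", {
  expect_equal(profile_skewness(c(1, 2, 3)), 0)
  expect_equal(profile_skewness(c(1, 1, 1, 1, 9)), 1.5)
  set.seed(4)
  x <- rnorm(100)^2
  expect_equal(profile_skewness(-x), -profile_skewness(x))
  expect_true(is.na(profile_skewness(rep(2, 10))))
})

test_that("pulse detection finds planted events and stays quiet on noise", {
  # all-zero movie: nothing to find
  zero <- array(0, c(20, 16, 16))
  expect_equal(nrow(detect_pulsing_cells(zero)), 0)

  # small planted movie: high recall and precision
  mv <- generate_calcium_movie(n_frames = 80, shape = c(128, 128),
                               n_cells = 150, pulse_prob = 8e-4, seed = 11)
  ev <- detect_pulsing_cells(mv$stack, pitch_um = 1.1)
  sc <- score_events(ev, mv$truth, dist_tol_um = 10, frame_tol = 1)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)

  # pure-noise movie: false positives within budget, and monotone in the
  # skewness threshold
  set.seed(12)
  noise <- array(rnorm(60 * 64 * 64, 100, 2), c(60, 64, 64))
  fp_low <- nrow(detect_pulsing_cells(noise, skew_threshold = 0.8))
  fp_def <- nrow(detect_pulsing_cells(noise, skew_threshold = 1.0))
  fp_high <- nrow(detect_pulsing_cells(noise, skew_threshold = 1.5))
  expect_lte(fp_def, 2)
  expect_true(fp_low >= fp_def && fp_def >= fp_high)
})

test_that("pulse count series bins events as specified", {
  none <- data.frame(frame = integer())
  expect_equal(pulse_count_series(none, n_frames = 30)$count, rep(0, 5))
  one_per_frame <- data.frame(frame = 1:30)
  expect_equal(pulse_count_series(one_per_frame, n_frames = 30,
                                  bin_frames = 6)$count,
               rep(6, 5))
  # Poisson-planted rate: bin mean close to 6 * lambda
  set.seed(5)
  ev <- data.frame(frame = which(runif(6000) < 0.1))
  bins <- pulse_count_series(ev, n_frames = 6000, bin_frames = 6)
  expect_lt(abs(mean(bins$count) - 0.6), 3 * sqrt(0.6 / nrow(bins)))
})

test_that("ANN statistic equals hand values and the brute-force oracle", {
  expect_equal(ann_frame(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(ann_frame(rbind(c(0, 0), c(1, 0), c(3, 0))), 4 / 3)
  grid <- as.matrix(expand.grid(x = 1:5, y = 1:5))
  expect_equal(ann_frame(grid), 1)
  expect_true(is.na(ann_frame(rbind(c(1, 1)))))

  set.seed(6)
  for (n in c(2, 7, 50, 400)) {
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 60))
    expect_equal(ann_frame(pts), brute_force_ann(pts))
  }
})

test_that("expected and normalised ANN follow the CSR first-order form", {
  expect_equal(expected_ann(1, 4), 1)        # M/S = 0.25
  expect_equal(expected_ann(100, 147.46), 0.60717, tolerance = 1e-4)
  expect_equal(normalized_ann(0.6072, 100, 147.46), 1, tolerance = 1e-3)
  expect_equal(normalized_ann(0, 10, 1), 0)  # coincident points
})

test_that("the normal null parameters evaluate exactly as printed", {
  g <- field_geometry(1, 1)   # S = 1, L = 4
  np <- ann_null_params(100, g)
  expect_equal(np[["mean"]],
               0.5 * sqrt(1 / 100) + 0.051 * 4 / 100 + 0.041 * 4 / 1000)
  expect_equal(np[["mean"]], 0.052204)
  expect_equal(np[["variance"]], 0.070 / 1e4 + 0.037 * sqrt(1e-10))
  expect_equal(np[["variance"]], 7.37e-6)
  # Donnelly variance carries the perimeter factor
  npd <- ann_null_params(100, g, form = "donnelly")
  expect_equal(npd[["variance"]], 0.070 / 1e4 + 0.037 * 4 / 1e5)
  expect_equal(npd[["mean"]], np[["mean"]])
  # edge terms vanish for large n: mean -> 0.5 sqrt(S/n)
  big <- ann_null_params(1e8, g)
  expect_equal(big[["mean"]] / (0.5 * sqrt(1 / 1e8)), 1, tolerance = 1e-3)
})

test_that("information content is the negative log lower-tail probability", {
  g <- field_geometry(1, 1)
  np <- ann_null_params(100, g)
  expect_equal(information_content(np[["mean"]], 100, g), log(2))
  w3 <- np[["mean"]] - 3 * sqrt(np[["variance"]])
  expect_equal(information_content(w3, 100, g), -pnorm(-3, log.p = TRUE))
  expect_equal(information_content(w3, 100, g), 6.6077, tolerance = 1e-4)
  expect_lt(information_content(np[["mean"]] + 20 * sqrt(np[["variance"]]),
                                100, g), 1e-8)
})

test_that("frames with fewer than two points are skipped, never flagged", {
  g <- field_geometry(100, 100)
  pts <- list(rbind(c(1, 1)),                       # M = 1
              matrix(numeric(), ncol = 2),          # M = 0
              rbind(c(10, 10), c(10.5, 10)),        # clustered pair
              generate_csr_points(30, g, seed = 7))
  ann <- ann_series(pts, g)
  expect_equal(ann$m, c(1L, 0L, 2L, 30L))
  expect_true(all(is.na(ann$w_obs[1:2])))
  flagged <- flag_clustered_frames(ann)
  expect_false(any(flagged %in% c(1L, 2L)))
  expect_true(3L %in% flagged)   # a near-coincident pair is non-random
})

test_that("ratio-to-baseline transform reproduces planted dynamics", {
  const <- array(5, c(10, 8, 8))
  expect_equal(ratio_to_baseline_movie(const, 1:4),
               array(1, c(10, 8, 8)))
  mv <- array(10, c(10, 4, 4))
  mv[6:10, 2, 2] <- 20
  rat <- ratio_to_baseline_movie(mv, 1:5)
  expect_equal(rat[8, 2, 2], 2)
  expect_equal(rat[3, 2, 2], 1)
  # zero-baseline pixel is masked
  mv[, 1, 1] <- 0
  expect_warning(rat2 <- ratio_to_baseline_movie(mv, 1:5), "masked")
  expect_true(all(is.na(rat2[, 1, 1])))
  expect_error(ratio_to_baseline_movie(mv, 9:12), "outside")
})
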