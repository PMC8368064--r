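test_that("nuclei segmentation finds disjoint disks exactly", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))), 0)

  img <- matrix(0, 64, 64)
  img <- draw_disk(img, 20, 20, 5.5, 1)
  img <- draw_disk(img, 45, 40, 5.5, 1)
  seg <- segment_nuclei(img, size_min_px = 50, size_max_px = 200)
  expect_equal(nrow(seg), 2)
  seg <- seg[order(seg$y_px), ]
  # centroids at disk centres (0-based) within half a pixel
  expect_lt(abs(seg$x_px[1] - 19), 0.5)
  expect_lt(abs(seg$y_px[1] - 19), 0.5)
  expect_lt(abs(seg$x_px[2] - 39), 0.5)
  expect_lt(abs(seg$y_px[2] - 44), 0.5)
})

test_that("watershed splits touching nuclei connected by a thin bridge", {
  img <- matrix(0, 48, 64)
  img <- draw_disk(img, 24, 20, 6, 1)
  img <- draw_disk(img, 24, 36, 6, 1)
  img[23:26, 20:36] <- 1   # thin bridge surviving the opening
  merged <- segment_nuclei(img, size_min_px = 20, size_max_px = 500,
                           split_touching = FALSE)
  expect_equal(nrow(merged), 1)
  split <- segment_nuclei(img, size_min_px = 20, size_max_px = 500)
  expect_equal(nrow(split), 2)
})

test_that("segmentation count equals the planted count on synthetic scenes", {
  sc <- generate_nuclei_scene(n_cells = 350, shape = c(480, 480),
                              cluster_length_um = 0, blur_sigma_px = 0,
                              phase_fractions = c(G1 = 0.5, S = 0.2,
                                                  G2 = 0.3, M = 0),
                              seed = 21)
  seg <- segment_nuclei(sc$image, size_min_px = 5, size_max_px = 200,
                        pitch_um = 1.1)
  expect_equal(nrow(seg), 350)
  # measured total intensity tracks the planted per-cell intensity
  near <- vapply(seq_len(nrow(seg)), function(i) {
    which.min((sc$cells$x_px - seg$x_px[i])^2 +
              (sc$cells$y_px - seg$y_px[i])^2)
  }, integer(1))
  expect_gt(cor(seg$intensity, sc$cells$intensity[near]), 0.99)
})

test_that("intensity histogram identifies the G1 and G2 peaks", {
  set.seed(22)
  ints <- c(rnorm(2000, 1, 0.08), runif(500, 1, 2), rnorm(1200, 2, 0.16))
  m <- intensity_histogram(ints)
  expect_equal(m$status, "ok")
  expect_equal(m$g1_peak, 1)
  expect_equal(m$g2_peak, 2, tolerance = 0.05)
  expect_equal(m$midpoint, (1 + m$g2_peak) / 2)

  # all-equal intensities: no phase model
  expect_equal(intensity_histogram(rep(3, 100))$status, "unimodal")

  # peak-height ordering follows the G1:G2 mix
  height_at <- function(m, x) {
    stats::approx(m$density$x, m$density$y, xout = x)$y
  }
  mix31 <- c(rnorm(3000, 1, 0.08), rnorm(1000, 2, 0.16))
  mix11 <- c(rnorm(2000, 1, 0.08), rnorm(2000, 2, 0.16))
  m31 <- intensity_histogram(mix31)
  m11 <- intensity_histogram(mix11)
  r31 <- height_at(m31, m31$g1_peak) / height_at(m31, m31$g2_peak)
  r11 <- height_at(m11, m11$g1_peak) / height_at(m11, m11$g2_peak)
  expect_gt(r31, r11)
})

test_that("midpoint classification is deterministic, exhaustive, exclusive", {
  model <- structure(list(status = "ok", g1_peak = 1, g2_peak = 2,
                          midpoint = 1.5, density = NULL,
                          normalized = TRUE),
                     class = "phase_model")
  cells <- data.frame(intensity = c(1.2, 1.8, 1.5, 0.4, 2.6))
  cl <- classify_phase(cells, model)
  expect_equal(cl$phase, c("G1", "G2", "G2", "G1", "G2"))  # tie -> G2
  expect_true(all(cl$phase %in% c("G1", "G2")))
  # M mask wins over intensity
  cl2 <- classify_phase(cells, model, m_ids = c(1, 5))
  expect_equal(cl2$phase[c(1, 5)], c("M", "M"))
  # 4-sigma peak separation: agreement with planted labels >= 97%
  set.seed(23)
  truth <- sample(c("G1", "G2"), 4000, replace = TRUE)
  ints <- ifelse(truth == "G1", rnorm(4000, 1, 0.125), rnorm(4000, 2, 0.125))
  cl3 <- classify_phase(data.frame(intensity = ints), model)
  expect_gte(mean(cl3$phase == truth), 0.97)
  bad <- structure(list(status = "unimodal"), class = "phase_model")
  expect_error(classify_phase(cells, bad), "unavailable")
})

test_that("in-phase rates match the permutation oracle on shuffled labels", {
  set.seed(24)
  n <- 400
  cells <- data.frame(x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                      phase = sample(c("G1", "G2"), n, replace = TRUE,
                                     prob = c(0.6, 0.4)))
  p <- mean(cells$phase == "G1")
  byo <- in_phase_rate_by_order(cells, "G1", k_max = 8, seed = 1)
  expect_true(all(byo$rate >= 0 & byo$rate <= 1))
  expect_true(all(abs(byo$rate - p) <= 3 * pmax(byo$se, 0.02)))
  byr <- in_phase_rate_by_radius(cells, "G1", c(30, 60, 120, 240), seed = 1)
  expect_true(all(abs(byr$rate - p) <= 3 * pmax(byr$se, 0.02)))

  # single label: rate identically one
  cells$phase <- "G1"
  expect_equal(in_phase_rate_by_order(cells, "G1", k_max = 5,
                                      seed = 1)$rate, rep(1, 5))
  expect_equal(in_phase_rate_by_radius(cells, "G1", c(50, 100),
                                       seed = 1)$rate, rep(1, 2))
})

test_that("correlated labels raise the near-order rate, decaying to the
           group fraction", {
  sc <- generate_nuclei_scene(n_cells = 2000, shape = c(600, 600),
                              cluster_length_um = 60, blur_sigma_px = 0,
                              seed = 25)
  cells <- sc$cells
  model <- intensity_histogram(cells$intensity[cells$phase != "M"])
  cl <- classify_phase(cells, model, m_ids = which(cells$phase == "M"))
  p <- mean(cl$phase[cl$phase != "M"] == "G1")
  byo <- in_phase_rate_by_order(cl, "G1", k_max = 60, seed = 1)
  expect_gt(byo$rate[1], p + 5 * byo$se[1])
  # distal orders approach the group fraction
  expect_lt(mean(byo$rate[55:60]), (byo$rate[1] + p) / 2)
})

test_that("exponential cluster-length fit inverts noiseless curves", {
  r <- seq(5, 150, by = 5)
  y <- 0.5 + 0.3 * exp(-r / 60)
  fit <- cluster_length_fit(y, radii = r)
  expect_equal(fit$status, "ok")
  expect_equal(fit$length_um, 60, tolerance = 1e-6)
  expect_equal(fit$p_inf, 0.5, tolerance = 1e-6)
  fit2 <- cluster_length_fit(y, radii = r, asymptote = 0.5)
  expect_equal(fit2$length_um, 60, tolerance = 1e-6)
  expect_equal(cluster_length_fit(rep(0.4, 10), radii = 1:10)$status,
               "failed")
  expect_error(cluster_length_fit(c(1, 0.5), radii = c(1, 2)), "4 radii")
})
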