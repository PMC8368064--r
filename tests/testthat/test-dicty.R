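test_that("ratio image is defined only where both channels pass threshold", {
  red <- matrix(100, 8, 8)
  green <- matrix(100, 8, 8)
  expect_equal(ratio_image(red, green), matrix(1, 8, 8))
  green[3, 3] <- 4
  rt <- ratio_image(red, green, red_min = 10, green_min = 10)
  expect_true(is.na(rt[3, 3]))
  expect_equal(rt[1, 1], 1)
  # a pulse that halves green doubles the ratio
  green2 <- matrix(100, 8, 8); green2[5, 5] <- 50
  expect_equal(ratio_image(red, green2)[5, 5], 2)
  expect_error(ratio_image(matrix(1, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("active-particle detection applies the ratio and size filters", {
  rt <- matrix(1, 64, 64)
  expect_equal(nrow(detect_active_particles(rt, 1.3)), 0)
  rt <- draw_disk(rt, 30, 40, 3.1, 1)   # ~30 px at ratio 2
  parts <- detect_active_particles(rt, 1.3, min_size_px = 10, frame = 7L)
  expect_equal(nrow(parts), 1)
  expect_equal(parts$frame, 7L)
  expect_lt(abs(parts$x_px - 39), 1)
  expect_lt(abs(parts$y_px - 29), 1)
  # a 5-px speck falls below min_size
  rt2 <- matrix(1, 64, 64); rt2[10, 10:14] <- 2
  expect_equal(nrow(detect_active_particles(rt2, 1.3, min_size_px = 10)), 0)
})

test_that("linking respects the maximum per-frame displacement", {
  walk <- function(step_um, n = 5, pitch = 1.1) {
    data.frame(frame = 1:n, x_px = (0:(n - 1)) * step_um / pitch,
               y_px = 0)
  }
  under <- link_particles(walk(16), max_disp_um = 16.5)
  expect_equal(length(unique(under$track_id)), 1)
  over <- link_particles(walk(17), max_disp_um = 16.5)
  expect_equal(length(unique(over$track_id)), 5)

  # two far-apart cells keep their identities across frames
  a <- data.frame(frame = rep(1:4, each = 2),
                  x_px = rep(c(10, 100), 4) + rep(0:3, each = 2) * 2,
                  y_px = rep(c(10, 100), 4))
  lk <- link_particles(a, max_disp_um = 16.5, pitch_um = 1.1)
  expect_equal(length(unique(lk$track_id)), 2)
  expect_equal(length(unique(lk$track_id[lk$y_px == 10])), 1)
})

test_that("single-frame candidates are screened out", {
  parts <- data.frame(frame = c(1L, 3L, 4L, 4L),
                      x_px = c(5, 50, 50, 80), y_px = c(5, 50, 51, 80))
  tracks <- link_particles(parts, max_disp_um = 16.5, pitch_um = 1.1)
  ev <- screen_single_frame(tracks, pitch_um = 1.1)
  # only the 2-frame track at (50, 50) survives; events sit at its onset
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 3L)
  expect_equal(ev$track_len, 2L)
  expect_equal(ev$x_um, 50 * 1.1)
})

test_that("tree links obey the square-root-lag reach rule", {
  ev <- data.frame(event_id = 1:5,
                   frame = c(1L, 2L, 3L, 5L, 2L),
                   x_um = c(0, 200, 350, 100, 600),
                   y_um = 0)
  links <- build_tree(ev, dprime_um = 250, fmax = 3)
  key <- paste(links$parent, links$child)
  expect_true("1 2" %in% key)        # lag 1, 200 um <= 250
  expect_true("1 3" %in% key)        # lag 2, 350 um <= sqrt(2)*250 = 353.6
  expect_false("1 4" %in% key)       # lag 4 > fmax
  expect_false("1 5" %in% key)       # lag 1, 600 um > 250
  # no link ever exceeds the maximum reach
  expect_true(all(links$dist_um <= sqrt(links$lag) * 250 + 1e-9))
  expect_true(all(links$lag >= 1 & links$lag <= 3))
})

test_that("primary parents form a deterministic forest", {
  # child 3 reachable from both 1 (lag 2) and 2 (lag 1): lag decides
  ev <- data.frame(event_id = 1:3, frame = c(1L, 2L, 3L),
                   x_um = c(0, 50, 100), y_um = 0)
  links <- build_tree(ev, dprime_um = 250, fmax = 3)
  prim3 <- links[links$child == 3 & links$primary, ]
  expect_equal(prim3$parent, 2)
  expect_equal(nrow(links[links$child == 3, ]), 2)   # both candidates kept

  # equal lag: smaller distance wins
  ev2 <- data.frame(event_id = 1:3, frame = c(1L, 1L, 2L),
                    x_um = c(0, 120, 100), y_um = 0)
  links2 <- build_tree(ev2, dprime_um = 250, fmax = 3)
  expect_equal(links2$parent[links2$child == 3 & links2$primary], 2)

  # property: on random event sets, each child has exactly one primary
  # parent and primary links never point forward in time
  set.seed(31)
  for (i in 1:5) {
    n <- 40
    evr <- data.frame(event_id = 1:n,
                      frame = sort(sample.int(12, n, replace = TRUE)),
                      x_um = runif(n, 0, 800), y_um = runif(n, 0, 800))
    lk <- build_tree(evr, dprime_um = 250, fmax = 3)
    if (nrow(lk) == 0) next
    prim <- lk[lk$primary, ]
    expect_false(any(duplicated(prim$child)))
    f <- evr$frame[match(prim$parent, evr$event_id)]
    expect_true(all(f < evr$frame[match(prim$child, evr$event_id)]))
  }
})

test_that("wave origins are parentless events with at least one child", {
  # isolated event: no origin
  ev <- data.frame(event_id = 1L, frame = 1L, x_um = 0, y_um = 0)
  expect_equal(nrow(find_wave_origins(ev, build_tree(ev))), 0)
  # two independent planted cascades: exactly two origins
  mk <- function(x0, t0, id0) {
    data.frame(event_id = id0 + 0:3, frame = t0 + c(0L, 1L, 2L, 3L),
               x_um = x0 + c(0, 100, 200, 300), y_um = 0)
  }
  ev2 <- rbind(mk(0, 1, 1), mk(5000, 1, 11))
  links <- build_tree(ev2, dprime_um = 250, fmax = 3)
  org <- find_wave_origins(ev2, links)
  expect_equal(sort(org$event_id), c(1L, 11L))
})

test_that("quadrat counting scales a compartment count to the field", {
  expect_equal(quadrat_estimate(57, 10, 10), 57)
  expect_equal(quadrat_estimate(100, 1, 147.46), 14746)
  # uniform synthetic scene: estimate within the binomial interval
  g <- field_geometry(1000, 1000)
  pts <- generate_csr_points(5000, g, seed = 32)
  q <- sum(pts[, "x"] < 250 & pts[, "y"] < 250)
  est <- quadrat_estimate(q, 250 * 250, g$area)
  p <- (250 * 250) / g$area
  ci <- qbinom(c(0.0005, 0.9995), 5000, p) / p
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("dual-channel detection recovers planted pulses end to end", {
  mv <- generate_dicty_movie(n_frames = 30, shape = c(256, 256),
                             n_cells = 120, motility_sd_um = 1,
                             pulse_prob = 2e-3, seed = 33)
  parts <- detect_particles_stack(mv$red, mv$green, red_min = 10,
                                  green_min = 10, ratio_threshold = 1.3,
                                  min_size_px = 10)
  ev <- screen_single_frame(link_particles(parts))
  sc <- score_events(ev, mv$truth$pulses, dist_tol_um = 8, frame_tol = 0)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})
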