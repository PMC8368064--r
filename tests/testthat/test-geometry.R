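test_that("optical geometry arithmetic matches independent re-derivation", {
  cfg <- optical_config(29.2, 20.2, 2.2, 2, numerical_aperture = 0.12,
                        wavelength_nm = 520)
  expect_equal(sample_pixel_pitch(cfg), 1.1)
  d <- fov_dimensions(cfg)
  expect_equal(unname(d), c(29.2 / 2, 20.2 / 2, sqrt(14.6^2 + 10.1^2)))
  expect_equal(unname(fov_dimensions(cfg, display = TRUE)),
               c(14.6, 10.1, 17.8))

  # identity and sCMOS-style configurations
  expect_equal(sample_pixel_pitch(optical_config(10, 10, 1, 1)), 1)
  expect_equal(sample_pixel_pitch(optical_config(13.3, 13.3, 6.5, 5)), 1.3)
  expect_equal(unname(fov_dimensions(optical_config(10, 10, 1, 1))),
               c(10, 10, sqrt(200)))
  expect_equal(fov_dimensions(optical_config(29.2, 20.2, 2.2, 1))[["diagonal_mm"]],
               35.5063, tolerance = 1e-4)

  # property: random configs against plain division, 0-based re-derivation
  set.seed(1)
  for (i in 1:25) {
    w <- runif(1, 5, 40); h <- runif(1, 5, 40)
    px <- runif(1, 1, 10); mag <- runif(1, 0.5, 10)
    cfg_i <- optical_config(w, h, px, mag)
    expect_equal(sample_pixel_pitch(cfg_i), px / mag)
    expect_equal(unname(fov_dimensions(cfg_i)),
                 c(w / mag, h / mag, sqrt(w^2 + h^2) / mag))
  }
})

test_that("invalid optical configurations are rejected", {
  expect_error(optical_config(-1, 20, 2.2, 2), "strictly positive")
  expect_error(optical_config(29, 20, 2.2, 0), "strictly positive")
  expect_error(optical_config(29, 20, 2.2, 2, numerical_aperture = 1.2),
               "numerical_aperture")
  expect_error(half_angular_aperture_deg(1), "na must satisfy")
  expect_error(field_geometry(0, 1), "strictly positive")
})

test_that("angular aperture and diffraction-limited FWHM evaluate correctly", {
  expect_equal(half_angular_aperture_deg(0.12), asin(0.12) * 180 / pi)
  expect_lt(abs(half_angular_aperture_deg(0.12) - 7), 0.2)
  expect_equal(half_angular_aperture_deg(0.5), 30)
  expect_equal(half_angular_aperture_deg(0.9), 64.158, tolerance = 1e-4)
  expect_equal(theoretical_lateral_fwhm(520, 0.12), 2.21)
  expect_equal(theoretical_lateral_fwhm(510, 0.12), 2.1675)
  # cancellation: lambda = 1000 nm (1 um), NA = 0.51
  expect_equal(theoretical_lateral_fwhm(1000, 0.51), 1)
})

test_that("cell capacity and area conversion are exact arithmetic", {
  fov_um <- field_geometry(14.6e3, 10.1e3)
  expect_equal(cell_capacity(fov_um, 10, 10), 1474600)
  expect_gte(cell_capacity(fov_um, 10, 10), 1e6)
  expect_equal(cell_capacity(field_geometry(1000, 1000), 10, 10), 1e4)
  expect_equal(cell_capacity(fov_um, 100, 100), 14746)
  expect_equal(area_um2_to_pixels(123.8, 1.1), 102.31, tolerance = 1e-4)
  expect_equal(area_um2_to_pixels(1.21, 1.1), 1)
  expect_equal(area_um2_to_pixels(100, 1), 100)
  # property: floor-tiling against a counting loop
  set.seed(2)
  for (i in 1:10) {
    w <- runif(1, 10, 100); h <- runif(1, 10, 100); cw <- runif(1, 1, 9)
    expect_equal(cell_capacity(field_geometry(w, h), cw, cw),
                 length(seq(cw, w, by = cw)) * length(seq(cw, h, by = cw)))
  }
})

test_that("field geometry derives area and perimeter", {
  g <- field_geometry(14.6, 10.1)
  expect_equal(g$area, 14.6 * 10.1)
  expect_equal(g$perimeter, 2 * (14.6 + 10.1))
})

test_that("flat-field correction recovers a uniform sample", {
  ref <- matrix(runif(100, 0.5, 1.5), 10, 10)
  # self-division: raw = reference gives a constant image at mean(reference)
  corr <- flatfield_correct(ref, ref)
  expect_equal(max(corr) - min(corr), 0, tolerance = 1e-12)
  expect_equal(corr[1, 1], mean(ref))

  # uniform raw under a vignetted reference: inverse-vignette image
  vign <- matrix(1, 8, 8); vign[1, 1] <- 0.5
  raw <- matrix(3, 8, 8)
  corr2 <- flatfield_correct(raw, vign)
  expect_equal(min(corr2) / max(corr2), 0.5, tolerance = 1e-12)

  # synthetic truth x illumination (0.8) x lens (0.7): uncorrected < 0.6
  ff <- generate_flatfield_pair(truth = 100, illum_minmax = 0.8,
                                lens_corner_center = 0.7, seed = 1)
  expect_lte(min(ff$raw) / max(ff$raw), 0.6)
  rec <- flatfield_correct(ff$raw, ff$reference)
  expect_gte(min(rec) / max(rec), 0.98)

  # idempotence up to normalisation: uniform reference changes nothing
  again <- flatfield_correct(rec, matrix(7, nrow(rec), ncol(rec)))
  expect_equal(again, rec)
})

test_that("non-positive reference pixels are masked with a warning", {
  ref <- matrix(1, 4, 4); ref[2, 2] <- 0
  expect_warning(corr <- flatfield_correct(matrix(1, 4, 4), ref), "masked")
  expect_true(is.na(corr[2, 2]))
  expect_true(all(is.finite(corr[-6])))
  expect_error(flatfield_correct(matrix(1, 3, 3), matrix(1, 4, 4)),
               "equal")
})

test_that("Gaussian FWHM fit recovers 2*sqrt(2 log 2)*sigma", {
  x <- 0:100
  prof <- 5 + 10 * exp(-(x - 48.3)^2 / (2 * 10^2))
  fit <- gaussian_fwhm(prof, spacing = 1)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 1e-6)
  expect_equal(fit$center, 48.3, tolerance = 1e-6)

  # physical units: sigma 0.955 um sampled at 0.1 um
  xs <- seq(0, 10, by = 0.1)
  prof2 <- exp(-(xs - 5)^2 / (2 * 0.955^2))
  expect_equal(gaussian_fwhm(prof2, spacing = 0.1)$fwhm, 2.249,
               tolerance = 1e-3)

  # 5% noise, 50 replicates: mean FWHM within 2% of truth
  set.seed(3)
  fw <- replicate(50, {
    noisy <- prof + rnorm(length(prof), 0, 0.5)
    gaussian_fwhm(noisy)$fwhm
  })
  expect_lt(abs(mean(fw) / (2 * sqrt(2 * log(2)) * 10) - 1), 0.02)

  expect_error(gaussian_fwhm(rep(1, 20)), "no peak")
  expect_error(gaussian_fwhm(c(1, 2, 1)), "at least 5")
})
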