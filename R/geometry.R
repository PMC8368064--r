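#' Optical configuration of a wide-field imaging system
#'
#' Bundles the sensor and lens parameters from which all micrometre/pixel
#' conversions are derived. The object-side sample pitch is
#' `sensor_pixel_um / magnification`.
#'
#' @param sensor_width_mm,sensor_height_mm Physical sensor dimensions (mm).
#' @param sensor_pixel_um Sensor pixel size (um).
#' @param magnification Lens magnification (dimensionless, > 0).
#' @param numerical_aperture Object-side numerical aperture (0 < NA < 1),
#'   optional.
#' @param wavelength_nm Emission wavelength (nm), optional.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(29.2, 20.2, 2.2, 2, numerical_aperture = 0.12,
#'                       wavelength_nm = 520)
#' sample_pixel_pitch(cfg)  # 1.1 um/px
#' @export
optical_config <- function(sensor_width_mm, sensor_height_mm, sensor_pixel_um,
                           magnification, numerical_aperture = NA_real_,
                           wavelength_nm = NA_real_) {
  vals <- c(sensor_width_mm, sensor_height_mm, sensor_pixel_um, magnification)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid optical config: sensor dimensions, pixel size and ",
         "magnification must be strictly positive", call. = FALSE)
  if (!is.na(numerical_aperture) &&
      (numerical_aperture <= 0 || numerical_aperture >= 1))
    stop("invalid optical config: numerical_aperture must be in (0, 1)",
         call. = FALSE)
  if (!is.na(wavelength_nm) && wavelength_nm <= 0)
    stop("invalid optical config: wavelength_nm must be positive",
         call. = FALSE)
  structure(list(sensor_width_mm = sensor_width_mm,
                 sensor_height_mm = sensor_height_mm,
                 sensor_pixel_um = sensor_pixel_um,
                 magnification = magnification,
                 numerical_aperture = numerical_aperture,
                 wavelength_nm = wavelength_nm),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  sensor: %.1f x %.1f mm, pixel %.2f um\n",
              x$sensor_width_mm, x$sensor_height_mm, x$sensor_pixel_um))
  cat(sprintf("  magnification: %gx  (sample pitch %.3f um/px)\n",
              x$magnification, sample_pixel_pitch(x)))
  if (!is.na(x$numerical_aperture))
    cat(sprintf("  NA: %.3f", x$numerical_aperture))
  if (!is.na(x$wavelength_nm))
    cat(sprintf("  wavelength: %g nm", x$wavelength_nm))
  cat("\n")
  invisible(x)
}

#' Sample-plane pixel pitch
#'
#' @param cfg An [optical_config()].
#' @return Pixel pitch at the sample plane, in um per pixel.
#' @export
sample_pixel_pitch <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  cfg$sensor_pixel_um / cfg$magnification
}

#' Field-of-view dimensions at the sample plane
#'
#' @param cfg An [optical_config()].
#' @param display If `TRUE`, round to 0.1 mm for display; stored values keep
#'   full precision.
#' @return Named numeric vector `c(width_mm, height_mm, diagonal_mm)`.
#' @export
fov_dimensions <- function(cfg, display = FALSE) {
  stopifnot(inherits(cfg, "optical_config"))
  w <- cfg$sensor_width_mm / cfg$magnification
  h <- cfg$sensor_height_mm / cfg$magnification
  d <- sqrt(w^2 + h^2)
  out <- c(width_mm = w, height_mm = h, diagonal_mm = d)
  if (display) round(out, 1) else out
}

#' Rectangular field geometry
#'
#' Width and height are unit-agnostic; area and perimeter are derived in the
#' same unit. Used both for the full field of view (mm) and for analysis
#' windows (um).
#'
#' @param width,height Rectangle dimensions (> 0), any consistent length unit.
#' @return An object of class `field_geometry` with `width`, `height`,
#'   `area` (`S`) and `perimeter` (`L`).
#' @export
field_geometry <- function(width, height) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("field_geometry: width and height must be strictly positive",
         call. = FALSE)
  structure(list(width = width, height = height,
                 area = width * height,
                 perimeter = 2 * (width + height)),
            class = "field_geometry")
}

#' Half angular aperture of a lens
#'
#' @param na Object-side numerical aperture, 0 < na < 1.
#' @return Half-acceptance angle `asin(na)` in degrees.
#' @export
half_angular_aperture_deg <- function(na) {
  if (!is.finite(na) || na <= 0 || na >= 1)
    stop("half_angular_aperture_deg: na must satisfy 0 < na < 1",
         call. = FALSE)
  asin(na) * 180 / pi
}

#' Theoretical lateral resolution as Gaussian FWHM
#'
#' Diffraction-limited lateral full width at half maximum, `0.51 * lambda / NA`.
#'
#' @param wavelength_nm Emission wavelength in nm.
#' @param na Numerical aperture.
#' @return FWHM in um.
#' @export
theoretical_lateral_fwhm <- function(wavelength_nm, na) {
  stopifnot(wavelength_nm > 0, na > 0)
  0.51 * (wavelength_nm * 1e-3) / na
}

#' Cell capacity of a rectangular field
#'
#' Number of rectangular cell footprints tiling the field,
#' `floor(width/cell_w) * floor(height/cell_h)`. All lengths must share one
#' unit.
#'
#' @param fov A [field_geometry()].
#' @param cell_w,cell_h Cell footprint dimensions (> 0).
#' @return Integer-valued count.
#' @export
cell_capacity <- function(fov, cell_w, cell_h) {
  stopifnot(inherits(fov, "field_geometry"), cell_w > 0, cell_h > 0)
  floor(fov$width / cell_w) * floor(fov$height / cell_h)
}

#' Convert an area in um^2 to a pixel count
#'
#' @param area_um2 Area in um^2.
#' @param pitch_um Pixel pitch in um/px.
#' @return Equivalent number of pixels (`area / pitch^2`).
#' @export
area_um2_to_pixels <- function(area_um2, pitch_um) {
  stopifnot(pitch_um > 0)
  area_um2 / pitch_um^2
}

#' Flat-field (shading) correction
#'
#' Divides a raw image by a reference image of a uniform fluorescent plate,
#' normalised by its mean so that corrected intensities keep the raw scale.
#' Compensates both illumination non-uniformity and position-dependent lens
#' throughput. Non-positive reference pixels are masked to `NA` with a
#' warning.
#'
#' @param raw 2-D numeric matrix, the raw image.
#' @param reference 2-D numeric matrix, same shape, reference image of a
#'   uniform sample.
#' @return Corrected image, same shape as `raw`.
#' @export
flatfield_correct <- function(raw, reference) {
  if (!is.matrix(raw) || !is.matrix(reference) ||
      !all(dim(raw) == dim(reference)))
    stop("flatfield_correct: raw and reference must be matrices of equal ",
         "shape", call. = FALSE)
  bad <- !is.finite(reference) | reference <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive reference pixel(s) masked to NA")
    reference[bad] <- NA_real_
  }
  gain <- reference / mean(reference, na.rm = TRUE)
  raw / gain
}

#' Gaussian FWHM of a one-dimensional intensity profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to a sampled profile with a single dominant peak (a bead image line
#' profile, for instance). The full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma`, returned in the physical unit implied by
#' `spacing`.
#'
#' Initialisation is deterministic: `center` at the argmax, `sigma` from the
#' second moment of the background-subtracted profile, `offset` at the
#' profile minimum.
#'
#' @param profile Numeric vector of sampled intensities (length >= 5).
#' @param spacing Sample spacing in physical units (default 1, i.e. pixels).
#' @return A list of class `gaussian_fwhm_fit` with elements `fwhm`, `sigma`,
#'   `center`, `amplitude`, `offset`, `residuals` and `fitted`.
#' @export
gaussian_fwhm <- function(profile, spacing = 1) {
  profile <- as.numeric(profile)
  if (length(profile) < 5)
    stop("gaussian_fwhm: need at least 5 samples", call. = FALSE)
  stopifnot(spacing > 0)
  x <- (seq_along(profile) - 1) * spacing
  off0 <- min(profile)
  amp0 <- max(profile) - off0
  if (amp0 <= 0)
    stop("gaussian_fwhm: profile has no peak", call. = FALSE)
  ctr0 <- x[which.max(profile)]
  wts <- pmax(profile - off0, 0)
  sig0 <- sqrt(sum(wts * (x - sum(wts * x) / sum(wts))^2) / sum(wts))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- spacing
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ off + amp * exp(-(x - ctr)^2 / (2 * sig^2)),
      data = data.frame(x = x, y = profile),
      start = list(off = off0, amp = amp0, ctr = ctr0, sig = sig0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("gaussian_fwhm: fit did not converge (", conditionMessage(fit),
         "); residual sd of initial guess ",
         signif(stats::sd(profile - (off0 + amp0 *
           exp(-(x - ctr0)^2 / (2 * sig0^2)))), 4), call. = FALSE)
  cf <- stats::coef(fit)
  sigma <- abs(unname(cf["sig"]))
  structure(list(fwhm = 2 * sqrt(2 * log(2)) * sigma,
                 sigma = sigma,
                 center = unname(cf["ctr"]),
                 amplitude = unname(cf["amp"]),
                 offset = unname(cf["off"]),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit)),
            class = "gaussian_fwhm_fit")
}
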