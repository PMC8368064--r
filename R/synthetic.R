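# Synthetic scene and movie generators. Each generator is seed-deterministic
# and returns the rendered image data together with a ground-truth table in
# the same schema the corresponding detector emits, so recovered events can
# be scored directly against planted ones.

# Non-overlapping random centers via grid-hashed rejection sampling.
# Returns an n x 2 matrix of (x, y) pixel coordinates (0-based, continuous).
place_centers <- function(n, ny, nx, min_dist, margin = 0, max_tries = 200L) {
  if (n == 0) return(matrix(numeric(), ncol = 2))
  cell <- max(min_dist, 1)
  gx <- max(1L, ceiling((nx - 2 * margin) / cell))
  gy <- max(1L, ceiling((ny - 2 * margin) / cell))
  grid <- vector("list", gx * gy)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  total_cap <- max_tries * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > total_cap)
      stop("place_centers: packing failure, density too high for min_dist = ",
           min_dist, call. = FALSE)
    x <- stats::runif(1, margin, nx - margin)
    y <- stats::runif(1, margin, ny - margin)
    ix <- min(gx, 1L + floor((x - margin) / cell))
    iy <- min(gy, 1L + floor((y - margin) / cell))
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > gx || jy < 1 || jy > gy) next
      for (idx in grid[[(jx - 1L) * gy + jy]]) {
        if ((pts[idx, 1] - x)^2 + (pts[idx, 2] - y)^2 < min_dist^2) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    pts[placed, ] <- c(x, y)
    key <- (ix - 1L) * gy + iy
    grid[[key]] <- c(grid[[key]], placed)
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Integer pixel offsets (dy, dx) of a filled disk of radius r.
disk_offsets <- function(r) {
  s <- -ceiling(r):ceiling(r)
  g <- expand.grid(dy = s, dx = s)
  as.matrix(g[g$dy^2 + g$dx^2 <= r^2, ])
}

# Add `value` to the disk footprint centred at (y0, x0) (1-based indices)
# in matrix img, clipping at the borders.
add_disk <- function(img, y0, x0, offs, value) {
  yy <- round(y0) + offs[, "dy"]
  xx <- round(x0) + offs[, "dx"]
  ok <- yy >= 1 & yy <= nrow(img) & xx >= 1 & xx <= ncol(img)
  img[cbind(yy[ok], xx[ok])] <- img[cbind(yy[ok], xx[ok])] + value
  img
}

#' Uniform random points in a rectangle (complete spatial randomness)
#'
#' The null model of the ANN spatial-randomness test: `n` points placed
#' independently and uniformly in the window.
#'
#' @param n Number of points (>= 0).
#' @param geom A [field_geometry()] giving the window.
#' @param seed Optional integer seed.
#' @return `n x 2` matrix of (x, y) coordinates in the window's unit.
#' @export
generate_csr_points <- function(n, geom, seed = NULL) {
  stopifnot(inherits(geom, "field_geometry"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(matrix(numeric(), ncol = 2,
                            dimnames = list(NULL, c("x", "y"))))
  cbind(x = stats::runif(n, 0, geom$width),
        y = stats::runif(n, 0, geom$height))
}

# Maps the requested phase-cluster length (the exponential decay length of
# the in-phase rate curve, um) to the range parameter of the label field in
# pixels. The affine form absorbs the discreteness of the cell lattice
# (nearest centres sit ~10 um apart, which offsets the fitted decay);
# slope and offset were calibrated once by simulating the generator +
# classification + rate-curve + exponential-fit loop at two scales.
phase_field_range_px <- function(cluster_length_um, pitch_um) {
  max(2, 0.74 * cluster_length_um / pitch_um - 5)
}

# Stationary Gaussian random field with exponential (Matern nu = 1/2)
# autocorrelation exp(-r / range_px), generated spectrally: white noise
# filtered in Fourier space by the square root of the Matern spectral
# density (1 + (k * range)^2)^(-3/2). Periodic boundary; unit variance.
exp_corr_field <- function(ny, nx, range_px) {
  fy <- c(seq(0, floor(ny / 2)), seq(-ceiling(ny / 2) + 1, -1)) / ny
  fx <- c(seq(0, floor(nx / 2)), seq(-ceiling(nx / 2) + 1, -1)) / nx
  k2 <- outer((2 * pi * fy)^2, (2 * pi * fx)^2, `+`)
  filt <- (1 + k2 * range_px^2)^(-0.75)
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  f <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE))
  (f - mean(f)) / stats::sd(f)
}

#' Synthetic nuclei scene with cell-cycle phase structure
#'
#' Renders non-overlapping disk nuclei at random positions. Per-cell total
#' intensity follows a bimodal DNA-content distribution (G2 peak at twice
#' the G1 peak, S phase spread between them). Phase labels are spatially
#' correlated: a spectrally filtered white-noise field with exponential
#' autocorrelation is sampled at the cell centres and thresholded at
#' quantiles matching the phase fractions, giving in-phase clusters whose
#' fitted exponential length matches `cluster_length_um`. M-phase cells are
#' drawn as a split pair of condensed
#' half-nuclei and labelled in the truth table.
#'
#' @param n_cells Number of nuclei.
#' @param shape Image shape `c(ny, nx)` in pixels.
#' @param pitch_um Pixel pitch (um/px).
#' @param phase_fractions Named fractions for `G1`, `S`, `G2`, `M`
#'   (must sum to 1).
#' @param cluster_length_um Spatial correlation length of the phase labels
#'   (um); 0 gives independent labels.
#' @param peak_intensities Length-2 vector, G1 and G2 total-intensity peaks.
#' @param intensity_cv Coefficient of variation within the G1 and G2 peaks.
#' @param nucleus_radius_px Nucleus disk radius in pixels.
#' @param blur_sigma_px Gaussian blur applied to the rendered image
#'   (0 = none).
#' @param read_noise_sd Additive Gaussian noise sd (0 = none).
#' @param seed Optional integer seed.
#' @return List with `image` (matrix, rows = y), `cells` (data frame:
#'   `id`, `x_px`, `y_px`, `x_um`, `y_um`, `phase`, `intensity`,
#'   `area_px`) and `params`.
#' @export
generate_nuclei_scene <- function(n_cells = 1500, shape = c(512, 512),
                                  pitch_um = 1.1,
                                  phase_fractions = c(G1 = 0.5, S = 0.15,
                                                      G2 = 0.3, M = 0.05),
                                  cluster_length_um = 60,
                                  peak_intensities = c(1, 2),
                                  intensity_cv = 0.08,
                                  nucleus_radius_px = 3,
                                  blur_sigma_px = 1,
                                  read_noise_sd = 0,
                                  seed = NULL) {
  stopifnot(abs(sum(phase_fractions) - 1) < 1e-8, cluster_length_um >= 0)
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  r <- nucleus_radius_px
  centers <- place_centers(n_cells, ny, nx,
                           min_dist = 2 * r + 3, margin = r + 2)

  # spatially correlated phase labels from a thresholded correlated field
  if (cluster_length_um > 0) {
    range_px <- phase_field_range_px(cluster_length_um, pitch_um)
    field <- exp_corr_field(ny, nx, range_px)
    vals <- field[cbind(pmin(pmax(round(centers[, "y"]), 1), ny),
                        pmin(pmax(round(centers[, "x"]), 1), nx))]
  } else {
    vals <- stats::rnorm(n_cells)
  }
  # M cells are a random subset (mitosis is not spatially clustered here);
  # interphase cells split G1 | S | G2 along the field quantiles.
  n_m <- round(n_cells * phase_fractions[["M"]])
  m_idx <- sample.int(n_cells, n_m)
  phase <- rep(NA_character_, n_cells)
  phase[m_idx] <- "M"
  inter <- setdiff(seq_len(n_cells), m_idx)
  fr <- phase_fractions[c("G1", "S", "G2")]
  fr <- fr / sum(fr)
  ord <- inter[order(vals[inter])]
  n1 <- round(length(inter) * fr[["G1"]])
  n2 <- round(length(inter) * fr[["S"]])
  phase[ord[seq_len(n1)]] <- "G1"
  phase[ord[n1 + seq_len(n2)]] <- "S"
  phase[ord[(n1 + n2 + 1):length(ord)]] <- "G2"

  p1 <- peak_intensities[1]; p2 <- peak_intensities[2]
  intensity <- numeric(n_cells)
  intensity[phase == "G1"] <- stats::rnorm(sum(phase == "G1"), p1,
                                           intensity_cv * p1)
  intensity[phase == "S"] <- stats::runif(sum(phase == "S"), p1, p2)
  intensity[phase == "G2"] <- stats::rnorm(sum(phase == "G2"), p2,
                                           intensity_cv * p2)
  intensity[phase == "M"] <- stats::rnorm(sum(phase == "M"), p2,
                                          intensity_cv * p2)
  intensity <- pmax(intensity, 0.05 * p1)

  offs <- disk_offsets(r)
  offs_m <- disk_offsets(max(1, r - 1.5))
  img <- matrix(0, ny, nx)
  for (i in seq_len(n_cells)) {
    if (phase[i] == "M") {
      # split/condensed morphology: two compact half-intensity lobes
      per_px <- intensity[i] / (2 * nrow(offs_m))
      img <- add_disk(img, centers[i, "y"], centers[i, "x"] - r + 0.5,
                      offs_m, per_px)
      img <- add_disk(img, centers[i, "y"], centers[i, "x"] + r - 0.5,
                      offs_m, per_px)
    } else {
      img <- add_disk(img, centers[i, "y"], centers[i, "x"], offs,
                      intensity[i] / nrow(offs))
    }
  }
  if (blur_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma_px))
  if (read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(ny * nx, 0, read_noise_sd), ny, nx)

  cells <- data.frame(id = seq_len(n_cells),
                      x_px = centers[, "x"], y_px = centers[, "y"],
                      x_um = centers[, "x"] * pitch_um,
                      y_um = centers[, "y"] * pitch_um,
                      phase = phase, intensity = intensity,
                      area_px = ifelse(phase == "M", 2 * nrow(offs_m),
                                       nrow(offs)))
  list(image = img, cells = cells,
       params = list(n_cells = n_cells, shape = shape, pitch_um = pitch_um,
                     phase_fractions = phase_fractions,
                     cluster_length_um = cluster_length_um,
                     peak_intensities = peak_intensities,
                     nucleus_radius_px = nucleus_radius_px, seed = seed))
}

#' Synthetic single-channel calcium movie with planted rare pulses
#'
#' Renders static cell footprints with a constant baseline plus a global
#' polynomial drift, and plants two kinds of transient pulses on top:
#' isolated pulses, occurring independently per cell and frame at the rare
#' rate `pulse_prob`, and optional propagation clusters in which a trigger
#' cell pulses and its nearest neighbours within `cluster_radius_um` pulse
#' at increasing frame lags (up to 3 cells per lag step). Gaussian read
#' noise and an optional signal-proportional (shot-like) variance term are
#' added last. Pulse amplitude defaults to 10x the read noise.
#'
#' @param n_frames,shape,n_cells Movie geometry and cell count.
#' @param pitch_um Pixel pitch (um/px).
#' @param frame_interval_s Frame interval (s), recorded in params.
#' @param pulse_prob Per-cell per-frame probability of an isolated pulse.
#' @param pulse_amplitude Peak amplitude of a pulse (intensity units).
#' @param pulse_width Pulse duration in frames (>= 2).
#' @param n_clusters Number of planted propagation clusters.
#' @param cluster_size Cells per cluster (trigger + children).
#' @param cluster_per_step Children pulsing at each successive frame lag
#'   (the cluster spreads outward over `ceiling((cluster_size - 1) /
#'   cluster_per_step)` frames).
#' @param cluster_radius_um Radius within which cluster children are drawn.
#' @param baseline Cell baseline intensity.
#' @param background Dark offset added everywhere (keeps the noise floor
#'   above zero, as a camera offset does).
#' @param drift_coef Polynomial coefficients of the global additive drift in
#'   normalised time u = (t-1)/(T-1): `drift(u) = sum(drift_coef[k] u^k)`.
#' @param read_noise_sd Gaussian read noise sd.
#' @param shot_scale Signal-proportional variance scale (variance =
#'   `read_noise_sd^2 + shot_scale * signal`); 0 disables.
#' @param cell_radius_px Cell footprint radius (px).
#' @param seed Optional integer seed.
#' @return List with `stack` (`[T, Y, X]` array), `cells` (data frame),
#'   `truth` (data frame of planted pulse events: `cell_id`, `frame` =
#'   peak frame, `x_um`, `y_um`, `amplitude`, `role`, `cluster_id`) and
#'   `params`.
#' @export
generate_calcium_movie <- function(n_frames = 200, shape = c(512, 512),
                                   n_cells = 2000, pitch_um = 1.1,
                                   frame_interval_s = 5,
                                   pulse_prob = 1e-4, pulse_amplitude = 20,
                                   pulse_width = 4,
                                   n_clusters = 0, cluster_size = 7,
                                   cluster_per_step = 6,
                                   cluster_radius_um = 60,
                                   baseline = 100, background = 20,
                                   drift_coef = c(0, -5),
                                   read_noise_sd = 2, shot_scale = 0,
                                   cell_radius_px = 3, seed = NULL) {
  stopifnot(pulse_prob >= 0, pulse_prob <= 1, pulse_width >= 2,
            n_frames >= 10)
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  r <- cell_radius_px
  centers <- place_centers(n_cells, ny, nx, min_dist = 2 * r + 2,
                           margin = r + 1)
  offs <- disk_offsets(r)

  # isolated pulses: Bernoulli per cell-frame, peak frames kept away from
  # the movie edges so every pulse has a well-defined local maximum
  lo <- pulse_width; hi <- n_frames - pulse_width
  hits <- which(stats::runif(n_cells * n_frames) < pulse_prob)
  cell_of <- (hits - 1L) %% n_cells + 1L
  frame_of <- (hits - 1L) %/% n_cells + 1L
  ok <- frame_of >= lo & frame_of <= hi
  truth <- data.frame(cell_id = cell_of[ok], frame = frame_of[ok],
                      role = rep("isolated", sum(ok)),
                      cluster_id = rep(NA_integer_, sum(ok)))

  # planted propagation clusters
  if (n_clusters > 0) {
    used <- unique(truth$cell_id)
    for (cl in seq_len(n_clusters)) {
      avail <- setdiff(seq_len(n_cells), used)
      trig <- sample(avail, 1)
      d2 <- (centers[, "x"] - centers[trig, "x"])^2 +
            (centers[, "y"] - centers[trig, "y"])^2
      nb <- setdiff(order(d2), c(trig, used))
      nb <- nb[sqrt(d2[nb]) * pitch_um <= cluster_radius_um]
      nb <- nb[seq_len(min(cluster_size - 1, length(nb)))]
      t0 <- sample(seq(lo + 5, hi - 10), 1)
      lags <- 1 + (seq_along(nb) - 1) %/% cluster_per_step
      truth <- rbind(truth,
                     data.frame(cell_id = trig, frame = t0, role = "trigger",
                                cluster_id = cl),
                     data.frame(cell_id = nb, frame = t0 + lags,
                                role = "child", cluster_id = cl))
      used <- c(used, trig, nb)
    }
  }
  truth <- truth[order(truth$frame, truth$cell_id), , drop = FALSE]
  truth$x_um <- centers[truth$cell_id, "x"] * pitch_um
  truth$y_um <- centers[truth$cell_id, "y"] * pitch_um
  truth$amplitude <- rep(pulse_amplitude, nrow(truth))
  rownames(truth) <- NULL

  # render: static base + global drift + pulses + noise
  base <- matrix(background, ny, nx)
  for (i in seq_len(n_cells))
    base <- add_disk(base, centers[i, "y"], centers[i, "x"], offs, baseline)
  stack <- aperm(array(base, c(ny, nx, n_frames)), c(3, 1, 2))
  u <- (seq_len(n_frames) - 1) / (n_frames - 1)
  drift <- drop(outer(u, seq_along(drift_coef) - 1, `^`) %*% drift_coef)
  stack <- stack + drift   # recycles along T (first, fastest index)

  # temporal pulse shape: rise one frame before the peak, decay after
  shape_t <- c(0.5, 1, 0.6^seq_len(pulse_width - 2))
  t_offs <- seq_along(shape_t) - 2L
  for (e in seq_len(nrow(truth))) {
    cid <- truth$cell_id[e]
    yy <- round(centers[cid, "y"]) + offs[, "dy"]
    xx <- round(centers[cid, "x"]) + offs[, "dx"]
    okp <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    frames <- truth$frame[e] + t_offs
    okf <- frames >= 1 & frames <= n_frames
    idx <- cbind(rep(frames[okf], each = sum(okp)),
                 rep(yy[okp], sum(okf)), rep(xx[okp], sum(okf)))
    stack[idx] <- stack[idx] +
      pulse_amplitude * rep(shape_t[okf], each = sum(okp))
  }

  if (read_noise_sd > 0 || shot_scale > 0) {
    sdv <- sqrt(read_noise_sd^2 + shot_scale * pmax(stack, 0))
    stack <- stack + stats::rnorm(length(stack)) * sdv
  }

  cells <- data.frame(id = seq_len(n_cells),
                      x_px = centers[, "x"], y_px = centers[, "y"],
                      x_um = centers[, "x"] * pitch_um,
                      y_um = centers[, "y"] * pitch_um)
  list(stack = stack, cells = cells, truth = truth,
       params = list(n_frames = n_frames, shape = shape, n_cells = n_cells,
                     pitch_um = pitch_um, frame_interval_s = frame_interval_s,
                     pulse_prob = pulse_prob,
                     pulse_amplitude = pulse_amplitude,
                     pulse_width = pulse_width, n_clusters = n_clusters,
                     baseline = baseline, read_noise_sd = read_noise_sd,
                     seed = seed))
}

#' Synthetic dual-channel movie with pulse cascades and entotic inclusions
#'
#' Emulates a ratiometric cAMP reporter: the signal-sensitive "green"
#' channel dims while a cell pulses, the insensitive "red" channel stays
#' constant, so the red/green ratio rises during a pulse. Plants three
#' event classes with full ground truth: background isolated pulses,
#' wave cascades (an origin cell pulses, children pulse within
#' `step_frac * sqrt(lag) * dprime_um` of their parent at lags
#' `1..fmax`), and entotic inclusions (small particles with a high
#' red/green ratio persisting an exponentially distributed number of
#' frames while random-walking).
#'
#' @param n_frames,shape,n_cells Movie geometry and cell count.
#' @param pitch_um Pixel pitch (um/px).
#' @param frame_interval_s Frame interval (s).
#' @param motility_sd_um Per-frame random-walk step sd of the cells (um).
#' @param pulse_prob Per-cell per-frame background pulse probability.
#' @param pulse_width Frames a pulse stays elevated (>= 2).
#' @param n_waves Number of planted cascades.
#' @param wave_children Children per cascade.
#' @param dprime_um Pseudo-diffusion coefficient used when planting links.
#' @param fmax Maximum planted frame lag.
#' @param step_frac Planted parent-child distances are at most
#'   `step_frac * sqrt(lag) * dprime_um` (margin below the reach used at
#'   recovery).
#' @param n_entosis Number of planted entotic inclusions.
#' @param entosis_duration_mean Mean of the exponential duration draw
#'   (frames); durations are `ceiling(rexp())`.
#' @param entosis_onset_range Frame range for inclusion onsets.
#' @param green_baseline,red_baseline Channel baselines on a cell.
#' @param pulse_green_factor Green multiplier during a pulse (< 1).
#' @param read_noise_sd Gaussian read noise sd per channel (0 = noiseless).
#' @param cell_radius_px Cell footprint radius (px).
#' @param seed Optional integer seed.
#' @return List with `red`, `green` (`[T, Y, X]` arrays), `cells`, and
#'   `truth`: a list of `pulses` (event table with `event_id`, `cell_id`,
#'   `frame` = onset, `x_um`, `y_um`, `role`, `wave_id`), `links`
#'   (`parent_event`, `child_event`, `lag`, `dist_um`), `origins` and
#'   `entosis` (`id`, `onset`, `duration_frames`, `x_um`, `y_um`), plus
#'   `params`.
#' @export
generate_dicty_movie <- function(n_frames = 60, shape = c(512, 512),
                                 n_cells = 300, pitch_um = 1.1,
                                 frame_interval_s = 30,
                                 motility_sd_um = 2,
                                 pulse_prob = 0, pulse_width = 3,
                                 n_waves = 0, wave_children = 20,
                                 dprime_um = 250, fmax = 3,
                                 step_frac = 0.8,
                                 n_entosis = 0, entosis_duration_mean = 15,
                                 entosis_onset_range = NULL,
                                 green_baseline = 100, red_baseline = 100,
                                 pulse_green_factor = 0.4,
                                 read_noise_sd = 0,
                                 cell_radius_px = 3, seed = NULL) {
  stopifnot(pulse_width >= 2, step_frac > 0, step_frac <= 1,
            motility_sd_um * 1 / pitch_um <= 16.5)
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  r <- cell_radius_px
  margin <- r + 2
  centers0 <- place_centers(n_cells, ny, nx, min_dist = 2 * r + 2,
                            margin = margin)

  # per-frame positions: reflected random walk (px)
  pos <- array(NA_real_, c(n_frames, n_cells, 2))
  pos[1, , ] <- centers0[, c("x", "y")]
  step_px <- motility_sd_um / pitch_um
  lim <- c(nx - margin, ny - margin)
  for (t in 2:n_frames) {
    p <- pos[t - 1, , ] + matrix(stats::rnorm(2 * n_cells, 0, step_px),
                                 n_cells, 2)
    for (k in 1:2) {
      p[, k] <- ifelse(p[, k] < margin, 2 * margin - p[, k], p[, k])
      p[, k] <- ifelse(p[, k] > lim[k], 2 * lim[k] - p[, k], p[, k])
    }
    pos[t, , ] <- p
  }

  # background pulses (onset frames)
  lo <- 2L; hi <- n_frames - pulse_width
  pulses <- data.frame(cell_id = integer(), frame = integer(),
                       role = character(), wave_id = integer())
  if (pulse_prob > 0) {
    hits <- which(stats::runif(n_cells * n_frames) < pulse_prob)
    cell_of <- (hits - 1L) %% n_cells + 1L
    frame_of <- (hits - 1L) %/% n_cells + 1L
    ok <- frame_of >= lo & frame_of <= hi
    if (any(ok))
      pulses <- data.frame(cell_id = cell_of[ok], frame = frame_of[ok],
                           role = "isolated", wave_id = NA_integer_)
  }

  # planted cascades
  links <- data.frame(parent_event = integer(), child_event = integer(),
                      lag = integer(), dist_um = numeric())
  if (n_waves > 0) {
    for (wv in seq_len(n_waves)) {
      used <- unique(pulses$cell_id)
      avail <- setdiff(seq_len(n_cells), used)
      # origin near the field centre so cascades stay in bounds
      ctr_d2 <- (centers0[avail, "x"] - nx / 2)^2 +
                (centers0[avail, "y"] - ny / 2)^2
      origin <- avail[which.min(ctr_d2)]
      t0 <- lo + 2L
      ev <- data.frame(cell_id = origin, frame = t0,
                       role = "origin", wave_id = wv)
      used <- c(used, origin)
      for (j in seq_len(wave_children)) {
        placed <- FALSE
        for (try in 1:50) {
          pe <- sample.int(nrow(ev), 1)
          lag <- sample.int(fmax, 1)
          tc <- ev$frame[pe] + lag
          if (tc > hi) next
          # target point within the planted reach of the parent
          px_parent <- pos[ev$frame[pe], ev$cell_id[pe], ]
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0.2, step_frac) * sqrt(lag) * dprime_um /
                 pitch_um
          tx <- px_parent[1] + rad * cos(ang)
          ty <- px_parent[2] + rad * sin(ang)
          if (tx < margin || tx > nx - margin ||
              ty < margin || ty > ny - margin) next
          cand <- setdiff(seq_len(n_cells), used)
          if (length(cand) == 0) break
          d2 <- (pos[tc, cand, 1] - tx)^2 + (pos[tc, cand, 2] - ty)^2
          child <- cand[which.min(d2)]
          dist_um <- sqrt(sum((pos[tc, child, ] -
                               pos[tc, ev$cell_id[pe], ])^2)) * pitch_um
          if (dist_um > sqrt(lag) * dprime_um) next
          ev <- rbind(ev, data.frame(cell_id = child, frame = tc,
                                     role = "child", wave_id = wv))
          links <- rbind(links,
                         data.frame(parent_event = pe + nrow(pulses),
                                    child_event = nrow(ev) + nrow(pulses),
                                    lag = lag, dist_um = dist_um))
          used <- c(used, child)
          placed <- TRUE
          break
        }
        if (!placed) break
      }
      pulses <- rbind(pulses, ev)
    }
  }
  if (nrow(pulses) > 0) {
    pulses$event_id <- seq_len(nrow(pulses))
    pulses$x_um <- pos[cbind(pulses$frame, pulses$cell_id, 1)] * pitch_um
    pulses$y_um <- pos[cbind(pulses$frame, pulses$cell_id, 2)] * pitch_um
    pulses <- pulses[, c("event_id", "cell_id", "frame", "x_um", "y_um",
                         "role", "wave_id")]
  } else {
    pulses <- data.frame(event_id = integer(), cell_id = integer(),
                         frame = integer(), x_um = numeric(),
                         y_um = numeric(), role = character(),
                         wave_id = integer())
  }
  origins <- pulses[pulses$role == "origin", , drop = FALSE]

  # entotic inclusions: small high-ratio particles with exponential lifetime
  ent_r <- max(1, r - 1)
  if (is.null(entosis_onset_range))
    entosis_onset_range <- c(1L, max(1L, n_frames - 4L *
                                       ceiling(entosis_duration_mean)))
  entosis <- data.frame(id = integer(), onset = integer(),
                        duration_frames = integer(),
                        x_um = numeric(), y_um = numeric())
  ent_paths <- list()
  if (n_entosis > 0) {
    clear_px <- 2 * r + ent_r + 2
    e_centers <- matrix(NA_real_, n_entosis, 2)
    for (i in seq_len(n_entosis)) {
      for (try in 1:500) {
        cx <- stats::runif(1, margin, nx - margin)
        cy <- stats::runif(1, margin, ny - margin)
        d2 <- min((centers0[, "x"] - cx)^2 + (centers0[, "y"] - cy)^2)
        prev <- if (i > 1) min((e_centers[seq_len(i - 1), 1] - cx)^2 +
                               (e_centers[seq_len(i - 1), 2] - cy)^2) else Inf
        if (d2 > clear_px^2 && prev > (4 * ent_r)^2) break
      }
      e_centers[i, ] <- c(cx, cy)
    }
    onset <- sample(seq(entosis_onset_range[1], entosis_onset_range[2]),
                    n_entosis, replace = TRUE)
    dur <- pmin(ceiling(stats::rexp(n_entosis, 1 / entosis_duration_mean)),
                n_frames - onset + 1L)
    entosis <- data.frame(id = seq_len(n_entosis), onset = onset,
                          duration_frames = as.integer(dur),
                          x_um = e_centers[, 1] * pitch_um,
                          y_um = e_centers[, 2] * pitch_um)
    # random-walk path per inclusion, steps resampled to keep clear of cells
    for (i in seq_len(n_entosis)) {
      path <- matrix(NA_real_, dur[i], 2)
      path[1, ] <- e_centers[i, ]
      if (dur[i] > 1) for (t in 2:dur[i]) {
        for (try in 1:20) {
          p <- path[t - 1, ] + stats::rnorm(2, 0, 2 / pitch_um)
          p <- pmin(pmax(p, margin), c(nx - margin, ny - margin))
          tf <- min(onset[i] + t - 1L, n_frames)
          if (min((pos[tf, , 1] - p[1])^2 + (pos[tf, , 2] - p[2])^2) >
              clear_px^2 || try == 20) break
        }
        path[t, ] <- p
      }
      ent_paths[[i]] <- path
    }
  }

  # render the two channels
  offs <- disk_offsets(r)
  offs_e <- disk_offsets(ent_r)
  green <- array(0, c(n_frames, ny, nx))
  red <- array(0, c(n_frames, ny, nx))
  pulse_until <- matrix(0L, n_frames, n_cells)  # frames in elevated state
  for (e in seq_len(nrow(pulses))) {
    fr <- pulses$frame[e]:min(pulses$frame[e] + pulse_width - 1L, n_frames)
    pulse_until[fr, pulses$cell_id[e]] <- 1L
  }
  for (t in seq_len(n_frames)) {
    g <- matrix(0, ny, nx); rd <- matrix(0, ny, nx)
    for (i in seq_len(n_cells)) {
      gval <- if (pulse_until[t, i] == 1L)
        green_baseline * pulse_green_factor else green_baseline
      g <- add_disk(g, pos[t, i, 2], pos[t, i, 1], offs, gval)
      rd <- add_disk(rd, pos[t, i, 2], pos[t, i, 1], offs, red_baseline)
    }
    if (n_entosis > 0) for (i in seq_len(n_entosis)) {
      k <- t - entosis$onset[i] + 1L
      if (k >= 1 && k <= entosis$duration_frames[i]) {
        p <- ent_paths[[i]][k, ]
        g <- add_disk(g, p[2], p[1], offs_e, green_baseline * 0.15)
        rd <- add_disk(rd, p[2], p[1], offs_e, red_baseline * 1.2)
      }
    }
    green[t, , ] <- g
    red[t, , ] <- rd
  }
  if (read_noise_sd > 0) {
    green <- green + stats::rnorm(length(green), 0, read_noise_sd)
    red <- red + stats::rnorm(length(red), 0, read_noise_sd)
  }

  cells <- data.frame(id = seq_len(n_cells),
                      x_px = centers0[, "x"], y_px = centers0[, "y"],
                      x_um = centers0[, "x"] * pitch_um,
                      y_um = centers0[, "y"] * pitch_um)
  list(red = red, green = green, cells = cells,
       truth = list(pulses = pulses, links = links, origins = origins,
                    entosis = entosis),
       params = list(n_frames = n_frames, shape = shape, n_cells = n_cells,
                     pitch_um = pitch_um, frame_interval_s = frame_interval_s,
                     motility_sd_um = motility_sd_um, dprime_um = dprime_um,
                     fmax = fmax, pulse_width = pulse_width,
                     entosis_duration_mean = entosis_duration_mean,
                     seed = seed))
}

#' Synthetic flat-field pair with illumination and lens non-uniformity
#'
#' Builds a multiplicative shading field as the product of a smooth
#' illumination gradient (min/max ratio `illum_minmax`) and a radial lens
#' throughput fall-off (corner/centre ratio `lens_corner_center`), and
#' returns both the shaded "raw" image of a given truth scene and the
#' shaded uniform-plate "reference" image.
#'
#' @param truth Matrix of true signal, or a scalar for a uniform scene.
#' @param shape Image shape `c(ny, nx)` if `truth` is scalar.
#' @param illum_minmax Min/max ratio of the illumination field.
#' @param lens_corner_center Corner/centre ratio of the lens throughput.
#' @param reference_level Plate brightness of the reference image.
#' @param noise_sd Additive Gaussian noise on both images (0 = none).
#' @param seed Optional integer seed.
#' @return List with `raw`, `reference`, `shading` and `truth`.
#' @export
generate_flatfield_pair <- function(truth = 100, shape = c(256, 256),
                                    illum_minmax = 0.8,
                                    lens_corner_center = 0.7,
                                    reference_level = 1000,
                                    noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(truth)) truth <- matrix(truth, shape[1], shape[2])
  ny <- nrow(truth); nx <- ncol(truth)
  xg <- matrix(seq(0, 1, length.out = nx), ny, nx, byrow = TRUE)
  yg <- matrix(seq(0, 1, length.out = ny), ny, nx)
  # centre-peaked illumination, slightly decentred from the lens axis
  gi <- (xg - 0.45)^2 + (yg - 0.55)^2
  illum <- 1 - (1 - illum_minmax) * gi / max(gi)
  r2 <- ((xg - 0.5)^2 + (yg - 0.5)^2) / 0.5   # 1 at the corners
  lens <- 1 - (1 - lens_corner_center) * r2
  shading <- illum * lens
  raw <- truth * shading
  reference <- reference_level * shading
  if (noise_sd > 0) {
    raw <- raw + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    reference <- reference + matrix(stats::rnorm(ny * nx, 0, noise_sd),
                                    ny, nx)
  }
  list(raw = raw, reference = reference, shading = shading, truth = truth)
}

#' Recover the phase-cluster length from synthetic nuclei scenes
#'
#' Generator-recovery protocol for the spatial cytometry statistics:
#' generates `n_scenes` independent nuclei scenes with the requested
#' cluster length, classifies each by the DNA-content midpoint rule,
#' computes the radius-dependent in-phase rate for both G1 and G2, pools
#' the rate curves (pointwise mean over scenes) and fits the exponential
#' decay for each group with the asymptote fixed at the pooled group
#' fraction. Pooling over scenes and groups suppresses the scene-level
#' fluctuation of a single correlated label field.
#'
#' @param cluster_length_um Planted cluster length (um).
#' @param n_scenes Independent scenes to pool (default 3).
#' @param seed Base seed; scene s uses `seed + s`.
#' @param radii_um Radii for the rate curves; the default spans 0.2 to 2.5
#'   times the planted length, so the fit window is scale-invariant and the
#'   recovery bias does not depend on the cluster scale.
#' @param ... Further arguments to [generate_nuclei_scene()].
#' @return List with `length_um` (mean of the G1 and G2 fitted lengths),
#'   `by_group` (named vector) and the pooled `rates` per group.
#' @export
recover_cluster_length <- function(cluster_length_um, n_scenes = 3,
                                   seed = 1,
                                   radii_um = seq(0.2, 2.5, by = 0.1) *
                                     cluster_length_um, ...) {
  curves <- list(G1 = NULL, G2 = NULL)
  fracs <- c(G1 = 0, G2 = 0)
  for (s in seq_len(n_scenes)) {
    sc <- generate_nuclei_scene(cluster_length_um = cluster_length_um,
                                seed = seed + s, ...)
    cells <- sc$cells
    model <- intensity_histogram(cells$intensity[cells$phase != "M"])
    cl <- classify_phase(cells, model, m_ids = which(cells$phase == "M"))
    for (g in c("G1", "G2")) {
      rr <- in_phase_rate_by_radius(cl, g, radii_um, n_samples = 2000,
                                    seed = seed + s)
      curves[[g]] <- cbind(curves[[g]], rr$rate)
      fracs[g] <- fracs[g] + mean(cl$phase[cl$phase != "M"] == g)
    }
  }
  fracs <- fracs / n_scenes
  by_group <- vapply(c(G1 = "G1", G2 = "G2"), function(g) {
    fit <- cluster_length_fit(rowMeans(curves[[g]]), radii = radii_um,
                              asymptote = fracs[[g]])
    fit$length_um
  }, numeric(1))
  list(length_um = mean(by_group, na.rm = TRUE), by_group = by_group,
       rates = lapply(curves, rowMeans))
}

#' Score detected events against a planted truth table
#'
#' Greedy one-to-one matching: detections are paired to the nearest
#' unmatched truth event within `dist_tol_um` and `frame_tol` frames, in
#' ascending order of spatial distance.
#'
#' @param detected Data frame with `frame`, `x_um`, `y_um`.
#' @param truth Data frame with `frame`, `x_um`, `y_um`.
#' @param dist_tol_um Spatial matching tolerance (um).
#' @param frame_tol Temporal matching tolerance (frames).
#' @return List with `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
score_events <- function(detected, truth, dist_tol_um = 10, frame_tol = 1) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                n_matched = 0L, n_detected = nd, n_truth = nt))
  dx <- outer(detected$x_um, truth$x_um, `-`)
  dy <- outer(detected$y_um, truth$y_um, `-`)
  dd <- sqrt(dx^2 + dy^2)
  df <- abs(outer(detected$frame, truth$frame, `-`))
  dd[df > frame_tol | dd > dist_tol_um] <- Inf
  n_matched <- 0L
  while (TRUE) {
    k <- which.min(dd)
    if (!is.finite(dd[k])) break
    i <- (k - 1) %% nd + 1
    j <- (k - 1) %/% nd + 1
    n_matched <- n_matched + 1L
    dd[i, ] <- Inf
    dd[, j] <- Inf
  }
  list(precision = n_matched / nd, recall = n_matched / nt,
       n_matched = n_matched, n_detected = nd, n_truth = nt)
}
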