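#' Flatten the baseline of a temporal intensity profile
#'
#' Removes slow baseline drift (photobleaching, focus drift) by subtracting a
#' least-squares polynomial. The fit is made robust to transient pulses by a
#' single re-fit pass in which frames with positive residuals above two
#' residual standard deviations are excluded, so a pulse is not absorbed
#' into the baseline.
#'
#' @param profile Numeric vector, one value per frame.
#' @param poly_order Polynomial order (default 3); must satisfy
#'   `length(profile) > poly_order + 1`.
#' @param robust If `TRUE` (default), apply the pulse-excluding re-fit pass.
#' @return Residual profile (same length), baseline removed.
#' @export
flatten_baseline <- function(profile, poly_order = 3, robust = TRUE) {
  profile <- as.numeric(profile)
  t_len <- length(profile)
  if (t_len <= poly_order + 1)
    stop("flatten_baseline: profile length must exceed poly_order + 1",
         call. = FALSE)
  tt <- seq_len(t_len)
  x <- stats::poly(tt, degree = poly_order, raw = FALSE)
  fit <- stats::lm.fit(cbind(1, x), profile)
  res <- fit$residuals
  if (robust) {
    s <- stats::sd(res)
    keep <- res <= 2 * s
    if (sum(keep) > poly_order + 1 && any(!keep)) {
      fit2 <- stats::lm.fit(cbind(1, x)[keep, , drop = FALSE], profile[keep])
      res <- profile - cbind(1, x) %*% fit2$coefficients
    }
  }
  as.numeric(res)
}

#' Sample skewness of a temporal profile
#'
#' Population-moment skewness `m3 / m2^(3/2)`. A profile containing a few
#' large positive transients on a flat baseline has large positive skewness,
#' which is what makes it a cheap per-pixel screen for rare pulses.
#'
#' @param profile Numeric vector, length >= 3.
#' @return Skewness, or `NA_real_` when the variance is zero.
#' @export
profile_skewness <- function(profile) {
  profile <- as.numeric(profile)
  if (length(profile) < 3)
    stop("profile_skewness: need at least 3 samples", call. = FALSE)
  mu <- mean(profile)
  m2 <- mean((profile - mu)^2)
  if (m2 == 0) return(NA_real_)
  mean((profile - mu)^3) / m2^1.5
}

# Per-pixel skewness of polynomial-flattened profiles, vectorised over
# pixels in column chunks to bound peak memory on large stacks.
skewness_map <- function(stack, poly_order = 3, chunk = 65536L) {
  d <- dim(stack)
  t_len <- d[1]
  n_px <- d[2] * d[3]
  m <- matrix(stack, nrow = t_len)
  q <- qr.Q(qr(cbind(1, stats::poly(seq_len(t_len), degree = poly_order))))
  sk <- numeric(n_px)
  for (start in seq(1L, n_px, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_px)
    y <- m[, idx, drop = FALSE]
    r <- y - q %*% crossprod(q, y)
    m2 <- colMeans(r^2)
    m3 <- colMeans(r^3)
    sk[idx] <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  }
  matrix(sk, nrow = d[2], ncol = d[3])
}

#' Detect rare pulsing cells in a single-channel movie
#'
#' Screens every pixel of a T x Y x X stack by the skewness of its
#' baseline-flattened temporal profile; pixels above `skew_threshold` are
#' candidate cells and are merged into cell regions by connected components.
#' For each candidate region, the mean temporal profile is flattened
#' robustly and local maxima exceeding `noise_k` times the robust noise
#' level (1.4826 x MAD of the flattened profile) are emitted as pulse
#' events, with the time and the region centroid.
#'
#' @param stack Numeric array `[T, Y, X]`, T >= 10.
#' @param pitch_um Pixel pitch at the sample plane (um/px).
#' @param skew_threshold Candidate threshold on per-pixel skewness
#'   (default 1).
#' @param noise_k Peak threshold in robust noise units (default 5).
#' @param poly_order Baseline polynomial order (default 3).
#' @param min_size_px Minimum candidate-region size in pixels (default 2).
#' @return Data frame of pulse events: `event_id`, `cell_id`, `frame`
#'   (peak frame), `x_um`, `y_um`, `amplitude`. Zero rows when nothing is
#'   detected.
#' @export
detect_pulsing_cells <- function(stack, pitch_um = 1, skew_threshold = 1,
                                 noise_k = 5, poly_order = 3,
                                 min_size_px = 2) {
  d <- dim(stack)
  if (length(d) != 3 || d[1] < 10)
    stop("detect_pulsing_cells: stack must be [T, Y, X] with T >= 10",
         call. = FALSE)
  empty <- data.frame(event_id = integer(), cell_id = integer(),
                      frame = integer(), x_um = numeric(), y_um = numeric(),
                      amplitude = numeric())
  sk <- skewness_map(stack, poly_order = poly_order)
  mask <- sk > skew_threshold
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  if (length(keep) == 0) return(empty)
  m <- matrix(stack, nrow = d[1])
  lab_vec <- as.integer(lab)
  events <- vector("list", length(keep))
  eid <- 0L
  for (k in seq_along(keep)) {
    cid <- keep[k]
    px <- which(lab_vec == cid)
    prof <- if (length(px) == 1L) m[, px] else rowMeans(m[, px, drop = FALSE])
    res <- flatten_baseline(prof, poly_order = poly_order)
    noise <- stats::mad(res)
    if (noise == 0) noise <- stats::sd(res)
    if (!is.finite(noise) || noise == 0) next
    peaks <- find_local_maxima(res, noise_k * noise)
    if (length(peaks) == 0) next
    # centroid of the candidate region (row = y, col = x), 0-based px
    rows <- (px - 1L) %% d[2]
    cols <- (px - 1L) %/% d[2]
    events[[k]] <- data.frame(
      event_id = eid + seq_along(peaks), cell_id = cid, frame = peaks,
      x_um = mean(cols) * pitch_um, y_um = mean(rows) * pitch_um,
      amplitude = res[peaks])
    eid <- eid + length(peaks)
  }
  events <- events[!vapply(events, is.null, logical(1))]
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Strict local maxima above a threshold; plateaus take the first index.
find_local_maxima <- function(x, threshold) {
  n <- length(x)
  if (n < 3) return(integer())
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > threshold & x > left & x >= right)
}

#' Histogram of pulse events over time
#'
#' Counts pulse events in consecutive time bins of `bin_frames` frames
#' (the per-frame pulsing-cell histogram convention, e.g. 6 frames = 30 s at
#' 5-s intervals).
#'
#' @param events Data frame with a `frame` column (from
#'   [detect_pulsing_cells()], or a truth table).
#' @param n_frames Total number of frames in the recording.
#' @param bin_frames Bin width in frames (default 6).
#' @return Data frame with `bin_start` (first frame of the bin, 1-based)
#'   and `count`.
#' @export
pulse_count_series <- function(events, n_frames, bin_frames = 6) {
  stopifnot(bin_frames >= 1, n_frames >= 1)
  starts <- seq(1L, n_frames, by = bin_frames)
  bin_of <- function(f) (f - 1L) %/% bin_frames + 1L
  counts <- tabulate(bin_of(events$frame), nbins = length(starts))
  data.frame(bin_start = starts, count = counts)
}

#' Transform a movie to its ratio to a per-pixel baseline
#'
#' Each pixel's temporal profile is divided by the mean of its own values in
#' a baseline window (e.g. the first frames before any activity). Used to
#' visualise intracellular signal propagation from single-channel intensity.
#' Pixels with non-positive baseline mean are masked to `NA`.
#'
#' @param stack Numeric array `[T, Y, X]`.
#' @param baseline_frames Integer vector of frame indices forming the
#'   baseline window.
#' @return Ratio stack, same dimensions.
#' @export
ratio_to_baseline_movie <- function(stack, baseline_frames) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  if (any(baseline_frames < 1) || any(baseline_frames > d[1]))
    stop("ratio_to_baseline_movie: baseline window outside the recording",
         call. = FALSE)
  m <- matrix(stack, nrow = d[1])
  base <- colMeans(m[baseline_frames, , drop = FALSE])
  bad <- !is.finite(base) | base <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with non-positive baseline masked to NA")
    base[bad] <- NA_real_
  }
  array(t(t(m) / base), dim = d)
}
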