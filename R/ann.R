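#' Average nearest-neighbour distance of a point pattern
#'
#' For the pulsing cells detected in one movie frame, the ANN statistic is
#' the mean, over all points, of the distance from each point to its nearest
#' other point. With fewer than two points the statistic is undefined and
#' `NA` is returned (such frames are skipped downstream, matching the gaps
#' in per-frame ANN plots).
#'
#' @param points Two-column numeric matrix (x, y) in um (or any one unit).
#' @return Mean nearest-neighbour distance, or `NA_real_` if fewer than two
#'   points.
#' @export
ann_frame <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Expected ANN under complete spatial randomness
#'
#' First-order expectation `1 / (2 * sqrt(M / S))` for `M` uniformly random
#' points in a window of area `S` (edge effects neglected).
#'
#' @param m Number of points (>= 1).
#' @param s Window area (same squared unit as the distances).
#' @return Expected mean nearest-neighbour distance.
#' @export
expected_ann <- function(m, s) {
  stopifnot(m >= 1, s > 0)
  1 / (2 * sqrt(m / s))
}

#' Normalised ANN
#'
#' Ratio of the observed ANN to its expectation under complete spatial
#' randomness; values near 1 indicate randomness, values below 1 clustering.
#'
#' @param w Observed ANN.
#' @param m Number of points.
#' @param s Window area.
#' @return Dimensionless normalised ANN.
#' @export
normalized_ann <- function(w, m, s) w / expected_ann(m, s)

#' Null mean and variance of the ANN in a rectangular window
#'
#' Under complete spatial randomness of `n` points in a rectangle of area
#' `S` and perimeter `L`, the ANN is approximately normal. The default
#' (`form = "printed"`) evaluates
#' \deqn{mean = 0.500 \sqrt{S/n} + 0.051 L/n + 0.041 L/(n\sqrt n)}
#' \deqn{var  = 0.070 S/n^2 + 0.037 \sqrt{S/n^5}}
#' Note the second variance term of the printed form is dimensionally
#' inconsistent with the first (it lacks a factor of the perimeter); the
#' classical Donnelly edge-corrected variance
#' `0.070 S/n^2 + 0.037 L sqrt(S)/n^{5/2}` is available as
#' `form = "donnelly"`.
#'
#' @param n Number of points (>= 2).
#' @param geom A [field_geometry()] for the window.
#' @param form `"printed"` (default) or `"donnelly"` variance form.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
ann_null_params <- function(n, geom, form = c("printed", "donnelly")) {
  form <- match.arg(form)
  stopifnot(inherits(geom, "field_geometry"), n >= 2)
  s <- geom$area
  l <- geom$perimeter
  mu <- 0.500 * sqrt(s / n) + 0.051 * l / n + 0.041 * l / (n * sqrt(n))
  v <- if (form == "printed") {
    0.070 * s / n^2 + 0.037 * sqrt(s / n^5)
  } else {
    0.070 * s / n^2 + 0.037 * l * sqrt(s) / n^2.5
  }
  c(mean = mu, variance = v)
}

#' Information content of an observed ANN
#'
#' Non-randomness score `I(W) = -log p(W)` in nats, where `p(W)` is the
#' lower-tail probability of the observed ANN under the normal null of
#' [ann_null_params()]. Small ANN (clustering) gives small `p` and large
#' `I`; `I(null mean) = log 2`.
#'
#' @inheritParams ann_null_params
#' @param w Observed ANN (same unit as the window dimensions).
#' @return Information content in nats (`>= 0` for `p <= 1`).
#' @export
information_content <- function(w, n, geom, form = c("printed", "donnelly")) {
  np <- ann_null_params(n, geom, form)
  if (np[["variance"]] <= 0)
    stop("information_content: null variance must be positive", call. = FALSE)
  -stats::pnorm(w, mean = np[["mean"]], sd = sqrt(np[["variance"]]),
                log.p = TRUE)
}

#' Per-frame ANN statistics for a sequence of point patterns
#'
#' Computes, for every frame, the pulsing-cell count `M`, the observed ANN
#' `W`, its CSR expectation `E[W]`, the normalised ANN `w = W / E[W]`, the
#' normal null mean and variance, the lower-tail probability `p` and the
#' information content `I = -log p`. Frames with fewer than two points get
#' `NA` statistics.
#'
#' @param points_by_frame List of two-column matrices, one per frame.
#' @param geom A [field_geometry()] for the field of view.
#' @param form Null variance form, see [ann_null_params()].
#' @return A data frame with one row per frame: `frame`, `m`, `w_obs`,
#'   `e_w`, `w_norm`, `null_mean`, `null_var`, `p`, `info`.
#' @export
ann_series <- function(points_by_frame, geom, form = c("printed", "donnelly")) {
  form <- match.arg(form)
  stopifnot(inherits(geom, "field_geometry"))
  n_frames <- length(points_by_frame)
  out <- data.frame(frame = seq_len(n_frames), m = 0L, w_obs = NA_real_,
                    e_w = NA_real_, w_norm = NA_real_, null_mean = NA_real_,
                    null_var = NA_real_, p = NA_real_, info = NA_real_)
  for (i in seq_len(n_frames)) {
    pts <- points_by_frame[[i]]
    m <- if (is.null(pts)) 0L else nrow(as.matrix(pts))
    out$m[i] <- m
    if (m < 2) next
    w <- ann_frame(pts)
    np <- ann_null_params(m, geom, form)
    out$w_obs[i] <- w
    out$e_w[i] <- expected_ann(m, geom$area)
    out$w_norm[i] <- w / out$e_w[i]
    out$null_mean[i] <- np[["mean"]]
    out$null_var[i] <- np[["variance"]]
    out$p[i] <- stats::pnorm(w, np[["mean"]], sqrt(np[["variance"]]))
    out$info[i] <- -stats::pnorm(w, np[["mean"]], sqrt(np[["variance"]]),
                                 log.p = TRUE)
  }
  out
}

#' Flag frames with non-random clustering of pulsing cells
#'
#' A frame is flagged when its observed ANN falls below the null mean minus
#' `sd_band` null standard deviations (one-sided test for clustering; the
#' shaded +/- 3 sd band convention). Frames with fewer than two points are
#' never flagged.
#'
#' @param ann Data frame from [ann_series()].
#' @param sd_band Width of the band in null standard deviations (default 3).
#' @return Integer vector of flagged frame indices.
#' @export
flag_clustered_frames <- function(ann, sd_band = 3) {
  stopifnot(is.data.frame(ann), sd_band > 0)
  ok <- ann$m >= 2 & !is.na(ann$w_obs)
  flagged <- ok & ann$w_obs < ann$null_mean - sd_band * sqrt(ann$null_var)
  ann$frame[which(flagged)]
}
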