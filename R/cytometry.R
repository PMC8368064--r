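#' Segment nuclei in a 2-D fluorescence image
#'
#' Classical nuclei segmentation: global threshold (Otsu on the image by
#' default, or a user-supplied absolute value), morphological opening and
#' closing to remove speckle, hole filling, watershed splitting of touching
#' objects on the distance map, and a size filter. Per-object features are
#' the intensity-weighted centroid, area and total fluorescence intensity.
#'
#' @param image 2-D numeric matrix (rows = y).
#' @param threshold `"otsu"` (default) or an absolute intensity value.
#' @param size_min_px,size_max_px Size band in pixels; objects outside are
#'   discarded.
#' @param pitch_um Pixel pitch (um/px) for physical centroids and areas.
#' @param brush_size Diameter of the morphological structuring element
#'   (odd integer, default 3).
#' @param split_touching If `TRUE` (default), split touching objects by
#'   watershed on the distance map.
#' @return Data frame of cell objects: `id`, `x_px`, `y_px`, `x_um`,
#'   `y_um`, `area_px`, `area_um2`, `intensity`. Zero rows for a blank
#'   image.
#' @export
segment_nuclei <- function(image, threshold = "otsu",
                           size_min_px = 5, size_max_px = 500,
                           pitch_um = 1, brush_size = 3,
                           split_touching = TRUE) {
  stopifnot(is.matrix(image), size_min_px < size_max_px)
  empty <- data.frame(id = integer(), x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      intensity = numeric())
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    norm <- (image - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng)
  } else {
    as.numeric(threshold)
  }
  mask <- EBImage::Image(image > thr)
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  mask <- EBImage::closing(EBImage::opening(mask, brush), brush)
  mask <- EBImage::fillHull(mask)
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask))
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- as.matrix(lab)
  if (max(lab) == 0) return(empty)
  px <- which(lab > 0)
  ids <- lab[px]
  vals <- image[px]
  rows <- (px - 1L) %% nrow(image) + 1L
  cols <- (px - 1L) %/% nrow(image) + 1L
  area <- tabulate(ids)
  tot <- as.numeric(rowsum(vals, ids))
  cx <- as.numeric(rowsum(vals * (cols - 1), ids)) / tot
  cy <- as.numeric(rowsum(vals * (rows - 1), ids)) / tot
  keep <- which(area >= size_min_px & area <= size_max_px)
  if (length(keep) == 0) return(empty)
  data.frame(id = seq_along(keep), x_px = cx[keep], y_px = cy[keep],
             x_um = cx[keep] * pitch_um, y_um = cy[keep] * pitch_um,
             area_px = area[keep], area_um2 = area[keep] * pitch_um^2,
             intensity = tot[keep])
}

#' DNA-content intensity histogram and two-peak phase model
#'
#' Kernel-smoothed density of per-cell total fluorescence intensity. When
#' the density has at least two well-separated modes, the two tallest are
#' identified as the G1 (lower intensity) and G2 (higher intensity) peaks
#' of the DNA-content distribution; intensities can then be normalised so
#' the G1 peak sits at 1. Cells between the peaks are S phase and are not
#' separately resolved.
#'
#' @param intensities Numeric vector of per-cell total intensities, or a
#'   data frame with an `intensity` column.
#' @param normalize_to_g1 If `TRUE` (default), express the returned
#'   density axis and peak positions in units of the G1 peak.
#' @param adjust Bandwidth adjustment passed to [stats::density()].
#' @return List of class `phase_model` with `status` (`"ok"` or
#'   `"unimodal"`), `g1_peak`, `g2_peak`, `midpoint` (all `NA` when
#'   unimodal), `density` and `normalized`.
#' @export
intensity_histogram <- function(intensities, normalize_to_g1 = TRUE,
                                adjust = 1) {
  if (is.data.frame(intensities)) intensities <- intensities$intensity
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 10 || stats::sd(intensities) == 0) {
    return(structure(list(status = "unimodal", g1_peak = NA_real_,
                          g2_peak = NA_real_, midpoint = NA_real_,
                          density = NULL, normalized = normalize_to_g1),
                     class = "phase_model"))
  }
  dens <- stats::density(intensities, adjust = adjust)
  y <- dens$y
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  # suppress shoulder wiggles: a mode must rise above 5% of the tallest
  modes <- which(is_max & y > 0.05 * max(y))
  if (length(modes) < 2) {
    return(structure(list(status = "unimodal", g1_peak = NA_real_,
                          g2_peak = NA_real_, midpoint = NA_real_,
                          density = dens, normalized = normalize_to_g1),
                     class = "phase_model"))
  }
  top2 <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  g1 <- dens$x[min(top2)]
  g2 <- dens$x[max(top2)]
  if (normalize_to_g1) {
    dens$x <- dens$x / g1
    g2 <- g2 / g1
    g1 <- 1
  }
  structure(list(status = "ok", g1_peak = g1, g2_peak = g2,
                 midpoint = (g1 + g2) / 2, density = dens,
                 normalized = normalize_to_g1),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  if (x$status != "ok") {
    cat("Phase model unavailable (", x$status, ")\n", sep = "")
  } else {
    cat(sprintf("Phase model: G1 peak %.3f, G2 peak %.3f, midpoint %.3f%s\n",
                x$g1_peak, x$g2_peak, x$midpoint,
                if (x$normalized) " (G1-normalised)" else ""))
  }
  invisible(x)
}

#' Classify cells into G1 and G2 by the DNA-content midpoint
#'
#' Cells with intensity below the midpoint of the two histogram peaks are
#' labelled G1, cells at or above it G2 (a deterministic half-open
#' convention; the tie goes to G2). S-phase cells necessarily fall into one
#' of the two groups. Cells listed in `m_ids` are labelled M and are meant
#' to be excluded from the spatial statistics.
#'
#' @param cells Data frame with an `intensity` column (from
#'   [segment_nuclei()]).
#' @param model A `phase_model` from [intensity_histogram()] with
#'   `status == "ok"`. If the model is G1-normalised, intensities are
#'   normalised by `g1_scale` before comparison.
#' @param m_ids Optional vector of row indices (into `cells`) of M-phase
#'   cells, e.g. from an externally supplied mitosis mask or synthetic
#'   truth.
#' @param g1_scale The raw-intensity position of the G1 peak when the model
#'   is normalised; defaults to 1 (intensities already on the model scale).
#' @return `cells` with an added `phase` column (`"G1"`, `"G2"` or `"M"`).
#' @export
classify_phase <- function(cells, model, m_ids = NULL, g1_scale = 1) {
  stopifnot(inherits(model, "phase_model"))
  if (model$status != "ok")
    stop("classify_phase: phase model unavailable (", model$status, ")",
         call. = FALSE)
  val <- cells$intensity / g1_scale
  cells$phase <- ifelse(val < model$midpoint, "G1", "G2")
  if (!is.null(m_ids)) cells$phase[m_ids] <- "M"
  cells
}

# distances from probe rows to all rows of cells (um)
probe_dist <- function(cells, probes) {
  dx <- outer(cells$x_um[probes], cells$x_um, `-`)
  dy <- outer(cells$y_um[probes], cells$y_um, `-`)
  sqrt(dx^2 + dy^2)
}

#' In-phase cell rate by neighbour order
#'
#' For sampled probe cells of one cell-cycle group, sorts all other (G1/G2)
#' cells by distance and asks whether the k-th nearest neighbour shares the
#' probe's phase. The rate at order k is the fraction of probes whose k-th
#' neighbour is in phase; under random labels it equals the group fraction.
#' M-phase and unlabelled cells are excluded entirely; the probe itself is
#' never its own neighbour.
#'
#' @param cells Data frame with `x_um`, `y_um`, `phase`.
#' @param group `"G1"` or `"G2"`: the group probes are drawn from.
#' @param k_max Largest neighbour order.
#' @param n_samples Number of probe cells (default 1000); when the group
#'   has fewer members, all are used.
#' @param seed Optional seed for the probe sampling.
#' @return Data frame with `order`, `rate` and `se` (standard error of the
#'   rate over probes).
#' @export
in_phase_rate_by_order <- function(cells, group, k_max = 20,
                                   n_samples = 1000, seed = NULL) {
  stopifnot(group %in% c("G1", "G2"))
  cells <- cells[cells$phase %in% c("G1", "G2"), , drop = FALSE]
  n <- nrow(cells)
  if (n < k_max + 1) {
    warning("fewer cells than k_max + 1; truncating order range to ", n - 1)
    k_max <- n - 1
  }
  members <- which(cells$phase == group)
  if (length(members) == 0)
    stop("in_phase_rate_by_order: no cells in group ", group, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probes <- if (length(members) > n_samples)
    sample(members, n_samples) else members
  d <- probe_dist(cells, probes)
  d[cbind(seq_along(probes), probes)] <- Inf   # exclude self
  hits <- matrix(NA, length(probes), k_max)
  for (i in seq_along(probes)) {
    nb <- order(d[i, ])[seq_len(k_max)]
    hits[i, ] <- cells$phase[nb] == group
  }
  rate <- colMeans(hits)
  data.frame(order = seq_len(k_max), rate = rate,
             se = sqrt(rate * (1 - rate) / nrow(hits)))
}

#' In-phase cell rate by neighbourhood radius
#'
#' For sampled probe cells of one group, the fraction of in-phase cells
#' among all other (G1/G2) cells within radius `r` of the probe, averaged
#' over probes, for each radius. Probes with no neighbour within a given
#' radius are skipped at that radius. The decay of this rate towards the
#' group fraction carries the spatial scale of the phase clusters.
#'
#' @inheritParams in_phase_rate_by_order
#' @param radii_um Ascending vector of radii (um).
#' @return Data frame with `radius_um`, `rate`, `se` and `n_probes` (probes
#'   contributing at that radius).
#' @export
in_phase_rate_by_radius <- function(cells, group, radii_um,
                                    n_samples = 1000, seed = NULL) {
  stopifnot(group %in% c("G1", "G2"), all(diff(radii_um) > 0),
            all(radii_um > 0))
  cells <- cells[cells$phase %in% c("G1", "G2"), , drop = FALSE]
  members <- which(cells$phase == group)
  if (length(members) == 0)
    stop("in_phase_rate_by_radius: no cells in group ", group, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probes <- if (length(members) > n_samples)
    sample(members, n_samples) else members
  d <- probe_dist(cells, probes)
  d[cbind(seq_along(probes), probes)] <- Inf
  k_r <- length(radii_um)
  # cumulative neighbour counts per probe within each radius, via binning:
  # findInterval with left-open intervals puts d <= radii[k] into bins < k
  in_phase <- cells$phase == group
  count_within <- function(dv) {
    b <- findInterval(dv, radii_um, left.open = TRUE) + 1L
    b[b > k_r] <- k_r + 1L   # beyond the largest radius (incl. Inf)
    cumsum(tabulate(b, nbins = k_r + 1L))[seq_len(k_r)]
  }
  n_all <- t(apply(d, 1, count_within))
  d_in <- d
  d_in[, !in_phase] <- Inf
  n_in <- t(apply(d_in, 1, count_within))
  use <- n_all > 0
  frac <- ifelse(use, n_in / pmax(n_all, 1L), NA_real_)
  out <- data.frame(radius_um = radii_um,
                    rate = colMeans(frac, na.rm = TRUE),
                    se = apply(frac, 2, stats::sd, na.rm = TRUE) /
                      sqrt(colSums(use)),
                    n_probes = colSums(use))
  out$rate[out$n_probes == 0] <- NA_real_
  out
}

#' Exponential fit of the in-phase rate decay
#'
#' Least-squares fit of `rate(r) = p_inf + A * exp(-r / l)` to the
#' radius-dependent in-phase rate, returning the cluster length `l` (the
#' exponential decay length, in the unit of the radii). The asymptote
#' `p_inf` defaults to a free parameter started at the last observed rate;
#' fixing it to the group fraction is supported via `asymptote`.
#'
#' @param rate_curve Data frame from [in_phase_rate_by_radius()] (columns
#'   `radius_um`, `rate`), or a numeric vector of rates with `radii`
#'   supplied.
#' @param radii Radii when `rate_curve` is a bare vector.
#' @param asymptote Optional fixed asymptote `p_inf`.
#' @return List with `status` (`"ok"` or `"failed"`), `length_um`, `ci`
#'   (95% Wald interval), `p_inf`, `amplitude` and the `fit` object.
#' @export
cluster_length_fit <- function(rate_curve, radii = NULL, asymptote = NULL) {
  if (is.data.frame(rate_curve)) {
    r <- rate_curve$radius_um
    y <- rate_curve$rate
  } else {
    r <- radii
    y <- as.numeric(rate_curve)
  }
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(r) < 4)
    stop("cluster_length_fit: need at least 4 radii", call. = FALSE)
  fail <- list(status = "failed", length_um = NA_real_,
               ci = c(NA_real_, NA_real_), p_inf = NA_real_,
               amplitude = NA_real_, fit = NULL)
  if (y[1] <= y[length(y)] + 1e-12 || stats::sd(y) == 0) return(fail)
  l0 <- max(diff(range(r)) / 3, min(r))
  dat <- data.frame(r = r, y = y)
  fit <- tryCatch({
    if (is.null(asymptote)) {
      minpack.lm::nlsLM(y ~ p + a * exp(-r / l), data = dat,
                        start = list(p = y[length(y)],
                                     a = max(y[1] - y[length(y)], 1e-3),
                                     l = l0),
                        lower = c(p = 0, a = 1e-6, l = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      p_fix <- asymptote
      minpack.lm::nlsLM(y ~ p_fix + a * exp(-r / l), data = dat,
                        start = list(a = max(y[1] - p_fix, 1e-3), l = l0),
                        lower = c(a = 1e-6, l = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  se_l <- tryCatch(summary(fit)$coefficients["l", "Std. Error"],
                   error = function(e) NA_real_)
  list(status = "ok", length_um = unname(cf[["l"]]),
       ci = unname(cf[["l"]]) + c(-1.96, 1.96) * se_l,
       p_inf = if (is.null(asymptote)) unname(cf[["p"]]) else asymptote,
       amplitude = unname(cf[["a"]]), fit = fit)
}
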