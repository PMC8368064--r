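#' Red/green intensity-ratio image
#'
#' Per-pixel ratio of the signal-insensitive (red) to the signal-sensitive
#' (green) channel, so that a cell in the high-signal state has a high
#' ratio. The ratio is defined only where both channels exceed their
#' intensity thresholds; other pixels are `NA`.
#'
#' @param red,green 2-D matrices of equal shape.
#' @param red_min,green_min Intensity thresholds below which a pixel is
#'   considered background and masked.
#' @return Matrix of ratios with `NA` off the validity mask.
#' @export
ratio_image <- function(red, green, red_min = 0, green_min = 0) {
  if (!all(dim(red) == dim(green)))
    stop("ratio_image: channel shapes differ", call. = FALSE)
  mask <- red > red_min & green > green_min
  out <- matrix(NA_real_, nrow(red), ncol(red))
  out[mask] <- red[mask] / green[mask]
  out
}

# Connected components of ratio > threshold, size-filtered.
# Returns data frame frame/x_px/y_px/size_px (centroids 0-based).
ratio_particles <- function(ratio, ratio_threshold, size_min, size_max,
                            frame) {
  bin <- !is.na(ratio) & ratio > ratio_threshold
  if (!any(bin)) {
    return(data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      size_px = integer()))
  }
  lab <- as.matrix(EBImage::bwlabel(bin))
  px <- which(lab > 0)
  ids <- lab[px]
  area <- tabulate(ids)
  rows <- (px - 1L) %% nrow(ratio)
  cols <- (px - 1L) %/% nrow(ratio)
  cx <- as.numeric(rowsum(cols, ids)) / area
  cy <- as.numeric(rowsum(rows, ids)) / area
  keep <- which(area >= size_min & area <= size_max)
  data.frame(frame = rep(frame, length(keep)), x_px = cx[keep],
             y_px = cy[keep], size_px = area[keep])
}

#' Detect high-ratio particles (candidate pulsing cells) in one frame
#'
#' Binarises a ratio image at `ratio_threshold` and keeps connected
#' components of at least `min_size_px` pixels as candidate pulsing cells.
#'
#' @param ratio Ratio matrix from [ratio_image()].
#' @param ratio_threshold Binarisation threshold on the ratio.
#' @param min_size_px Minimum particle size (px).
#' @param frame Frame index recorded with each particle.
#' @param max_size_px Optional upper size bound (default unlimited).
#' @return Data frame with `frame`, `x_px`, `y_px`, `size_px`.
#' @export
detect_active_particles <- function(ratio, ratio_threshold, min_size_px = 10,
                                    frame = 1L, max_size_px = Inf) {
  stopifnot(ratio_threshold > 0, min_size_px > 0)
  ratio_particles(ratio, ratio_threshold, min_size_px, max_size_px, frame)
}

#' Detect candidate pulsing cells across a dual-channel stack
#'
#' Convenience wrapper: builds the per-frame ratio image and runs
#' [detect_active_particles()] on every frame.
#'
#' @param red,green `[T, Y, X]` arrays.
#' @param red_min,green_min Channel intensity thresholds for the ratio mask.
#' @param ratio_threshold,min_size_px See [detect_active_particles()].
#' @return Row-bound particle table over all frames.
#' @export
detect_particles_stack <- function(red, green, red_min = 0, green_min = 0,
                                   ratio_threshold = 1.3, min_size_px = 10) {
  stopifnot(all(dim(red) == dim(green)), length(dim(red)) == 3)
  out <- lapply(seq_len(dim(red)[1]), function(t) {
    rt <- ratio_image(red[t, , ], green[t, , ], red_min, green_min)
    detect_active_particles(rt, ratio_threshold, min_size_px, frame = t)
  })
  do.call(rbind, out)
}

# Greedy nearest-neighbour linking between consecutive frames within
# max_disp (px). A particle unmatched in the next frame ends its track; a
# missed frame is never bridged. Adds a track_id column.
link_nn <- function(particles, max_disp_px) {
  if (nrow(particles) == 0) {
    particles$track_id <- integer()
    return(particles)
  }
  particles <- particles[order(particles$frame), , drop = FALSE]
  particles$track_id <- NA_integer_
  next_id <- 0L
  frames <- sort(unique(particles$frame))
  prev_idx <- integer()
  for (f in frames) {
    cur_idx <- which(particles$frame == f)
    if (length(prev_idx) > 0 &&
        particles$frame[prev_idx[1]] == f - 1L) {
      d <- sqrt(outer(particles$x_px[cur_idx], particles$x_px[prev_idx],
                      `-`)^2 +
                outer(particles$y_px[cur_idx], particles$y_px[prev_idx],
                      `-`)^2)
      d[d > max_disp_px] <- Inf
      while (TRUE) {
        k <- which.min(d)
        if (length(k) == 0 || !is.finite(d[k])) break
        i <- (k - 1) %% length(cur_idx) + 1
        j <- (k - 1) %/% length(cur_idx) + 1
        particles$track_id[cur_idx[i]] <- particles$track_id[prev_idx[j]]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    new <- cur_idx[is.na(particles$track_id[cur_idx])]
    if (length(new) > 0) {
      particles$track_id[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  particles
}

#' Link candidate particles across consecutive frames
#'
#' Particles in consecutive frames within the maximum per-frame migration
#' distance are considered the same cell (greedy nearest-neighbour
#' assignment, closest pairs first). Unmatched particles start new tracks.
#'
#' @param particles Particle table (`frame`, `x_px`, `y_px`, ...).
#' @param max_disp_um Maximum displacement between consecutive frames (um);
#'   default 16.5 um.
#' @param pitch_um Pixel pitch (um/px).
#' @return `particles` with an added `track_id` column.
#' @export
link_particles <- function(particles, max_disp_um = 16.5, pitch_um = 1.1) {
  stopifnot(max_disp_um > 0, pitch_um > 0)
  link_nn(particles, max_disp_um / pitch_um)
}

#' Screen out single-frame candidates and emit pulse events
#'
#' A candidate present in only one frame is treated as a detection error,
#' since a true pulsing cell stays elevated across consecutive frames.
#' Every surviving track emits one pulse event at its first (onset) frame,
#' positioned at the track's first centroid.
#'
#' @param tracks Linked particle table from [link_particles()].
#' @param pitch_um Pixel pitch for physical event coordinates.
#' @param min_track_len Minimum frames a track must span (default 2).
#' @return Data frame of pulse events: `event_id`, `track_id`, `frame`,
#'   `x_px`, `y_px`, `x_um`, `y_um`, `track_len`.
#' @export
screen_single_frame <- function(tracks, pitch_um = 1.1, min_track_len = 2) {
  if (nrow(tracks) == 0 || !"track_id" %in% names(tracks))
    stop("screen_single_frame: expected linked particles with track_id",
         call. = FALSE)
  len <- table(tracks$track_id)
  keep <- as.integer(names(len)[len >= min_track_len])
  tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  if (nrow(tracks) == 0) {
    return(data.frame(event_id = integer(), track_id = integer(),
                      frame = integer(), x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      track_len = integer()))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  first <- !duplicated(tracks$track_id)
  ev <- tracks[first, c("track_id", "frame", "x_px", "y_px"), drop = FALSE]
  ev$x_um <- ev$x_px * pitch_um
  ev$y_um <- ev$y_px * pitch_um
  ev$track_len <- as.integer(len[as.character(ev$track_id)])
  ev <- ev[order(ev$frame, ev$track_id), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev[, c("event_id", "track_id", "frame", "x_px", "y_px", "x_um", "y_um",
         "track_len")]
}

#' Infer the pulse-propagation tree network
#'
#' For every pulse event, later events within frame lag `F = 1..fmax` and
#' distance at most `sqrt(F) * dprime_um` are its candidate children (the
#' reach grows with the square root of the lag, a pseudo-diffusive
#' spreading law). A child may satisfy the reach criterion for several
#' earlier events; all candidate links are recorded, and one primary parent
#' per child is designated deterministically by smallest lag, then smallest
#' distance, then lowest parent event id, so the primary links always form
#' a forest.
#'
#' @param events Pulse-event table from [screen_single_frame()] (needs
#'   `event_id`, `frame`, `x_um`, `y_um`), or any table in that schema.
#' @param dprime_um Pseudo-diffusion coefficient: reach per square-root
#'   frame lag (um); default 250.
#' @param fmax Sustainment time: maximum lag in frames; default 3.
#' @return Data frame of links: `parent`, `child`, `lag`, `dist_um`,
#'   `primary` (logical). Zero rows when no link exists.
#' @export
build_tree <- function(events, dprime_um = 250, fmax = 3) {
  stopifnot(dprime_um > 0, fmax >= 1)
  empty <- data.frame(parent = integer(), child = integer(), lag = integer(),
                      dist_um = numeric(), primary = logical())
  n <- nrow(events)
  if (n < 2) return(empty)
  events <- events[order(events$frame, events$event_id), , drop = FALSE]
  links <- vector("list", n)
  for (i in seq_len(n)) {
    lag <- events$frame - events$frame[i]
    cand <- which(lag >= 1 & lag <= fmax)
    if (length(cand) == 0) next
    d <- sqrt((events$x_um[cand] - events$x_um[i])^2 +
              (events$y_um[cand] - events$y_um[i])^2)
    ok <- d <= sqrt(lag[cand]) * dprime_um
    if (!any(ok)) next
    links[[i]] <- data.frame(parent = events$event_id[i],
                             child = events$event_id[cand[ok]],
                             lag = lag[cand[ok]], dist_um = d[ok])
  }
  links <- links[!vapply(links, is.null, logical(1))]
  if (length(links) == 0) return(empty)
  links <- do.call(rbind, links)
  ord <- order(links$child, links$lag, links$dist_um, links$parent)
  links <- links[ord, , drop = FALSE]
  links$primary <- !duplicated(links$child)
  rownames(links) <- NULL
  links
}

#' Identify wave-origin cells in a propagation forest
#'
#' An origin is an event that is nobody's child (it has no candidate parent
#' at all) and has at least one primary child: a cell whose pulse started a
#' relay. A solitary pulse with neither parent nor child is pulsing but not
#' an origin.
#'
#' @param events Pulse-event table (`event_id`, ...).
#' @param links Link table from [build_tree()].
#' @return The subset of `events` that are wave origins.
#' @export
find_wave_origins <- function(events, links) {
  if (nrow(events) == 0) return(events[0, , drop = FALSE])
  has_parent <- events$event_id %in% links$child
  has_child <- events$event_id %in% links$parent[links$primary]
  events[!has_parent & has_child, , drop = FALSE]
}

#' Quadrat estimate of the total cell count
#'
#' Scales a count made in a small compartment (quadrat) to the full field
#' of view, assuming spatially uniform density:
#' `count * fov_area / quadrat_area`.
#'
#' @param count Cells counted in the quadrat.
#' @param quadrat_area Quadrat area.
#' @param fov_area Full field area (same unit; must be >= quadrat_area).
#' @return Estimated total count.
#' @export
quadrat_estimate <- function(count, quadrat_area, fov_area) {
  stopifnot(count >= 0, quadrat_area > 0, fov_area >= quadrat_area)
  count * fov_area / quadrat_area
}
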