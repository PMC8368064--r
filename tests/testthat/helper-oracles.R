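# Independent oracles used across test files.

# Brute-force all-pairs mean nearest-neighbour distance.
brute_force_ann <- function(points) {
  n <- nrow(points)
  if (n < 2) return(NA_real_)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((points[i, 1] - points[j, 1])^2 +
                (points[i, 2] - points[j, 2])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}

# Render a filled disk of radius r at (y0, x0) into an image.
draw_disk <- function(img, y0, x0, r, value = 1) {
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    if ((y - y0)^2 + (x - x0)^2 <= r^2) img[y, x] <- img[y, x] + value
  }
  img
}

# Match detected events one-to-one to truth events at exact frame and
# within dist_um; returns the detected event_id for each truth row (NA if
# unmatched).
match_events_exact <- function(detected, truth, dist_um = 8) {
  m <- rep(NA_integer_, nrow(truth))
  taken <- integer()
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected$x_um - truth$x_um[i])^2 +
              (detected$y_um - truth$y_um[i])^2)
    ok <- which(d < dist_um & detected$frame == truth$frame[i] &
                !(detected$event_id %in% taken))
    if (length(ok)) {
      m[i] <- detected$event_id[ok[which.min(d[ok])]]
      taken <- c(taken, m[i])
    }
  }
  m
}
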