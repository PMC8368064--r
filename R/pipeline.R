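# Orchestration and I/O plumbing: TIFF stack reading/writing, YAML run
# configuration, and a stage dispatcher that writes CSV results plus a
# machine-readable run manifest.

#' Read a grayscale TIFF stack
#'
#' Reads a 2-D or multi-frame grayscale TIFF into a `[T, Y, X]` array.
#' Pixel pitch and frame interval are taken from the arguments (typically
#' the run config); values embedded in the file are not trusted, and a
#' conflict between the two would be resolved in favour of the config.
#'
#' @param path Path to a TIFF/OME-TIFF file.
#' @param pitch_um Pixel pitch (um/px), attached as attribute `pitch_um`.
#' @param interval_s Frame interval (s), attached as attribute
#'   `interval_s`.
#' @return Numeric array `[T, Y, X]` with attributes `pitch_um` and
#'   `interval_s`.
#' @export
read_stack <- function(path, pitch_um = NA_real_, interval_s = NA_real_) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) > 2, logical(1))))
    stop("read_stack: RGB/multi-sample TIFF is not a grayscale stack",
         call. = FALSE)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  stack <- array(NA_real_, c(length(frames), ny, nx))
  for (t in seq_along(frames)) stack[t, , ] <- frames[[t]]
  attr(stack, "pitch_um") <- pitch_um
  attr(stack, "interval_s") <- interval_s
  stack
}

#' Write a stack or image as multi-frame grayscale TIFF
#'
#' Intensities are written as 16-bit; the stack is scaled by `scale` (use
#' 1 for data already in [0, 65535]).
#'
#' @param stack `[T, Y, X]` array or a 2-D matrix.
#' @param path Output path.
#' @param scale Divisor applied before writing (written values are
#'   `stack / scale`, clipped to [0, 1] in TIFF terms after division by
#'   65535).
#' @export
write_stack <- function(stack, path, scale = 65535) {
  if (is.matrix(stack)) stack <- array(stack, c(1, dim(stack)))
  frames <- lapply(seq_len(dim(stack)[1]), function(t) {
    f <- stack[t, , ] / scale
    f[f < 0] <- 0
    f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file with optional blocks `optics`,
#'   `nuclei`, `calcium`, `dicty`, `entosis`, `simulate` and top-level
#'   `seed`, `output_dir`.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "run_config")
}

# default-filling lookup with error naming the missing key
cfg_get <- function(cfg, block, key, default = NULL) {
  val <- cfg[[block]][[key]]
  if (is.null(val)) {
    if (is.null(default))
      stop("run config: missing required key ", block, "$", key,
           call. = FALSE)
    val <- default
  }
  val
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches to the named stage, writes its result tables as CSV into
#' `output_dir` and a JSON manifest (`manifest.json`) recording the stage,
#' seed, parameters and package version. Stages:
#' \describe{
#'   \item{flatfield}{divide `input` by `reference`, write corrected TIFF}
#'   \item{nuclei}{segment nuclei, build the phase model, classify, write
#'     per-cell CSV and in-phase rate curves}
#'   \item{calcium}{detect pulsing cells, write events CSV, per-frame ANN
#'     CSV and flagged frames}
#'   \item{dicty}{detect/link/screen pulsing cells, build the propagation
#'     tree, write events, links and origins CSV}
#'   \item{entosis}{detect/link red particles, classify entosis, write
#'     entosis and occurrence CSV}
#'   \item{simulate}{generate a synthetic scenario (`scenario:` key) and
#'     write its stacks and truth tables}
#' }
#'
#' @param cfg A `run_config` from [read_run_config()], or a list in the
#'   same shape.
#' @param stage One of the stage names above.
#' @return Invisibly, a named list of the result objects (also written to
#'   disk).
#' @export
run_pipeline <- function(cfg, stage = c("flatfield", "nuclei", "calcium",
                                        "dicty", "entosis", "simulate")) {
  stage <- match.arg(stage)
  out_dir <- cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  pitch <- cfg$optics$pitch_um %||% 1.1
  interval <- cfg$optics$interval_s %||%
    switch(stage, calcium = 5, 30)
  res <- switch(stage,
    flatfield = {
      raw <- read_stack(cfg_get(cfg, stage, "input"), pitch)
      ref <- read_stack(cfg_get(cfg, stage, "reference"), pitch)
      corr <- array(NA_real_, dim(raw))
      for (t in seq_len(dim(raw)[1]))
        corr[t, , ] <- flatfield_correct(raw[t, , ], ref[1, , ])
      write_stack(corr, file.path(out_dir, "corrected.tif"))
      list(corrected_path = file.path(out_dir, "corrected.tif"))
    },
    nuclei = {
      img <- read_stack(cfg_get(cfg, stage, "input"), pitch)[1, , ]
      cells <- segment_nuclei(
        img, threshold = cfg_get(cfg, stage, "threshold", "otsu"),
        size_min_px = cfg_get(cfg, stage, "size_min", 5),
        size_max_px = cfg_get(cfg, stage, "size_max", 500),
        pitch_um = pitch)
      model <- intensity_histogram(cells)
      rates <- NULL
      if (model$status == "ok") {
        cells <- classify_phase(cells, model,
                                g1_scale = raw_g1_peak(cells$intensity))
        radii <- cfg_get(cfg, stage, "radii", seq(10, 150, by = 10))
        rates <- lapply(c(G1 = "G1", G2 = "G2"), function(g)
          in_phase_rate_by_radius(cells, g, radii, seed = seed))
        for (g in names(rates))
          utils::write.csv(rates[[g]],
                           file.path(out_dir, paste0("rate_", g, ".csv")),
                           row.names = FALSE)
      }
      utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                       row.names = FALSE)
      list(cells = cells, model = model, rates = rates)
    },
    calcium = {
      stk <- read_stack(cfg_get(cfg, stage, "input"), pitch, interval)
      events <- detect_pulsing_cells(
        stk, pitch_um = pitch,
        skew_threshold = cfg_get(cfg, stage, "skew_threshold", 1),
        noise_k = cfg_get(cfg, stage, "noise_k", 5),
        poly_order = cfg_get(cfg, stage, "poly_order", 3))
      geom <- field_geometry(dim(stk)[3] * pitch, dim(stk)[2] * pitch)
      pts <- split(data.frame(x = events$x_um, y = events$y_um),
                   factor(events$frame, levels = seq_len(dim(stk)[1])))
      ann <- ann_series(lapply(pts, as.matrix), geom)
      flagged <- flag_clustered_frames(ann)
      utils::write.csv(events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
      utils::write.csv(ann, file.path(out_dir, "ann.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(frame = flagged),
                       file.path(out_dir, "flagged_frames.csv"),
                       row.names = FALSE)
      list(events = events, ann = ann, flagged = flagged)
    },
    dicty = {
      red <- read_stack(cfg_get(cfg, stage, "red"), pitch, interval)
      green <- read_stack(cfg_get(cfg, stage, "green"), pitch, interval)
      parts <- detect_particles_stack(
        red, green,
        red_min = cfg_get(cfg, stage, "red_min", 0),
        green_min = cfg_get(cfg, stage, "green_min", 0),
        ratio_threshold = cfg_get(cfg, stage, "ratio_threshold", 1.3),
        min_size_px = cfg_get(cfg, stage, "min_size", 10))
      tracks <- link_particles(parts,
                               cfg_get(cfg, stage, "max_disp_um", 16.5),
                               pitch)
      events <- screen_single_frame(tracks, pitch)
      links <- build_tree(events,
                          dprime_um = cfg_get(cfg, stage, "dprime_um", 250),
                          fmax = cfg_get(cfg, stage, "fmax", 3))
      origins <- find_wave_origins(events, links)
      utils::write.csv(events, file.path(out_dir, "pulse_events.csv"),
                       row.names = FALSE)
      utils::write.csv(links, file.path(out_dir, "tree_links.csv"),
                       row.names = FALSE)
      utils::write.csv(origins, file.path(out_dir, "origins.csv"),
                       row.names = FALSE)
      list(events = events, links = links, origins = origins)
    },
    entosis = {
      red <- read_stack(cfg_get(cfg, stage, "red"), pitch, interval)
      green <- read_stack(cfg_get(cfg, stage, "green"), pitch, interval)
      parts <- do.call(rbind, lapply(seq_len(dim(red)[1]), function(t) {
        rt <- ratio_image(red[t, , ], green[t, , ],
                          cfg_get(cfg, stage, "red_min", 0),
                          cfg_get(cfg, stage, "green_min", 0))
        detect_red_particles(rt,
                             cfg_get(cfg, stage, "ratio_threshold", 1.3),
                             cfg_get(cfg, stage, "size_min", 3),
                             cfg_get(cfg, stage, "size_max", 100),
                             frame = t)
      }))
      tracks <- link_red_particles(parts,
                                   cfg_get(cfg, stage, "max_disp_um", 11),
                                   pitch)
      ent <- classify_entosis(tracks,
                              min_frames = cfg_get(cfg, stage,
                                                   "min_frames", 11),
                              frame_interval_s = interval,
                              pitch_um = pitch)
      occ <- occurrence_series(ent, dim(red)[1])
      utils::write.csv(ent, file.path(out_dir, "entosis.csv"),
                       row.names = FALSE)
      utils::write.csv(occ$per_frame, file.path(out_dir, "occurrence.csv"),
                       row.names = FALSE)
      list(entosis = ent, occurrence = occ)
    },
    simulate = {
      scen <- cfg_get(cfg, stage, "scenario")
      args <- cfg[[stage]]
      args$scenario <- NULL
      args$seed <- seed
      gen <- switch(scen,
                    nuclei = generate_nuclei_scene,
                    calcium = generate_calcium_movie,
                    dicty = generate_dicty_movie,
                    stop("unknown scenario: ", scen, call. = FALSE))
      sim <- do.call(gen, args)
      if (!is.null(sim$image))
        write_stack(sim$image * 1000, file.path(out_dir, "scene.tif"))
      if (!is.null(sim$stack))
        write_stack(sim$stack, file.path(out_dir, "movie.tif"), scale = 4096)
      if (!is.null(sim$red)) {
        write_stack(sim$red, file.path(out_dir, "red.tif"), scale = 4096)
        write_stack(sim$green, file.path(out_dir, "green.tif"),
                    scale = 4096)
      }
      truths <- if (is.data.frame(sim$truth)) list(truth = sim$truth)
                else sim$truth
      if (!is.null(sim$cells)) truths$cells <- sim$cells
      for (nm in names(truths))
        utils::write.csv(truths[[nm]],
                         file.path(out_dir, paste0("truth_", nm, ".csv")),
                         row.names = FALSE)
      sim["params"]
    })
  manifest <- list(stage = stage, seed = seed,
                   parameters = cfg[[stage]],
                   pitch_um = pitch, interval_s = interval,
                   package_version = as.character(
                     utils::packageVersion("rarecell")),
                   config_path = cfg$config_path %||% NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# position of the lower (G1) density peak on the raw intensity scale
raw_g1_peak <- function(intensities) {
  m <- intensity_histogram(intensities, normalize_to_g1 = FALSE)
  if (m$status == "ok") m$g1_peak else stats::median(intensities)
}
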