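# Synthetic imaging fixtures: 3D rod-field z-stacks (for the z-stack
# segmenter) and 2D filament movies (for the tracer/tracker), both with
# full ground truth.

# Pixel set of a filled disk, clipped to the image frame.
disk_pixels <- function(cx, cy, radius, nrow, ncol) {
  r0 <- max(1, floor(cy - radius)); r1 <- min(nrow, ceiling(cy + radius))
  c0 <- max(1, floor(cx - radius)); c1 <- min(ncol, ceiling(cx + radius))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate a 3D rod-field z-stack
#'
#' Builds a z-stack of straight fluorescent rods emanating from the base
#' plane at random tilt, each voxelized as a disk per plane, blurred with
#' a Gaussian PSF and optionally noised. Rods whose requested extent
#' exceeds the stack are clipped and flagged.
#'
#' @param n_rods Number of rods (0 allowed).
#' @param z_planes Number of z planes (>= 2).
#' @param psf_sigma_px PSF sigma, pixels (0 disables blurring).
#' @param noise_sd Additive Gaussian noise SD, in units of `amplitude`.
#' @param seed Integer seed.
#' @param dim Image dimensions `c(rows, cols)`, pixels.
#' @param px_size_um Lateral pixel size, um.
#' @param z_step_um Axial plane spacing, um.
#' @param rod_radius_px Rod (and base) radius, pixels.
#' @param max_tilt_deg Maximum tilt from the optical axis, degrees.
#' @param length_um Rod lengths, um; a scalar or vector recycled over
#'   rods; `NULL` draws uniform lengths spanning most of the stack depth.
#' @param amplitude,background Signal and background levels.
#' @param min_separation_px Minimum distance between base centroids
#'   (default 3 base diameters, so bases stay resolvable).
#' @return A `synthetic_scene` with `kind = "rod_stack"`, `stack` (array
#'   rows x cols x planes), `ground_truth` (data.frame of base centroid,
#'   base area, tip position, length, clipped flag) and geometry metadata.
#' @export
gen_rod_stack <- function(n_rods, z_planes, psf_sigma_px = 1, noise_sd = 0,
                          seed = 1L, dim = c(64, 64), px_size_um = 0.1487,
                          z_step_um = 0.5, rod_radius_px = 2,
                          max_tilt_deg = 15, length_um = NULL,
                          amplitude = 1, background = 0.05,
                          min_separation_px = 6 * rod_radius_px) {
  stopifnot(z_planes >= 2, n_rods >= 0)
  nr <- dim[1]; nc <- dim[2]
  stack <- array(background, c(nr, nc, z_planes))
  max_len_um <- (z_planes - 1) * z_step_um / cos(max_tilt_deg * pi / 180)
  withr::with_seed(seed, {
    # rejection-sample base positions with minimum separation
    margin <- rod_radius_px + 4
    bases <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(bases) < n_rods && tries < 10000) {
      cand <- c(stats::runif(1, margin, nc - margin),
                stats::runif(1, margin, nr - margin))
      if (nrow(bases) == 0 ||
          min(sqrt((bases[, 1] - cand[1])^2 + (bases[, 2] - cand[2])^2)) >=
          min_separation_px)
        bases <- rbind(bases, cand)
      tries <- tries + 1
    }
    if (nrow(bases) < n_rods) stop("could not place rods with the requested separation")
    if (is.null(length_um))
      lens <- stats::runif(n_rods, 0.5 * max_len_um, 1.2 * max_len_um)
    else lens <- rep_len(length_um, n_rods)
    tilt <- stats::runif(n_rods, 0, max_tilt_deg) * pi / 180
    azim <- stats::runif(n_rods, 0, 2 * pi)
    gt <- NULL
    for (k in seq_len(max(n_rods, 0))) {
      # direction in um units; dz per plane step fixed at z_step_um
      n_steps <- if (lens[k] == 0) 0 else
        floor(lens[k] * cos(tilt[k]) / z_step_um)
      clipped <- n_steps > (z_planes - 1)
      n_steps_used <- min(n_steps, z_planes - 1)
      len_used <- if (clipped) (z_planes - 1) * z_step_um / cos(tilt[k])
        else lens[k]
      # lateral drift per plane, pixels
      lat_per_plane <- tan(tilt[k]) * z_step_um / px_size_um
      dx <- lat_per_plane * cos(azim[k]); dy <- lat_per_plane * sin(azim[k])
      base_px <- disk_pixels(bases[k, 1], bases[k, 2], rod_radius_px, nr, nc)
      for (z in 0:n_steps_used) {
        px <- disk_pixels(bases[k, 1] + dx * z, bases[k, 2] + dy * z,
                          rod_radius_px, nr, nc)
        stack[cbind(px, z + 1)] <- amplitude
      }
      gt <- rbind(gt, data.frame(
        rod = k, base_x_px = bases[k, 1], base_y_px = bases[k, 2],
        base_area_px2 = nrow(base_px),
        tip_x_px = bases[k, 1] + dx * n_steps_used,
        tip_y_px = bases[k, 2] + dy * n_steps_used,
        tip_plane = n_steps_used + 1L,
        length_um = len_used, clipped = clipped))
    }
    if (psf_sigma_px > 0)
      for (z in seq_len(z_planes))
        stack[, , z] <- EBImage::gblur(stack[, , z], sigma = psf_sigma_px)
    if (noise_sd > 0)
      stack <- stack + array(stats::rnorm(length(stack),
                                          sd = noise_sd * amplitude),
                             base::dim(stack))
    structure(
      list(kind = "rod_stack", stack = stack, ground_truth = gt,
           px_size_um = px_size_um, z_step_um = z_step_um,
           rod_radius_px = rod_radius_px, seed = seed),
      class = "synthetic_scene"
    )
  })
}

# Pixel chain of a gently curved filament: arc-length parametrized curve
# starting at the anchor, with direction rotating by `curvature` rad/px.
filament_curve <- function(anchor, angle, length_px, curvature, nr, nc,
                           step = 0.5) {
  s <- seq(0, max(length_px, step), by = step)
  ang <- angle + curvature * s
  x <- anchor[1] + cumsum(c(0, diff(s)) * cos(ang))
  y <- anchor[2] + cumsum(c(0, diff(s)) * sin(ang))
  inside <- x >= 2 & x <= nc - 1 & y >= 2 & y <= nr - 1
  if (!all(inside)) {
    cut <- which(!inside)[1] - 1
    if (cut < 2) cut <- 2
    x <- x[seq_len(cut)]; y <- y[seq_len(cut)]; s <- s[seq_len(cut)]
  }
  px <- unique(cbind(row = round(y), col = round(x)))
  list(pixels = px, arc_length_px = s[length(s)],
       tip = c(x[length(x)], y[length(y)]))
}

#' Generate a 2D filament movie with ground-truth tracks
#'
#' Renders `n_filaments` curvilinear filaments anchored at fixed bases,
#' whose lengths evolve according to the sum-of-products growth model, as
#' a 2D time-lapse. Returns per-frame ground-truth skeletons and
#' identities, a partial "manual annotation" mask set (a fraction of
#' frames, mimicking a human-traced training subset), and optionally a
#' broken track table in which a fraction of tracks is split into
#' fragments (base displacement < 1 um, gaps <= 6 frames) for testing
#' track repair.
#'
#' @param n_filaments Number of filaments.
#' @param frames Number of frames (>= 5).
#' @param growth_model A [growth_model_params()]; drives length dynamics.
#' @param break_frac Fraction of tracks to split artificially.
#' @param seed Integer seed.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param px_size_um Pixel size, um (default 0.1487).
#' @param frame_interval_s Frame interval, seconds.
#' @param base_length_px Mean resting filament length, pixels.
#' @param curvature Maximum curve rate magnitude, radians per pixel of
#'   arc length; each filament draws its own curvature uniformly.
#' @param line_width_px Rendered filament width.
#' @param noise_sd Additive Gaussian noise SD (signal amplitude is 1).
#' @param annotate_frac Fraction of frames exported as annotated labels.
#' @param max_gap Maximum injected gap length, frames.
#' @return A `synthetic_scene` with `kind = "filament_movie"`: `movie`
#'   (rows x cols x frames array), `skeletons` (per frame, per filament
#'   pixel chains), `tracks` (intact ground-truth track table with
#'   `track_id`, `frame`, `cx`, `cy`, `x_um`, `y_um`, `length_px`,
#'   `arc_length_px`), `broken_tracks`, `breaks`, `annotated_frames`,
#'   `annotations`, and geometry metadata.
#' @export
gen_filament_movie <- function(n_filaments = 5, frames = 30,
                               growth_model = growth_model_params(duration = frames * frame_interval_s / 60 + 1),
                               break_frac = 0, seed = 1L, dim = c(128, 128),
                               px_size_um = 0.1487, frame_interval_s = 15,
                               base_length_px = 30, curvature = 0.003,
                               line_width_px = 2, noise_sd = 0,
                               annotate_frac = 0.2, max_gap = 6) {
  stopifnot(frames >= 5, n_filaments >= 1, break_frac >= 0, break_frac <= 1)
  nr <- dim[1]; nc <- dim[2]
  frame_times_min <- (seq_len(frames) - 1) * frame_interval_s / 60
  sim <- gen_trajectory_set(growth_model, n_filaments, initiation_window = 0)
  # sample model lengths (um) at frame times; convert to px around the base
  # resting length
  idx <- vapply(frame_times_min,
                function(tm) which.min(abs(sim$times - tm)), integer(1))
  dyn_px <- sim$lengths[, idx, drop = FALSE] / px_size_um
  withr::with_seed(seed + 17L, {
    # anchors spaced along the bottom edge, filaments pointing up with
    # slight angular jitter: emulates a leading-edge field of well
    # separated filopodia whose identities stay resolvable
    ax <- (seq_len(n_filaments) - 0.5) * nc / n_filaments
    anchors <- cbind(ax, rep(nr - 5, n_filaments))
    angles <- -pi / 2 + stats::runif(n_filaments, -0.08, 0.08)
    curvatures <- stats::runif(n_filaments, -curvature, curvature)
    movie <- array(0, c(nr, nc, frames))
    skeletons <- vector("list", frames)
    tracks <- NULL
    for (fr in seq_len(frames)) {
      chains <- vector("list", n_filaments)
      for (k in seq_len(n_filaments)) {
        len <- base_length_px + dyn_px[k, fr]
        cur <- filament_curve(anchors[k, ], angles[k], len, curvatures[k],
                              nr, nc)
        chains[[k]] <- cur$pixels
        movie[cbind(cur$pixels, fr)] <- 1
        if (line_width_px > 1) {
          for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            sh <- cbind(cur$pixels[, 1] + off[1], cur$pixels[, 2] + off[2])
            keep <- sh[, 1] >= 1 & sh[, 1] <= nr & sh[, 2] >= 1 & sh[, 2] <= nc
            movie[cbind(sh[keep, , drop = FALSE], fr)] <- 1
          }
        }
        tracks <- rbind(tracks, data.frame(
          track_id = k, frame = fr,
          cx = mean(cur$pixels[, 2]), cy = mean(cur$pixels[, 1]),
          x_um = anchors[k, 1] * px_size_um, y_um = anchors[k, 2] * px_size_um,
          length_px = len, arc_length_px = cur$arc_length_px))
      }
      skeletons[[fr]] <- chains
    }
    clean <- movie
    if (noise_sd > 0)
      movie <- movie + array(stats::rnorm(length(movie), sd = noise_sd),
                             base::dim(movie))
    n_ann <- max(1, round(annotate_frac * frames))
    annotated_frames <- sort(unique(round(seq(1, frames,
                                              length.out = n_ann))))
    # annotations mark every rendered filament pixel (the full-width
    # structure a human would trace), not just the 1-px centreline
    annotations <- lapply(annotated_frames, function(fr)
      clean[, , fr] > 0.5)
    # inject artificial breaks into a copy of the track table
    broken <- tracks
    breaks <- NULL
    n_break <- round(break_frac * n_filaments)
    if (n_break > 0) {
      victims <- sample(seq_len(n_filaments), n_break)
      next_id <- n_filaments
      for (vid in victims) {
        # a gap of g means the fragment restarts g frames after the first
        # fragment ends (g - 1 frames are deleted); g <= 6 stays repairable
        gap <- sample(seq_len(max_gap), 1)
        lo <- 3; hi <- frames - gap - 1
        if (hi < lo) next
        split_at <- if (lo == hi) lo else sample(lo:hi, 1)
        drop <- broken$track_id == vid & broken$frame >= split_at &
          broken$frame < split_at + gap - 1
        broken <- broken[!drop, ]
        next_id <- next_id + 1L
        relabel <- broken$track_id == vid & broken$frame >= split_at + gap - 1
        broken$track_id[relabel] <- next_id
        breaks <- rbind(breaks, data.frame(
          original = vid, fragment = next_id,
          split_frame = split_at, gap = gap))
      }
    }
    structure(
      list(kind = "filament_movie", movie = movie, skeletons = skeletons,
           tracks = tracks, broken_tracks = broken, breaks = breaks,
           annotated_frames = annotated_frames, annotations = annotations,
           ground_truth = list(model = growth_model, anchors = anchors,
                               angles = angles, base_length_px = base_length_px,
                               dyn_px = dyn_px),
           px_size_um = px_size_um, frame_interval_s = frame_interval_s,
           seed = seed),
      class = "synthetic_scene"
    )
  })
}
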