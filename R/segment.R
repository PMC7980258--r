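# Z-stack segmentation of filopodia-like structures: per-plane
# difference-of-Gaussians detection, greedy tracing through z, and
# morphology/intensity measurement with ring background correction.

# Per-plane DoG candidates: centroids and pixel sets of thresholded
# connected components.
dog_candidates <- function(plane, dog_sigma, dog_k,
                           threshold_method = c("otsu", "quantile"),
                           quantile = 0.99) {
  threshold_method <- match.arg(threshold_method)
  dog <- EBImage::imageData(EBImage::gblur(plane, sigma = dog_sigma)) -
    EBImage::imageData(EBImage::gblur(plane, sigma = dog_sigma * dog_k))
  rng <- range(dog)
  if (diff(rng) <= 0)
    return(list(centroids = matrix(numeric(0), ncol = 2), pixels = list()))
  norm <- (dog - rng[1]) / diff(rng)
  thr <- if (threshold_method == "otsu")
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    else stats::quantile(norm, quantile, names = FALSE)
  mask <- norm > thr
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n_obj <- max(lab)
  if (n_obj == 0)
    return(list(centroids = matrix(numeric(0), ncol = 2), pixels = list()))
  cents <- matrix(NA_real_, n_obj, 2)
  pix <- vector("list", n_obj)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  for (o in seq_len(n_obj)) {
    p <- idx[labs == o, , drop = FALSE]
    pix[[o]] <- p
    cents[o, ] <- c(mean(p[, 2]), mean(p[, 1]))     # (x, y) in pixels
  }
  list(centroids = cents, pixels = pix)
}

#' Segment filopodia-like structures in a z-stack
#'
#' Detects candidate positions independently in every XY plane with a 2D
#' difference-of-Gaussians filter (\eqn{G(\sigma) - G(k\sigma)}) followed
#' by thresholding and connected components, then traces each base-plane
#' candidate greedily through z: at every plane the trace extends to the
#' nearest candidate strictly within `max_trace_radius` (so a radius of 0
#' disables tracing entirely), stopping when none remains. Objects traced
#' through fewer than `min_planes` planes are discarded.
#'
#' @param stack Numeric array (rows x cols x planes, >= 2 planes).
#' @param dog_sigma DoG inner sigma, pixels.
#' @param dog_k Outer/inner sigma ratio (> 1).
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param min_planes Minimum traced planes per retained object.
#' @param max_trace_radius Greedy tracing radius, pixels.
#' @param base_plane Index of the base plane.
#' @param px_size_um,z_step_um Pixel geometry for physical lengths.
#' @param quantile Threshold quantile when `threshold_method = "quantile"`.
#' @return List of `fls_object`s, each with `base_centroid` (x, y, px),
#'   `base_pixels`, `centroids` (per traced plane), `planes`,
#'   `length_path_um`, `length_straight_um`, `straightness`.
#' @export
segment_fls_stack <- function(stack, dog_sigma = 1.5, dog_k = 2,
                              threshold_method = "otsu", min_planes = 2,
                              max_trace_radius = 3, base_plane = 1,
                              px_size_um = 0.1487, z_step_um = 0.5,
                              quantile = 0.99) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2, dog_k > 1)
  n_planes <- dim(stack)[3]
  if (base_plane < 1 || base_plane > n_planes)
    stop("base_plane outside the stack")
  cands <- lapply(seq_len(n_planes), function(z)
    dog_candidates(stack[, , z], dog_sigma, dog_k, threshold_method,
                   quantile))
  base <- cands[[base_plane]]
  objects <- list()
  for (o in seq_len(nrow(base$centroids))) {
    path <- base$centroids[o, , drop = FALSE]
    pos <- base$centroids[o, ]
    z <- base_plane
    while (z < n_planes) {
      nxt <- cands[[z + 1]]$centroids
      if (nrow(nxt) == 0) break
      d <- sqrt((nxt[, 1] - pos[1])^2 + (nxt[, 2] - pos[2])^2)
      j <- which.min(d)                    # ties: first = detection order
      if (d[j] >= max_trace_radius) break  # strictly within the radius
      pos <- nxt[j, ]
      path <- rbind(path, pos)
      z <- z + 1
    }
    if (nrow(path) < min_planes) next
    steps_um <- cbind(diff(path[, 1]) * px_size_um,
                      diff(path[, 2]) * px_size_um,
                      rep(z_step_um, max(nrow(path) - 1, 0)))
    length_path <- sum(sqrt(rowSums(steps_um^2)))
    d_lat <- (path[nrow(path), ] - path[1, ]) * px_size_um
    length_straight <- sqrt(sum(d_lat^2) +
                              ((nrow(path) - 1) * z_step_um)^2)
    objects[[length(objects) + 1]] <- structure(
      list(base_centroid = base$centroids[o, ],
           base_pixels = base$pixels[[o]],
           centroids = path, planes = base_plane:(base_plane + nrow(path) - 1),
           length_path_um = length_path,
           length_straight_um = length_straight,
           straightness = if (length_path > 0) length_straight / length_path
             else NA_real_),
      class = "fls_object")
  }
  objects
}

#' Measure morphology and channel intensities of a segmented structure
#'
#' Computes base area, effective diameter and straightness, plus mean
#' intensity inside the base and a ring background (over radii
#' `ring_inner` to `ring_outer` times the base-equivalent radius,
#' excluding every pixel belonging to any structure base) for each
#' supplied channel image, optionally after a translation registration
#' shift.
#'
#' @param object An `fls_object` from [segment_fls_stack()].
#' @param channel_images Named list of 2D base-slice images.
#' @param all_base_pixels Optional matrix of every base pixel in the field
#'   (rows = pixels, cols = row/col), used to exclude neighbouring bases
#'   from the ring; defaults to the object's own base.
#' @param registration_shift Integer `c(dx, dy)` translation applied to
#'   channel coordinates.
#' @param ring_inner,ring_outer Ring radii in units of the base-equivalent
#'   radius.
#' @param px_size_um Pixel size, um.
#' @param fov,structure_id,frame Identifiers copied into the record.
#' @return A one-row FLS record data.frame with raw, background and
#'   corrected intensity per channel (`NA` when the ring is fully
#'   occluded).
#' @export
measure_fls <- function(object, channel_images, all_base_pixels = NULL,
                        registration_shift = c(0, 0), ring_inner = 2,
                        ring_outer = 3, px_size_um = 0.1487,
                        fov = 1L, structure_id = 1L, frame = 1L) {
  stopifnot(inherits(object, "fls_object"))
  base_px <- object$base_pixels
  n_base <- nrow(base_px)
  area_um2 <- n_base * px_size_um^2
  r_eq <- sqrt(n_base / pi)
  if (is.null(all_base_pixels)) all_base_pixels <- base_px
  rec <- data.frame(
    fov = fov, structure_id = structure_id, frame = frame,
    x_um = object$base_centroid[1] * px_size_um,
    y_um = object$base_centroid[2] * px_size_um,
    base_area_um2 = area_um2,
    effective_diameter_um = 2 * sqrt(area_um2 / pi),
    length_um = object$length_path_um,
    length_straight_um = object$length_straight_um,
    straightness = object$straightness
  )
  for (ch in names(channel_images)) {
    img <- channel_images[[ch]]
    nr <- nrow(img); nc <- ncol(img)
    shift_rc <- c(registration_shift[2], registration_shift[1])
    sh_base <- sweep(base_px, 2, -shift_rc)
    ok <- sh_base[, 1] >= 1 & sh_base[, 1] <= nr &
      sh_base[, 2] >= 1 & sh_base[, 2] <= nc
    base_mean <- mean(img[sh_base[ok, , drop = FALSE]])
    cx <- object$base_centroid[1]; cy <- object$base_centroid[2]
    ring_px <- disk_pixels(cx, cy, ring_outer * r_eq, nr, nc)
    dist <- sqrt((ring_px[, 1] - cy)^2 + (ring_px[, 2] - cx)^2)
    ring_px <- ring_px[dist >= ring_inner * r_eq, , drop = FALSE]
    if (nrow(ring_px) > 0) {
      occupied <- paste(all_base_pixels[, 1], all_base_pixels[, 2])
      free <- !(paste(ring_px[, 1], ring_px[, 2]) %in% occupied)
      ring_px <- ring_px[free, , drop = FALSE]
    }
    ring_mean <- if (nrow(ring_px) == 0) NA_real_ else {
      sh_ring <- sweep(ring_px, 2, -shift_rc)
      okr <- sh_ring[, 1] >= 1 & sh_ring[, 1] <= nr &
        sh_ring[, 2] >= 1 & sh_ring[, 2] <= nc
      if (!any(okr)) NA_real_ else mean(img[sh_ring[okr, , drop = FALSE]])
    }
    rec[[paste0("raw_", ch)]] <- base_mean
    rec[[paste0("background_", ch)]] <- ring_mean
    rec[[paste0("intensity_", ch)]] <- background_correct(base_mean, ring_mean)
  }
  rec
}
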