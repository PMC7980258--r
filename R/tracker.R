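# Machine-learning filament tracer/tracker: local-threshold
# preprocessing, random-forest pixel classification on 13x13 patches,
# mask cleanup (small components, density clustering), skeletonization
# and tip joining, longest-path length measurement, Hungarian frame
# linking, and Savitzky-Golay track velocities.

#' Local Gaussian threshold preprocessing
#'
#' Marks pixels brighter than their Gaussian-weighted local mean
#' (window `size`, Gaussian profile), producing a binary-ready image.
#' Invariant to global additive offsets; a uniform image yields an
#' all-false mask.
#'
#' @param frame 2D numeric matrix.
#' @param size Local window size, pixels (odd).
#' @param offset Added to the local mean before comparison.
#' @return Logical matrix of the same size.
#' @export
preprocess_movie <- function(frame, size = 11, offset = 0) {
  frame <- as.matrix(frame)
  if (nrow(frame) < size || ncol(frame) < size)
    stop("frame smaller than the local-threshold window")
  sigma <- (size - 1) / 6
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  brush <- brush / sum(brush)
  local_mean <- EBImage::imageData(
    EBImage::filter2(frame, brush, boundary = "replicate"))
  # small tolerance so FFT round-off on flat regions cannot flip pixels
  eps <- 1e-7 * max(abs(frame), 1)
  (frame - local_mean) > (offset + eps)
}

# 13x13 patch features around given (row, col) positions of a numeric
# image, edge-replicated; one row per position, patch_size^2 columns
# (row-major over the patch).
extract_patches <- function(img, positions, patch_size = 13) {
  half <- (patch_size - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  feats <- matrix(NA_real_, nrow(positions), patch_size^2)
  col_j <- 0L
  for (dr in -half:half) {
    rr <- pmin(pmax(positions[, 1] + dr, 1), nr)
    for (dc in -half:half) {
      cc <- pmin(pmax(positions[, 2] + dc, 1), nc)
      col_j <- col_j + 1L
      feats[, col_j] <- img[cbind(rr, cc)]
    }
  }
  feats
}

#' Train the filament pixel classifier
#'
#' Random forest on the `patch_size^2`-value neighbourhoods of the
#' preprocessed (locally thresholded) frames: every annotated filament
#' pixel is a positive example, and negatives are sampled uniformly from
#' non-filament pixels at `neg_ratio` negatives per positive (truncated
#' and flagged when too few negatives exist). The forest uses a minimum
#' of five samples per leaf; depth is left unrestricted (equivalent in
#' practice to a large depth cap).
#'
#' @param frames List of 2D numeric frames.
#' @param masks List of logical annotation masks (same sizes).
#' @param seed Integer training seed (fixed seed gives identical models).
#' @param neg_ratio Negatives sampled per positive.
#' @param patch_size Patch side length, pixels.
#' @param ntree Number of trees.
#' @param preprocess Apply [preprocess_movie()] before patch extraction.
#' @return A `pixel_classifier` list: `forest`, `patch_size`,
#'   `preprocess`, `n_pos`, `n_neg`, `truncated`.
#' @export
train_pixel_classifier <- function(frames, masks, seed = 1L, neg_ratio = 20,
                                   patch_size = 13, ntree = 50,
                                   preprocess = TRUE) {
  stopifnot(length(frames) == length(masks), length(frames) >= 1)
  pos_feats <- neg_feats <- list()
  withr::with_seed(seed, {
    for (k in seq_along(frames)) {
      img <- if (preprocess) preprocess_movie(frames[[k]]) * 1
        else as.matrix(frames[[k]])
      mask <- masks[[k]]
      pos <- which(mask, arr.ind = TRUE)
      if (nrow(pos) == 0) next
      neg_pool <- which(!mask, arr.ind = TRUE)
      n_neg_want <- neg_ratio * nrow(pos)
      neg <- neg_pool[sample(nrow(neg_pool), min(n_neg_want, nrow(neg_pool))), ,
                      drop = FALSE]
      pos_feats[[length(pos_feats) + 1]] <- extract_patches(img, pos, patch_size)
      neg_feats[[length(neg_feats) + 1]] <- extract_patches(img, neg, patch_size)
    }
    if (length(pos_feats) == 0) stop("no positive pixels in the annotations")
    X_pos <- do.call(rbind, pos_feats)
    X_neg <- do.call(rbind, neg_feats)
    truncated <- nrow(X_neg) < neg_ratio * nrow(X_pos)
    X <- rbind(X_pos, X_neg)
    y <- factor(c(rep("filopodium", nrow(X_pos)),
                  rep("background", nrow(X_neg))),
                levels = c("background", "filopodium"))
    colnames(X) <- paste0("p", seq_len(ncol(X)))
    forest <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                         nodesize = 5)
    structure(list(forest = forest, patch_size = patch_size,
                   preprocess = preprocess,
                   n_pos = nrow(X_pos), n_neg = nrow(X_neg),
                   truncated = truncated),
              class = "pixel_classifier")
  })
}

#' Classify every pixel of a frame
#'
#' @param classifier A [train_pixel_classifier()] model.
#' @param frame 2D numeric frame.
#' @return Logical matrix: `TRUE` where the pixel is classified as
#'   filament.
#' @export
classify_frame <- function(classifier, frame) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  img <- if (classifier$preprocess) preprocess_movie(frame) * 1
    else as.matrix(frame)
  pos <- as.matrix(expand.grid(seq_len(nrow(img)), seq_len(ncol(img))))
  X <- extract_patches(img, pos, classifier$patch_size)
  colnames(X) <- paste0("p", seq_len(ncol(X)))
  pred <- stats::predict(classifier$forest, X)
  matrix(pred == "filopodium", nrow(img), ncol(img))
}

# Endpoints (degree-1 pixels) and ordered walk used for tip tangents.
chain_tips <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1) return(list(list(tip = pixels[1, ], tangent = c(0, 0))))
  key <- paste(pixels[, 1], pixels[, 2])
  degree <- vapply(seq_len(n), function(i) {
    sum(abs(pixels[, 1] - pixels[i, 1]) <= 1 &
          abs(pixels[, 2] - pixels[i, 2]) <= 1) - 1L
  }, numeric(1))
  tips <- which(degree == 1)
  lapply(tips, function(tp) {
    # walk up to 4 pixels inward from the tip to estimate the local tangent
    walk <- tp
    cur <- tp
    prev <- -1L
    for (s in 1:3) {
      nb <- which(abs(pixels[, 1] - pixels[cur, 1]) <= 1 &
                    abs(pixels[, 2] - pixels[cur, 2]) <= 1)
      nb <- setdiff(nb, c(cur, walk))
      if (length(nb) == 0) break
      nxt <- nb[1]
      walk <- c(walk, nxt)
      cur <- nxt
    }
    # mean of the successive difference vectors over the 3 pixels nearest
    # the tip, pointing outward (toward the tip)
    pts <- pixels[walk, , drop = FALSE]
    if (nrow(pts) >= 2) {
      d <- pts[1, ] - pts[nrow(pts), ]
      tangent <- d / max(sqrt(sum(d^2)), 1e-12)
    } else tangent <- c(0, 0)
    list(tip = pixels[tp, ], tangent = tangent)
  })
}

# Bresenham line pixels between two (row, col) points, endpoints excluded.
line_pixels <- function(a, b) {
  n <- max(abs(b - a)) + 1
  if (n <= 2) return(cbind(integer(0), integer(0)))
  rr <- round(seq(a[1], b[1], length.out = n))
  cc <- round(seq(a[2], b[2], length.out = n))
  cbind(rr, cc)[-c(1, n), , drop = FALSE]
}

#' Extract filament skeletons from a binary mask
#'
#' Cleanup and reduction of a classified mask to one-pixel-wide filament
#' skeletons: connected regions smaller than `min_component` pixels are
#' removed (strict); the surviving pixels are density-clustered (DBSCAN,
#' radius `dbscan_eps`, minimum `dbscan_min_pts` points); each cluster is
#' thinned to a skeleton; finally fragment tips within `join_dist` pixels
#' whose local tangent lines differ by at most `join_angle` degrees are
#' connected by a straight line, closest pairs first.
#'
#' @param mask Logical matrix.
#' @param min_component Minimum connected-component size kept.
#' @param dbscan_eps,dbscan_min_pts DBSCAN parameters.
#' @param join_dist Maximum tip-to-tip joining distance, pixels.
#' @param join_angle Maximum angle between tip tangent lines, degrees.
#' @return List of skeleton pixel matrices (row, col), one per filament.
#' @export
mask_to_filopodia <- function(mask, min_component = 40, dbscan_eps = 7,
                              dbscan_min_pts = 20, join_dist = 20,
                              join_angle = 30) {
  mask <- as.matrix(mask) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_component)
    mask[lab %in% small] <- FALSE
  }
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(list())
  labels <- dbscan_points(pts, eps = dbscan_eps, min_pts = dbscan_min_pts)
  skels <- list()
  for (cl in setdiff(unique(labels), 0L)) {
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[pts[labels == cl, , drop = FALSE]] <- TRUE
    sk <- skeletonize_mask(sub)
    px <- which(sk, arr.ind = TRUE)
    if (nrow(px) > 0) skels[[length(skels) + 1]] <- px
  }
  join_skeletons(skels, join_dist, join_angle)
}

# Greedy tip joining across skeleton fragments (closest admissible tip
# pair first, each tip used once); merged fragments include the
# connecting line pixels.
join_skeletons <- function(skels, join_dist = 20, join_angle = 30) {
  if (length(skels) < 2) return(skels)
  repeat {
    tips <- lapply(skels, chain_tips)
    best <- NULL
    for (a in seq_along(skels)) {
      for (b in seq_along(skels)) {
        if (b <= a) next
        for (ta in tips[[a]]) for (tb in tips[[b]]) {
          d <- sqrt(sum((ta$tip - tb$tip)^2))
          if (d > join_dist) next
          # angle between tangent lines (orientation-free, mod 180)
          dotp <- abs(sum(ta$tangent * tb$tangent))
          ang <- acos(min(max(dotp, 0), 1)) * 180 / pi
          if (ang > join_angle) next
          if (is.null(best) || d < best$d)
            best <- list(a = a, b = b, d = d, pa = ta$tip, pb = tb$tip)
        }
      }
    }
    if (is.null(best)) break
    bridge <- line_pixels(best$pa, best$pb)
    merged <- rbind(skels[[best$a]], bridge, skels[[best$b]])
    merged <- merged[!duplicated(paste(merged[, 1], merged[, 2])), ,
                     drop = FALSE]
    skels <- c(skels[-c(best$a, best$b)], list(merged))
  }
  skels
}

#' Measure skeleton length by the longest path
#'
#' Treats the skeleton pixels as an 8-connected graph (axial steps weigh
#' 1, diagonal steps sqrt(2)) and takes the longest path through it as
#' the filament; side branches at junction points are split off and, if
#' at least `min_branch` pixels, emitted as separate chains. Cycles are
#' broken at their shortest edges (maximum spanning tree) and flagged.
#'
#' @param pixels Skeleton pixel matrix (row, col).
#' @param min_branch Minimum split-off branch size, pixels.
#' @return List with `length_px`, `chain` (ordered main-path pixels),
#'   `branches` (list of split-off pixel matrices), `had_cycle`.
#' @export
measure_skeleton_length <- function(pixels, min_branch = 5) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n == 0) return(list(length_px = 0, chain = pixels,
                          branches = list(), had_cycle = FALSE))
  if (n == 1) return(list(length_px = 0, chain = pixels,
                          branches = list(), had_cycle = FALSE))
  key <- paste(pixels[, 1], pixels[, 2])
  has_px <- function(r, c) paste(r, c) %in% key
  edges <- NULL
  w <- NULL
  for (i in seq_len(n - 1)) {
    dr <- pixels[(i + 1):n, 1] - pixels[i, 1]
    dc <- pixels[(i + 1):n, 2] - pixels[i, 2]
    adj <- which(abs(dr) <= 1 & abs(dc) <= 1)
    for (a in adj) {
      j <- i + a
      diagonal <- abs(dr[a]) + abs(dc[a]) == 2
      if (diagonal) {
        # a diagonal step shortcutting an existing axial corner is
        # redundant and would let paths zig-zag to inflate the length
        if (has_px(pixels[i, 1], pixels[j, 2]) ||
            has_px(pixels[j, 1], pixels[i, 2])) next
      }
      edges <- rbind(edges, cbind(i, j))
      w <- c(w, if (diagonal) sqrt(2) else 1)
    }
  }
  if (is.null(edges))
    return(list(length_px = 0, chain = pixels[1, , drop = FALSE],
                branches = list(), had_cycle = FALSE))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  had_cycle <- igraph::ecount(g) >= igraph::vcount(g) -
    igraph::count_components(g) + 1
  if (had_cycle) {
    # maximum spanning tree: cycles lose their shortest edges
    g <- igraph::mst(g, weights = -igraph::E(g)$weight)
    igraph::E(g)$weight <- abs(igraph::E(g)$weight)
  }
  # largest component carries the filament; the rest are split off
  comp <- igraph::components(g)
  main_comp <- which.max(comp$csize)
  main_v <- which(comp$membership == main_comp)
  sub <- igraph::induced_subgraph(g, main_v)
  dia <- igraph::get_diameter(sub, weights = igraph::E(sub)$weight)
  path_v <- main_v[as.integer(dia)]
  length_px <- igraph::diameter(sub, weights = igraph::E(sub)$weight)
  # branches: everything not on the main path, grouped by connectivity
  rest <- setdiff(seq_len(n), path_v)
  branches <- list()
  if (length(rest) > 0) {
    g_rest <- igraph::induced_subgraph(g, rest)
    comp_r <- igraph::components(g_rest)
    for (cc in seq_len(comp_r$no)) {
      vv <- rest[comp_r$membership == cc]
      if (length(vv) >= min_branch)
        branches[[length(branches) + 1]] <- pixels[vv, , drop = FALSE]
    }
  }
  list(length_px = length_px, chain = pixels[path_v, , drop = FALSE],
       branches = branches, had_cycle = had_cycle)
}

#' Link per-frame filaments into tracks
#'
#' Frame-to-frame optimal assignment (Hungarian algorithm) under the cost
#' \eqn{C = w_d \sqrt{(x_1-x_2)^2 + (y_1-y_2)^2} + w_L |L_1 - L_2|};
#' filaments whose centres of mass are more than `max_dist` pixels apart
#' may not link. Unmatched filaments terminate or start tracks. The
#' printed form of the length term is signed; the absolute difference is
#' the default since a signed term would reward pairing with longer
#' filaments rather than similar ones (`signed = TRUE` restores the
#' literal form).
#'
#' @param detections List (one element per frame) of data.frames with
#'   `cx`, `cy`, `length_px`.
#' @param max_dist Centre-of-mass linking gate, pixels (strictly more
#'   than `max_dist` forbids the link).
#' @param w_dist,w_len Cost weights.
#' @param signed Use the signed length difference.
#' @return data.frame with `track_id`, `frame`, `cx`, `cy`, `length_px`.
#' @export
link_tracks <- function(detections, max_dist = 30, w_dist = 0.6,
                        w_len = 0.4, signed = FALSE) {
  out <- NULL
  active <- NULL            # data.frame: track_id, cx, cy, length_px
  next_id <- 0L
  for (fr in seq_along(detections)) {
    det <- detections[[fr]]
    n_new <- if (is.null(det)) 0L else nrow(det)
    assigned_new <- rep(FALSE, n_new)
    new_active <- NULL
    if (!is.null(active) && nrow(active) > 0 && n_new > 0) {
      cost <- matrix(Inf, nrow(active), n_new)
      for (i in seq_len(nrow(active))) {
        d <- sqrt((det$cx - active$cx[i])^2 + (det$cy - active$cy[i])^2)
        dl <- det$length_px - active$length_px[i]
        if (!signed) dl <- abs(dl)
        ok <- d <= max_dist
        cost[i, ok] <- w_dist * d[ok] + w_len * dl[ok]
      }
      match <- solve_assignment(cost)
      for (i in seq_len(nrow(active))) {
        j <- match[i]
        if (!is.na(j)) {
          assigned_new[j] <- TRUE
          new_active <- rbind(new_active, data.frame(
            track_id = active$track_id[i], cx = det$cx[j], cy = det$cy[j],
            length_px = det$length_px[j]))
          out <- rbind(out, data.frame(
            track_id = active$track_id[i], frame = fr, cx = det$cx[j],
            cy = det$cy[j], length_px = det$length_px[j]))
        }
      }
    }
    if (n_new > 0) {
      for (j in which(!assigned_new)) {
        next_id <- next_id + 1L
        new_active <- rbind(new_active, data.frame(
          track_id = next_id, cx = det$cx[j], cy = det$cy[j],
          length_px = det$length_px[j]))
        out <- rbind(out, data.frame(
          track_id = next_id, frame = fr, cx = det$cx[j], cy = det$cy[j],
          length_px = det$length_px[j]))
      }
    }
    active <- new_active
  }
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      length_px = numeric(0))
  out
}

#' Smoothed growth velocities per track
#'
#' Drops tracks persisting fewer than `min_frames` frames, then smooths
#' each track's length series and extracts its derivative with a
#' Savitzky-Golay filter (window 5, order 2 by default), scaled to
#' um/min.
#'
#' @param tracks Track table from [link_tracks()].
#' @param frame_interval_s Frame interval, seconds.
#' @param px_size_um Pixel size, um.
#' @param min_frames Minimum track lifespan, frames.
#' @param window,order Savitzky-Golay parameters.
#' @return data.frame with `track_id`, `frame`, `length_um`,
#'   `length_um_smooth`, `velocity_um_min`.
#' @export
track_velocities <- function(tracks, frame_interval_s = 15,
                             px_size_um = 0.1487, min_frames = 5,
                             window = 5, order = 2) {
  out <- NULL
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[base::order(tr$frame), ]   # `order` is the filter order here
    if (nrow(tr) < min_frames) next
    len_um <- tr$length_px * px_size_um
    sv <- smooth_velocity(len_um, frame_interval = frame_interval_s / 60,
                          window = window, order = order)
    out <- rbind(out, data.frame(
      track_id = id, frame = tr$frame, length_um = len_um,
      length_um_smooth = sv$smoothed, velocity_um_min = sv$velocity))
  }
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      length_um = numeric(0), length_um_smooth = numeric(0),
                      velocity_um_min = numeric(0))
  out
}
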