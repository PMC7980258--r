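# Self-contained algorithmic primitives used by the image pipelines:
# density-based clustering of mask pixels, Zhang-Suen skeletonization, and
# the Hungarian algorithm for frame-to-frame assignment.

#' Density-based clustering (DBSCAN) of 2D points
#'
#' Classic DBSCAN with Euclidean distance: core points have at least
#' `min_pts` neighbours (self included) within `eps`; clusters grow by
#' density reachability; non-reachable points are noise (label 0).
#'
#' @param xy Two-column matrix of point coordinates.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
dbscan_points <- function(xy, eps, min_pts) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  eps2 <- eps^2
  # coarse grid bucketing keeps neighbour queries near-linear
  cell <- pmax(eps, 1e-9)
  gx <- floor(xy[, 1] / cell); gy <- floor(xy[, 2] / cell)
  key <- paste(gx, gy)
  bucket <- split(seq_len(n), key)
  neighbours <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(gx[i] + dx, gy[i] + dy)
      b <- bucket[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps2]
  }
  labels <- integer(n)          # 0 = unvisited/noise
  visited <- logical(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_pts) next          # noise (may be claimed later)
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb_j <- neighbours(j)
        if (length(nb_j) >= min_pts) queue <- c(queue, nb_j)
      }
      if (labels[j] == 0L) labels[j] <- cluster
    }
  }
  labels
}

# 3x3 neighbourhood values of a padded logical matrix, as a list of 8
# shifted matrices in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W,
# NW) for image coordinates (row = y increasing downward).
zs_neighbours <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  shift <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  list(p2 = shift(-1, 0), p3 = shift(-1, 1), p4 = shift(0, 1),
       p5 = shift(1, 1), p6 = shift(1, 0), p7 = shift(1, -1),
       p8 = shift(0, -1), p9 = shift(-1, -1))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until the mask is one pixel wide,
#' preserving connectivity and line ends.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size containing the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  img <- mask
  storage.mode(img) <- "logical"
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- zs_neighbours(img)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9,
                   nb$p2)
      A <- matrix(0L, nrow(img), ncol(img))
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
      if (phase == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Solve the linear assignment problem (Hungarian algorithm)
#'
#' Minimum-cost bipartite assignment by the O(n^3) shortest augmenting
#' path formulation with dual potentials. Rectangular problems are padded
#' internally; `Inf` entries mark forbidden pairings.
#'
#' @param cost Numeric cost matrix (rows assigned to columns).
#' @return Integer vector `match` of length `nrow(cost)`: `match[i]` is
#'   the column assigned to row `i`, or `NA` if the row is unassigned
#'   (possible only for rectangular or infeasible problems).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  BIG <- {
    finite <- cost[is.finite(cost)]
    if (length(finite) == 0) 1 else (max(abs(finite)) + 1) * n * 4
  }
  C <- matrix(BIG, n, n)                       # padding cost for dummies
  Cf <- cost
  Cf[!is.finite(Cf)] <- BIG * n                # forbidden: worse than dummy
  C[seq_len(nr), seq_len(nc)] <- Cf
  # shortest-augmenting-path Hungarian with dual potentials; position k of
  # u/v/p/way/minv/used stores the classic algorithm's index k - 1, with
  # index 0 the virtual dummy row/column
  u <- numeric(n + 1)                          # u[r + 1] = potential of row r
  v <- numeric(n + 1)                          # v[j + 1] = potential of col j
  p <- integer(n + 1)                          # p[j + 1] = row matched to col j
  way <- integer(n + 1)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[cols + 1L])          # candidate columns (1-based j)
      cur <- C[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      k <- which.min(minv[free + 1L])
      delta <- minv[free[k] + 1L]
      j1 <- free[k]
      u[p[used] + 1L] <- u[p[used] + 1L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    row <- p[j + 1L]
    if (row >= 1 && row <= nr && j <= nc && is.finite(cost[row, j]) &&
        cost[row, j] < BIG)
      match[row] <- j
  }
  match
}
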