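# Shared fixtures and small independent oracles used across the suite.

# Default small model for fast simulations.
quick_params <- function(...) {
  args <- utils::modifyList(
    list(M = 2L, N = 2L, theta = 6, eta = 1, dt = 1, duration = 2, seed = 1L),
    list(...))
  do.call(growth_model_params, args)
}

# One-sample KS statistic against a CDF (test-side copy, kept independent
# of the package internals).
ks1 <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(abs(Fx - (seq_len(n) - 1) / n), abs(seq_len(n) / n - Fx)))
}

# Brute-force enumeration of all injective row->column assignments;
# returns the minimum total cost among maximum-cardinality finite
# assignments and that cardinality.
brute_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  k_max <- min(nr, nc)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i], k - 1)) out <- c(out, list(c(v[i], p)))
    out
  }
  for (k in k_max:0) {
    best <- Inf
    if (k == 0) return(list(cost = 0, cardinality = 0))
    rowsets <- utils::combn(seq_len(nr), k, simplify = FALSE)
    for (rs in rowsets) for (pm in perms(seq_len(nc), k)) {
      cc <- sum(cost[cbind(rs, pm)])
      if (is.finite(cc)) best <- min(best, cc)
    }
    if (is.finite(best)) return(list(cost = best, cardinality = k))
  }
}

# Brute-force longest simple path (edge weights 1 / sqrt(2)) over a small
# skeleton pixel set, on the same pruned graph as the implementation
# (diagonal steps shortcutting an axial corner are redundant).
brute_longest_path <- function(pixels) {
  n <- nrow(pixels)
  key <- paste(pixels[, 1], pixels[, 2])
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    dr <- abs(pixels[, 1] - pixels[i, 1])
    dc <- abs(pixels[, 2] - pixels[i, 2])
    nb <- which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    diagonal <- dr[nb] + dc[nb] == 2
    shortcut <- vapply(seq_along(nb), function(k) {
      j <- nb[k]
      diagonal[k] &&
        (paste(pixels[i, 1], pixels[j, 2]) %in% key ||
           paste(pixels[j, 1], pixels[i, 2]) %in% key)
    }, logical(1))
    nb <- nb[!shortcut]
    adj[[i]] <- nb
    wts[[i]] <- ifelse(dr[nb] + dc[nb] == 2, sqrt(2), 1)
  }
  best <- 0
  dfs <- function(v, visited, len) {
    best <<- max(best, len)
    for (k in seq_along(adj[[v]])) {
      u <- adj[[v]][k]
      if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, visited, len + wts[[v]][k])
        visited[u] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- logical(n)
    visited[s] <- TRUE
    dfs(s, visited, 0)
  }
  best
}

# Pixel matrix of a straight line segment (row, col), inclusive.
line_px <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  cbind(round(seq(r0, r1, length.out = n)),
        round(seq(c0, c1, length.out = n)))
}

channels3 <- paste0("intensity_", c("toca1", "cdc42", "ena"))
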