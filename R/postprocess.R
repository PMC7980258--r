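# Tabular post-processing of segmented FLS records: filters, background
# correction, track repair, Savitzky-Golay smoothing, per-field Spearman
# correlation, enrichment cohorts, cross-correlation, shaft-profile fits.

fls_required_cols <- c("fov", "structure_id", "base_area_um2", "length_um")

#' Effective diameter of an FLS base
#'
#' @param area_um2 Base area, um^2.
#' @return Diameter of the circle of equal area, um.
#' @export
effective_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Filter snapshot records
#'
#' Removes structures with an effective base diameter below `min_diameter`
#' (base size and intensity become unreliable at the resolution limit; the
#' boundary is strict, a 0.5-um diameter is kept). Optionally truncates to
#' the `length_window` used for length-distribution analyses. Records with
#' missing required fields are rejected and counted in the `n_rejected`
#' attribute.
#'
#' @param records FLS record data.frame (needs `base_area_um2`,
#'   `length_um`).
#' @param min_diameter Diameter cut, um.
#' @param apply_length Apply the length truncation.
#' @param length_window Closed length window, um.
#' @return Filtered data.frame with attribute `n_rejected`.
#' @export
filter_snapshots <- function(records, min_diameter = 0.5,
                             apply_length = FALSE,
                             length_window = c(5, 20)) {
  missing_cols <- setdiff(c("base_area_um2", "length_um"), names(records))
  if (length(missing_cols) > 0)
    stop("records lack required fields: ", paste(missing_cols, collapse = ", "))
  ok <- is.finite(records$base_area_um2) & is.finite(records$length_um)
  n_rejected <- sum(!ok)
  out <- records[ok, , drop = FALSE]
  keep <- effective_diameter(out$base_area_um2) >= min_diameter
  if (apply_length)
    keep <- keep & out$length_um >= length_window[1] &
      out$length_um <= length_window[2]
  out <- out[keep, , drop = FALSE]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Background-correct an intensity measurement
#'
#' Corrected intensity is the mean intensity inside the base minus the
#' local background (mean over a ring two to three base radii wide,
#' neighbouring bases excluded). Negative corrected values are preserved;
#' a missing ring (fully occluded by neighbours) propagates `NA`.
#'
#' @param base_mean Mean raw intensity over the base pixels.
#' @param ring_mean Mean intensity over the background ring (`NA` when the
#'   ring is occluded).
#' @return Corrected intensity, same units.
#' @export
background_correct <- function(base_mean, ring_mean) base_mean - ring_mean

#' Repair artificial breaks in trajectories
#'
#' Segmentation dropouts split one structure's track into fragments. Pairs
#' of fragments whose lifetime-average base positions are closer than
#' `max_dist` (strict), separated by at most `max_gap` frames, and without
#' temporal overlap are merged greedily in ascending distance order; the
#' merged track inherits the id of the earlier-starting fragment.
#'
#' @param tracks data.frame with `track_id`, `frame`, `x_um`, `y_um` (and
#'   any further per-frame columns, carried through).
#' @param max_dist Distance gate, um (default 1).
#' @param max_gap Maximum frame gap (default 6).
#' @return List with `tracks` (repaired table) and `merges` (data.frame of
#'   `kept`, `absorbed`, `distance`, `gap`).
#' @export
repair_tracks <- function(tracks, max_dist = 1, max_gap = 6) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  summarize <- function(tr) {
    ids <- unique(tr$track_id)
    do.call(rbind, lapply(ids, function(id) {
      rows <- tr[tr$track_id == id, ]
      data.frame(track_id = id, fmin = min(rows$frame), fmax = max(rows$frame),
                 mx = mean(rows$x_um), my = mean(rows$y_um))
    }))
  }
  merges <- NULL
  repeat {
    sm <- summarize(tracks)
    if (nrow(sm) < 2) break
    best <- NULL
    for (a in seq_len(nrow(sm) - 1)) {
      for (b in (a + 1):nrow(sm)) {
        # order so `first` ends before `second` starts
        if (sm$fmax[a] < sm$fmin[b]) { i <- a; j <- b }
        else if (sm$fmax[b] < sm$fmin[a]) { i <- b; j <- a }
        else next                                    # temporal overlap
        gap <- sm$fmin[j] - sm$fmax[i]
        if (gap > max_gap) next
        d <- sqrt((sm$mx[i] - sm$mx[j])^2 + (sm$my[i] - sm$my[j])^2)
        if (d >= max_dist) next
        if (is.null(best) || d < best$d)
          best <- list(i = i, j = j, d = d, gap = gap)
      }
    }
    if (is.null(best)) break
    keep_id <- if (sm$fmin[best$i] <= sm$fmin[best$j])
      sm$track_id[best$i] else sm$track_id[best$j]
    drop_id <- setdiff(sm$track_id[c(best$i, best$j)], keep_id)
    merges <- rbind(merges, data.frame(kept = keep_id, absorbed = drop_id,
                                       distance = best$d, gap = best$gap))
    tracks$track_id[tracks$track_id == drop_id] <- keep_id
  }
  list(tracks = tracks, merges = merges)
}

#' Savitzky-Golay smoothing and velocity extraction
#'
#' Smooths a length series and extracts its derivative (the growth
#' velocity) with a Savitzky-Golay filter. The default window of 11 time
#' points and polynomial order 3 suppresses segmentation noise while
#' reproducing any cubic trend exactly in the window interior. Series
#' shorter than the window are returned unsmoothed with a flag; their
#' velocity falls back to central finite differences.
#'
#' @param lengths Length series, um.
#' @param frame_interval Time between frames, minutes.
#' @param window Filter window length (odd).
#' @param order Polynomial order (< window).
#' @return List with `smoothed` (um), `velocity` (um/min), `flagged`.
#' @export
smooth_velocity <- function(lengths, frame_interval = 1, window = 11,
                            order = 3) {
  n <- length(lengths)
  if (n < window) {
    v <- c(NA, diff(lengths)) / frame_interval
    return(list(smoothed = lengths, velocity = v, flagged = TRUE))
  }
  sm <- signal::sgolayfilt(lengths, p = order, n = window)
  v <- signal::sgolayfilt(lengths, p = order, n = window, m = 1,
                          ts = frame_interval)
  list(smoothed = sm, velocity = v, flagged = FALSE)
}

#' Per-field-of-view Spearman correlation matrix
#'
#' Rank correlations between intensity and morphology variables are
#' computed separately within each field of view (so illumination and
#' batch differences between fields cannot masquerade as correlation) and
#' averaged unweighted across fields. A field contributes a cell only if
#' it has at least `min_per_fov` records and neither variable is constant
#' within it.
#'
#' @param records FLS record data.frame with a `fov` column.
#' @param variables Character vector of column names to correlate.
#' @param min_per_fov Minimum records per contributing field.
#' @return A `correlation_matrix` list: `labels`, `mean` (averaged
#'   matrix), `n` (fields per cell), `per_fov` (list of per-field
#'   matrices).
#' @export
spearman_matrix <- function(records, variables, min_per_fov = 3) {
  stopifnot("fov" %in% names(records), all(variables %in% names(records)))
  fovs <- unique(records$fov)
  per_fov <- list()
  for (f in fovs) {
    sub <- records[records$fov == f, variables, drop = FALSE]
    if (nrow(sub) < min_per_fov) next
    suppressWarnings(
      cm <- stats::cor(sub, method = "spearman",
                       use = "pairwise.complete.obs"))
    # constant variables yield NA rows: excluded from the average, but the
    # diagonal of a non-degenerate variable is exact
    per_fov[[as.character(f)]] <- cm
  }
  if (length(per_fov) == 0) stop("no field of view has enough records")
  arr <- simplify2array(per_fov)
  mean_mat <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  n_mat <- apply(arr, c(1, 2), function(x) sum(!is.na(x)))
  structure(list(labels = variables, mean = mean_mat, n = n_mat,
                 per_fov = per_fov),
            class = "correlation_matrix")
}

# 95% t-interval of the mean; returns c(mean, lo, hi, n)
t_ci <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

# Enrichment indicator: TRUE when the value is in the top half of `ref`
# (strictly above the median; continuous intensities make ties negligible).
top_half <- function(x, ref = x) x > stats::median(ref)

#' Relative length change by number of simultaneously enriched channels
#'
#' A channel is "enriched" in a record when its background-corrected
#' intensity lies in the top half of that channel's values (per field of
#' view by default; a global threshold would conflate illumination
#' differences between fields). Records are bucketed by how many channels
#' are simultaneously enriched; each bucket's relative length change is
#' bucket mean length / field mean length - 1, computed per field and
#' averaged across fields with a 95% t-interval.
#'
#' @param records FLS record data.frame.
#' @param channels Character vector (>= 2) of intensity column names.
#' @param threshold `"per_fov"` (default) or `"global"`.
#' @return data.frame with `n_enriched`, `mean_change`, `ci_lo`, `ci_hi`,
#'   `n_fov`.
#' @export
enrichment_length_change <- function(records, channels,
                                     threshold = c("per_fov", "global")) {
  threshold <- match.arg(threshold)
  stopifnot(length(channels) >= 2, all(channels %in% names(records)),
            "fov" %in% names(records))
  n_ch <- length(channels)
  if (threshold == "global") {
    enriched <- vapply(channels, function(ch) top_half(records[[ch]]),
                       logical(nrow(records)))
    counts <- rowSums(enriched)
  } else {
    counts <- rep(NA_integer_, nrow(records))
    for (f in unique(records$fov)) {
      idx <- records$fov == f
      e <- vapply(channels, function(ch) top_half(records[[ch]][idx]),
                  logical(sum(idx)))
      counts[idx] <- rowSums(matrix(e, ncol = n_ch))
    }
  }
  per_fov <- vapply(unique(records$fov), function(f) {
    idx <- records$fov == f
    fov_mean <- mean(records$length_um[idx])
    vapply(0:n_ch, function(k) {
      sel <- idx & counts == k
      if (!any(sel)) return(NA_real_)      # empty bucket: excluded
      mean(records$length_um[sel]) / fov_mean - 1
    }, numeric(1))
  }, numeric(n_ch + 1))
  per_fov <- matrix(per_fov, nrow = n_ch + 1)
  out <- t(apply(per_fov, 1, t_ci))
  data.frame(n_enriched = 0:n_ch, mean_change = out[, "mean"],
             ci_lo = out[, "lo"], ci_hi = out[, "hi"],
             n_fov = as.integer(out[, "n"]))
}

#' Length ECDFs for double-enrichment cohorts
#'
#' Splits records into three cohorts based on two channels: all records,
#' records with both channels above the `hi` percentile, and records with
#' both below the `lo` percentile; percentiles are computed per field of
#' view with linear interpolation between order statistics.
#'
#' @param records FLS record data.frame.
#' @param channels Character vector of exactly 2 intensity columns.
#' @param hi,lo High/low percentile thresholds, in `[0, 1]`.
#' @param min_n Cohorts below this size are flagged `low_n`.
#' @return List of three elements (`all`, `both_high`, `both_low`), each
#'   with `ecdf`, `lengths`, `n`, `low_n`.
#' @export
cohort_ecdf <- function(records, channels, hi = 0.7, lo = 0.3, min_n = 10) {
  stopifnot(length(channels) == 2, all(channels %in% names(records)))
  high <- low <- logical(nrow(records))
  for (f in unique(records$fov)) {
    idx <- which(records$fov == f)
    q_hi <- vapply(channels, function(ch)
      stats::quantile(records[[ch]][idx], hi, names = FALSE), numeric(1))
    q_lo <- vapply(channels, function(ch)
      stats::quantile(records[[ch]][idx], lo, names = FALSE), numeric(1))
    high[idx] <- records[[channels[1]]][idx] > q_hi[1] &
      records[[channels[2]]][idx] > q_hi[2]
    low[idx] <- records[[channels[1]]][idx] < q_lo[1] &
      records[[channels[2]]][idx] < q_lo[2]
  }
  make <- function(sel) {
    len <- records$length_um[sel]
    list(ecdf = if (length(len)) stats::ecdf(len) else NULL,
         lengths = len, n = length(len), low_n = length(len) < min_n)
  }
  list(all = make(rep(TRUE, nrow(records))),
       both_high = make(high), both_low = make(low))
}

#' Velocity-intensity time-shift cross-correlation
#'
#' Pearson correlation between the absolute growth velocity |v(t)| and the
#' background-corrected intensity I(t + shift), per trajectory at each
#' integer frame shift, averaged unweighted over trajectories with a 95%
#' t-interval. Negative shifts mean intensity changes precede velocity
#' changes. Trajectories shorter than `2 * max_shift` frames are skipped.
#'
#' @param trajectories List; each element a list with numeric `velocity`
#'   and `intensity` of equal length.
#' @param max_shift Maximum shift in frames.
#' @return data.frame with `shift`, `mean_corr`, `ci_lo`, `ci_hi`, `n`.
#' @export
cross_correlate <- function(trajectories, max_shift = 10) {
  shifts <- -max_shift:max_shift
  vals <- matrix(NA_real_, nrow = length(trajectories),
                 ncol = length(shifts))
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]
    stopifnot(length(tr$velocity) == length(tr$intensity))
    Tn <- length(tr$velocity)
    if (Tn < 2 * max_shift) next
    av <- abs(tr$velocity)
    for (s_i in seq_along(shifts)) {
      s <- shifts[s_i]
      t_idx <- max(1, 1 - s):min(Tn, Tn - s)
      if (length(t_idx) < 3) next
      vals[k, s_i] <- suppressWarnings(
        stats::cor(av[t_idx], tr$intensity[t_idx + s]))
    }
  }
  out <- t(apply(vals, 2, t_ci))
  data.frame(shift = shifts, mean_corr = out[, "mean"],
             ci_lo = out[, "lo"], ci_hi = out[, "hi"],
             n = as.integer(out[, "n"]))
}

#' Fit a decay profile along the FLS shaft
#'
#' Fits either an exponential decay (log-linear least squares on positive
#' values; the decay length is -1/slope) or a straight line to a profile
#' sampled along the shaft, with a residual-resampling bootstrap interval
#' (66% by default) on the headline coefficient.
#'
#' @param z Height along the shaft, um (>= 4 points).
#' @param y Intensity or width at each height.
#' @param type `"exponential"` or `"linear"`.
#' @param n_boot Bootstrap replicates.
#' @param conf Interval coverage (default 0.66).
#' @param seed Integer seed for the bootstrap.
#' @return List with `type`, `estimate` (decay length, um, or slope),
#'   `intercept`, `ci` (length 2), `n_used`, `n_excluded`.
#' @export
shaft_profile_fit <- function(z, y, type = c("exponential", "linear"),
                              n_boot = 200, conf = 0.66, seed = 1L) {
  type <- match.arg(type)
  stopifnot(length(z) == length(y), length(z) >= 4)
  if (type == "exponential") {
    pos <- y > 0
    n_excluded <- sum(!pos)
    zf <- z[pos]; yf <- log(y[pos])
    if (length(zf) < 4) stop("fewer than 4 positive values for the log-linear fit")
    to_est <- function(slope) -1 / slope
  } else {
    zf <- z; yf <- y
    n_excluded <- 0L
    to_est <- identity
  }
  fit <- stats::lm(yf ~ zf)
  slope <- unname(stats::coef(fit)[2])
  fitted <- stats::fitted(fit)
  res <- stats::resid(fit)
  boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    yb <- fitted + sample(res, replace = TRUE)
    unname(stats::coef(stats::lm(yb ~ zf))[2])
  }, numeric(1)))
  ci <- sort(to_est(stats::quantile(boot, c((1 - conf) / 2,
                                            1 - (1 - conf) / 2),
                                    names = FALSE)))
  list(type = type, estimate = to_est(slope),
       intercept = unname(stats::coef(fit)[1]), ci = ci,
       n_used = length(zf), n_excluded = n_excluded)
}
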