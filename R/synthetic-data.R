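# Synthetic-data generators with known ground truth for every downstream
# stage: trajectory sets, per-field intensity tables, and FRAP traces.
# (Image-stack and movie generators live in synthetic-imaging.R.)

#' Generate a set of growth trajectories
#'
#' Simulates `n_traj` length trajectories of the sum-of-products growth
#' model, each with an initiation time drawn uniformly on
#' `[0, initiation_window]` minutes (structures nucleate asynchronously
#' within an experiment).
#'
#' @param params A [growth_model_params()] object.
#' @param n_traj Number of trajectories (>= 1).
#' @param initiation_window Width of the random-initiation window, minutes
#'   (0 starts every trajectory at t = 0).
#' @return A `synthetic_scene` list with `kind = "trajectory_set"`,
#'   `times` (minutes), `lengths` (n_traj x T matrix), `velocities`
#'   (raw force), `initiation_times`, and `ground_truth` (true M, N,
#'   theta, eta, seed).
#' @export
gen_trajectory_set <- function(params, n_traj, initiation_window = 20) {
  stopifnot(inherits(params, "growth_model_params"), n_traj >= 1,
            initiation_window >= 0, initiation_window <= params$duration)
  init <- withr::with_seed(params$seed,
                           stats::runif(n_traj, 0, initiation_window))
  sim <- simulate_length_batch(params, n_traj, init,
                               seed = params$seed + 1L, record = "full")
  structure(
    list(kind = "trajectory_set", times = sim$times, lengths = sim$lengths,
         velocities = sim$velocities,
         initiation_times = sim$initiation_times,
         ground_truth = list(M = params$M, N = params$N,
                             theta = params$theta, eta = params$eta,
                             seed = params$seed),
         seed = params$seed),
    class = "synthetic_scene"
  )
}

# Validate a rank-correlation matrix, with a diagnosis on failure.
check_rank_corr <- function(rank_corr) {
  rank_corr <- as.matrix(rank_corr)
  if (nrow(rank_corr) != ncol(rank_corr))
    stop("rank_corr is not square")
  if (max(abs(rank_corr - t(rank_corr))) > 1e-8)
    stop("rank_corr is not symmetric")
  if (max(abs(diag(rank_corr) - 1)) > 1e-8)
    stop("rank_corr does not have a unit diagonal")
  ev <- eigen(rank_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("rank_corr is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev)))
  rank_corr
}

#' Generate a synthetic FLS snapshot table
#'
#' Emulates a segmented-snapshot experiment: per-channel tip intensities
#' are lognormal with a Gaussian-copula rank-correlation structure
#' (microscopy intensities are non-negative and right-skewed, and only the
#' rank structure needs controlling), grouped by field of view; lengths
#' are exponential with scale `length_scale`. Records with at least two
#' channels in their field's top intensity half receive a length boost
#' calibrated so that the expected [enrichment_length_change()] readout
#' for those buckets equals `effect_two_plus` exactly.
#'
#' @param n_fov Number of fields of view.
#' @param n_per_fov Records per field.
#' @param rank_corr Target Spearman correlation matrix between channels
#'   (symmetric, unit diagonal, positive semidefinite).
#' @param effect_two_plus Planted relative length change for records with
#'   >= 2 enriched channels (0 = no effect).
#' @param seed Integer seed.
#' @param channels Channel names.
#' @param length_scale Exponential length scale, um.
#' @param meanlog,sdlog Lognormal intensity parameters.
#' @return A `synthetic_scene` list with `kind = "intensity_table"`,
#'   `records` (FLS record data.frame) and `ground_truth`.
#' @export
gen_intensity_table <- function(n_fov, n_per_fov, rank_corr,
                                effect_two_plus = 0, seed = 1L,
                                channels = c("toca1", "cdc42", "ena"),
                                length_scale = 7.6,
                                meanlog = log(100), sdlog = 0.6) {
  rank_corr <- check_rank_corr(rank_corr)
  n_ch <- length(channels)
  stopifnot(nrow(rank_corr) == n_ch, n_fov >= 1, n_per_fov >= 1)
  # Pearson correlation of the Gaussian copula that induces the target
  # Spearman correlation
  pearson <- 2 * sin(pi * rank_corr / 6)
  es <- eigen(pearson, symmetric = TRUE)
  sqrt_mat <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), n_ch) %*%
    t(es$vectors)
  withr::with_seed(seed, {
    n <- n_fov * n_per_fov
    Z <- matrix(stats::rnorm(n * n_ch), ncol = n_ch) %*% sqrt_mat
    intens <- stats::qlnorm(stats::pnorm(Z), meanlog = meanlog, sdlog = sdlog)
    colnames(intens) <- paste0("intensity_", channels)
    fov <- rep(seq_len(n_fov), each = n_per_fov)
    lengths <- stats::rexp(n, rate = 1 / length_scale)
    enriched <- matrix(FALSE, n, n_ch)
    for (f in seq_len(n_fov)) {
      idx <- fov == f
      for (ch in seq_len(n_ch))
        enriched[idx, ch] <- top_half(intens[idx, ch])
    }
    n_enriched <- rowSums(enriched)
    boosted <- n_enriched >= 2
    p <- mean(boosted)
    e <- effect_two_plus
    multiplier <- if (e == 0 || p == 0) 1 else {
      if ((1 + e) * p >= 1)
        stop("planted effect too large for the enriched fraction")
      (1 + e) * (1 - p) / (1 - (1 + e) * p)
    }
    lengths[boosted] <- lengths[boosted] * multiplier
    records <- data.frame(
      fov = fov,
      structure_id = seq_len(n),
      frame = 1L,
      x_um = stats::runif(n, 0, 100),
      y_um = stats::runif(n, 0, 100),
      base_area_um2 = stats::rlnorm(n, meanlog = log(1.07), sdlog = 0.5),
      length_um = lengths,
      straightness = stats::rbeta(n, 20, 2)
    )
    records <- cbind(records, as.data.frame(intens))
    structure(
      list(kind = "intensity_table", records = records,
           ground_truth = list(rank_corr = rank_corr,
                               effect_two_plus = effect_two_plus,
                               multiplier = multiplier,
                               enriched_fraction = p,
                               n_enriched = n_enriched,
                               length_scale = length_scale),
           seed = seed),
      class = "synthetic_scene"
    )
  })
}

#' Generate a synthetic FRAP trace
#'
#' Emulates the four-ROI photobleaching protocol: a prebleach plateau, an
#' instantaneous drop of depth `bleach_depth` at the bleach frame,
#' single-exponential recovery of the mobile fraction, multiplicative
#' acquisition photobleaching on both structure ROIs, and additive
#' Gaussian noise. Sampling follows the standard protocol: prebleach
#' frames at 1-s intervals, then 40 post-bleach frames at 0.5 s and the
#' rest at 1 s.
#'
#' @param rate Recovery rate k, 1/s (>= 0).
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param bleach_depth Fraction of signal removed at the bleach (0, 1].
#' @param acq_bleach_rate Acquisition photobleaching rate, 1/s (>= 0).
#' @param noise_sd Noise SD as a fraction of the prebleach plateau (>= 0).
#' @param seed Integer seed.
#' @param n_pre,n_post_fast,n_post_slow Frame counts per sampling segment.
#' @param amplitude,bg Raw plateau and background intensity levels.
#' @return A `synthetic_scene` list with `kind = "frap_trace"`, `trace`
#'   (a [frap_trace()]) and `ground_truth` (rate, mobile fraction, bleach
#'   frame, acquisition rate).
#' @export
gen_frap_trace <- function(rate, mobile_fraction, bleach_depth = 0.9,
                           acq_bleach_rate = 0, noise_sd = 0, seed = 1L,
                           n_pre = 5, n_post_fast = 40, n_post_slow = 80,
                           amplitude = 1000, bg = 100) {
  stopifnot(rate >= 0, acq_bleach_rate >= 0,
            mobile_fraction >= 0, mobile_fraction <= 1,
            bleach_depth > 0, bleach_depth <= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  t_pre <- seq(0, by = 1, length.out = n_pre)
  t0 <- t_pre[n_pre] + 0.5
  t_fast <- t0 + seq(0, by = 0.5, length.out = n_post_fast)
  t_slow <- t_fast[n_post_fast] + seq(1, by = 1, length.out = n_post_slow)
  time_s <- c(t_pre, t_fast, t_slow)
  bleach_frame <- n_pre + 1L
  t_post <- time_s - time_s[bleach_frame]
  recovery <- ifelse(t_post < 0, 1,
                     (1 - bleach_depth) +
                       bleach_depth * mobile_fraction * (1 - exp(-rate * t_post)))
  acq <- exp(-acq_bleach_rate * time_s)
  withr::with_seed(seed, {
    noise <- function() stats::rnorm(length(time_s), sd = noise_sd * amplitude)
    trace <- frap_trace(
      time_s = time_s,
      bleached_fls = bg + amplitude * recovery * acq + noise(),
      unbleached_fls = bg + amplitude * acq + noise(),
      bleached_bg = bg + noise(),
      unbleached_bg = bg + noise()
    )
    structure(
      list(kind = "frap_trace", trace = trace,
           ground_truth = list(rate = rate,
                               mobile_fraction = mobile_fraction,
                               bleach_depth = bleach_depth,
                               acq_bleach_rate = acq_bleach_rate,
                               bleach_frame = bleach_frame),
           seed = seed),
      class = "synthetic_scene"
    )
  })
}
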