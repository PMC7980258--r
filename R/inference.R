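# Fitting and model selection: Laplace/exponential MLE, Q-Q diagnostics,
# persistence times, the (M, N) scan, theta fitting and the timescale
# prediction.

#' Maximum-likelihood Laplace fit
#'
#' The Laplace MLE: location is the sample median (lower median for even
#' `n`, a deterministic tie-break) and scale is the mean absolute deviation
#' from it. The distribution's variance, reported alongside, is
#' \eqn{2b^2}.
#'
#' @param sample Numeric vector (n >= 2).
#' @return A `laplace_fit` list: `location`, `scale`, `variance`,
#'   `loglik`, `n`, `degenerate` (TRUE when all values coincide).
#' @export
fit_laplace <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  stopifnot(n >= 2)
  s <- sort(sample)
  loc <- s[ceiling(n / 2)]                 # lower median for even n
  b <- mean(abs(sample - loc))
  degenerate <- b == 0
  ll <- if (degenerate) Inf else -n * log(2 * b) - sum(abs(sample - loc)) / b
  structure(
    list(location = loc, scale = b, variance = 2 * b^2, loglik = ll,
         n = n, degenerate = degenerate),
    class = "laplace_fit"
  )
}

#' @export
print.laplace_fit <- function(x, ...) {
  cat(sprintf("Laplace MLE: location %.4g, scale b %.4g (variance %.4g), n = %d%s\n",
              x$location, x$scale, x$variance, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Maximum-likelihood fit of a doubly truncated exponential
#'
#' Fits the scale of an exponential observed only inside `[lower, upper]`
#' (the standard 5-20 um window that excludes immature structures and
#' axial-resolution artifacts). The MLE solves the truncated-mean equation
#' \deqn{\bar y = s + \frac{a e^{-a/s} - b e^{-b/s}}{e^{-a/s} - e^{-b/s}}}
#' numerically; with bounds `(0, Inf)` it reduces to the sample mean.
#'
#' @param sample Lengths (or areas, or durations).
#' @param lower,upper Truncation bounds; values outside are discarded.
#' @return An `exponential_fit` list: `scale`, `lower`, `upper`, `n_used`,
#'   `n_input`, `converged`.
#' @export
fit_exponential <- function(sample, lower = 5, upper = 20) {
  sample <- sample[is.finite(sample)]
  n_input <- length(sample)
  y <- sample[sample >= lower & sample <= upper]
  if (length(y) < 10) stop("fewer than 10 values inside the truncation window")
  ybar <- mean(y)
  if (!is.finite(upper)) {
    # untruncated above: closed form, scale = mean excess over the floor
    scale <- ybar - lower
    return(structure(
      list(scale = scale, lower = lower, upper = upper,
           n_used = length(y), n_input = n_input, converged = scale > 0),
      class = "exponential_fit"))
  }
  d <- upper - lower
  # truncated mean = lower + d * h(u), u = d/scale, with the numerically
  # stable h(u) = 1/u - 1/(e^u - 1): decreasing from 1/2 (u -> 0) to 0
  h <- function(u) ifelse(u < 1e-6, 0.5 - u / 12,
                          ifelse(u > 500, 1 / u, 1 / u - 1 / expm1(u)))
  target <- (ybar - lower) / d
  sol <- if (target >= 0.5 || target <= 0) NULL else tryCatch(
    stats::uniroot(function(u) h(u) - target, lower = 1e-8, upper = 700,
                   tol = 1e-12),
    error = function(e) NULL)
  converged <- !is.null(sol)
  structure(
    list(scale = if (converged) d / sol$root else NA_real_,
         lower = lower, upper = upper,
         n_used = length(y), n_input = n_input, converged = converged),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Truncated-exponential MLE: scale %.4g on [%g, %g], n = %d/%d%s\n",
              x$scale, x$lower, x$upper, x$n_used, x$n_input,
              if (!x$converged) " [no solution]" else ""))
  invisible(x)
}

#' Exponential Q-Q diagnostic
#'
#' Pairs the ordered sample with exponential quantiles at plotting
#' positions \eqn{(i - 0.5)/n}. The comparison scale is the
#' regression-through-origin slope of the sample on the unit-scale
#' quantiles, so a sample that lies exactly on exponential quantiles maps
#' onto the identity line.
#'
#' @param sample Numeric vector (n >= 5).
#' @return List with `theoretical`, `empirical` (both sorted), `scale`,
#'   `max_deviation`.
#' @export
qq_exponential <- function(sample) {
  sample <- sort(sample[is.finite(sample)])
  n <- length(sample)
  stopifnot(n >= 5)
  p <- (seq_len(n) - 0.5) / n
  q1 <- stats::qexp(p)                      # unit-scale quantiles
  scale <- sum(q1 * sample) / sum(q1^2)
  theo <- scale * q1
  list(theoretical = theo, empirical = sample, scale = scale,
       max_deviation = max(abs(theo - sample)))
}

#' Extract growth/shrinkage persistence times
#'
#' A persistence phase is a maximal run of constant velocity sign; zero
#' velocities attach to the preceding phase (leading zeros to the first
#' signed phase). The first and last phases are censored by the
#' observation window and are discarded.
#'
#' @param velocity Smoothed velocity series (see [smooth_velocity()]).
#' @param frame_interval Time between frames, minutes.
#' @return Numeric vector of interior phase durations, minutes (possibly
#'   empty).
#' @export
extract_persistence_times <- function(velocity, frame_interval = 1) {
  velocity <- velocity[is.finite(velocity)]
  if (length(velocity) < 3) return(numeric(0))
  s <- sign(velocity)
  # zeros inherit the previous sign; leading zeros the first nonzero sign
  nz <- which(s != 0)
  if (length(nz) == 0) return(numeric(0))
  s[seq_len(nz[1] - 1)] <- s[nz[1]]
  for (k in seq_along(s)[-1]) if (s[k] == 0) s[k] <- s[k - 1]
  runs <- rle(s)
  if (length(runs$lengths) <= 2) return(numeric(0))
  runs$lengths[-c(1, length(runs$lengths))] * frame_interval
}

#' Kolmogorov-Smirnov scan over model complexity (M, N)
#'
#' For every combination of sum terms `M` and product factors `N`,
#' simulates stationary growth velocities and compares their
#' unit-variance-normalized distribution with the reference sample via the
#' two-sample KS statistic. The best-fitting `N` for each `M` is the
#' row-wise argmin. The normalized stationary velocity shape depends only
#' on `(M, N)`, so the simulation's `theta`/`eta` merely set the
#' equilibration speed.
#'
#' @param reference Reference velocity sample.
#' @param M_range,N_range Integer vectors of grid values.
#' @param n_sim Stationary samples per cell.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param theta,eta,dt Simulation parameters for the stationary sampler.
#' @return An `mn_scan` list: `ks` (matrix M x N), `best_n` (named vector,
#'   per-M argmin), `best_cell` (global argmin `c(M, N)`), `failed`
#'   (logical matrix), `n_sim`, `seeds`.
#' @export
scan_mn <- function(reference, M_range = 1:6, N_range = 1:6,
                    n_sim = 2e4, seed = 1L, theta = 6, eta = 1, dt = 1) {
  stopifnot(length(M_range) >= 1, length(N_range) >= 1, n_sim >= 1)
  ks <- matrix(NA_real_, nrow = length(M_range), ncol = length(N_range),
               dimnames = list(M = M_range, N = N_range))
  failed <- matrix(FALSE, nrow = length(M_range), ncol = length(N_range))
  seeds <- matrix(NA_integer_, nrow = length(M_range), ncol = length(N_range))
  for (i in seq_along(M_range)) {
    for (j in seq_along(N_range)) {
      cell_seed <- (seed + 1013L * i + 7717L * j) %% .Machine$integer.max
      seeds[i, j] <- cell_seed
      p <- growth_model_params(M = M_range[i], N = N_range[j], theta = theta,
                               eta = eta, dt = dt, duration = 1, seed = cell_seed)
      ks[i, j] <- tryCatch({
        v <- sample_stationary_velocities(p, n_sim, seed = cell_seed)
        ks_two_sample(reference, v, normalize = TRUE)
      }, error = function(e) { failed[i, j] <<- TRUE; NA_real_ })
    }
  }
  best_n <- N_range[apply(ks, 1, which.min)]
  names(best_n) <- M_range
  gmin <- which(ks == min(ks, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(
    list(ks = ks, best_n = best_n,
         best_cell = c(M = M_range[gmin[1]], N = N_range[gmin[2]]),
         failed = failed, n_sim = n_sim, seeds = seeds),
    class = "mn_scan"
  )
}

#' Compare observed and simulated length distributions
#'
#' Scales the simulated lengths by the ratio of the median observed length
#' above `lower` to the median simulated length above `lower`, then
#' compares the two truncated samples on a shared histogram grid and by
#' the two-sample KS statistic.
#'
#' @param observed,simulated Length samples (um); each needs >= 10 values
#'   above `lower`.
#' @param lower Truncation threshold, um (default 5).
#' @param n_bins Histogram bins on the shared grid.
#' @return List with `scale_factor`, `ks`, `breaks`, `observed_density`,
#'   `simulated_density`, `n_observed`, `n_simulated`.
#' @export
compare_length_distributions <- function(observed, simulated, lower = 5,
                                         n_bins = 30) {
  obs <- observed[is.finite(observed) & observed > lower]
  sim <- simulated[is.finite(simulated) & simulated > lower]
  if (length(obs) < 10 || length(sim) < 10)
    stop(sprintf("need >= 10 values above %g in both samples", lower))
  scale_factor <- stats::median(obs) / stats::median(sim)
  sim_scaled <- sim * scale_factor
  breaks <- seq(min(obs, sim_scaled), max(obs, sim_scaled),
                length.out = n_bins + 1)
  h_obs <- graphics::hist(obs, breaks = breaks, plot = FALSE)
  h_sim <- graphics::hist(sim_scaled, breaks = breaks, plot = FALSE)
  list(scale_factor = scale_factor,
       ks = ks_two_sample(obs, sim_scaled),
       breaks = breaks,
       observed_density = h_obs$density,
       simulated_density = h_sim$density,
       n_observed = length(obs), n_simulated = length(sim))
}

#' Fit the relaxation rate theta by simulation over a grid
#'
#' For each candidate `theta`, simulates `n_sim` trajectories with random
#' initiation times uniform on `[0, initiation_window]`, collects lengths
#' at the collection time point, truncates to lengths above `lower`, and
#' scores the candidate by the KS distance to the observed lengths after
#' median-ratio scaling. The fitted `theta` is the grid argmin; grid
#' search keeps the objective reproducible.
#'
#' @param observed Observed lengths at the collection time, um.
#' @param template A [growth_model_params()] supplying M, N, eta, dt; its
#'   `duration` is replaced by `t_collect`.
#' @param theta_grid Sorted positive candidate values, 1/min.
#' @param n_sim Trajectories per candidate.
#' @param seed Integer seed.
#' @param initiation_window Random-initiation window, minutes.
#' @param t_collect Collection time point, minutes.
#' @param lower Truncation threshold, um.
#' @return A `theta_fit` list: `theta_star`, `objective` (data.frame with
#'   `theta`, `ks`, `scale_factor`, `n_retained`), `n_sim`.
#' @export
fit_theta <- function(observed, template, theta_grid, n_sim = 5000,
                      seed = 1L, initiation_window = 20, t_collect = 20,
                      lower = 5) {
  stopifnot(all(diff(theta_grid) > 0) || length(theta_grid) == 1,
            all(theta_grid > 0))
  rows <- vector("list", length(theta_grid))
  for (g in seq_along(theta_grid)) {
    th <- theta_grid[g]
    p <- growth_model_params(M = template$M, N = template$N, theta = th,
                             eta = template$eta, baselines = template$baselines,
                             dt = template$dt, duration = t_collect,
                             seed = template$seed)
    g_seed <- (seed + 4241L * g) %% .Machine$integer.max
    rows[[g]] <- tryCatch({
      init <- withr::with_seed(g_seed,
                               stats::runif(n_sim, 0, initiation_window))
      sim <- simulate_length_batch(p, n_sim, init, seed = g_seed + 1L,
                                   record = "final")$final_lengths
      cmp <- compare_length_distributions(observed, sim, lower = lower)
      data.frame(theta = th, ks = cmp$ks, scale_factor = cmp$scale_factor,
                 n_retained = cmp$n_simulated)
    }, error = function(e)
      data.frame(theta = th, ks = NA_real_, scale_factor = NA_real_,
                 n_retained = 0L))
  }
  objective <- do.call(rbind, rows)
  if (all(is.na(objective$ks))) stop("all theta candidates failed")
  theta_star <- objective$theta[which.min(objective$ks)]
  structure(list(theta_star = theta_star, objective = objective,
                 n_sim = n_sim),
            class = "theta_fit")
}

#' Predicted per-protein fluctuation timescale
#'
#' Converts a fitted growth-velocity relaxation rate `lambda` into the
#' per-protein relaxation rate `lambda / N` (the fluctuation timescale of a
#' product of N regulators scales with the number of factors) and the
#' corresponding characteristic recovery time in seconds. The
#' `"reciprocal"` convention reports `60 / rate`; `"half_life"` reports
#' `60 * ln(2) / rate`.
#'
#' @param lambda Growth-velocity relaxation rate, 1/min (> 0).
#' @param N Number of factors per complex (>= 1).
#' @param convention Time conversion convention.
#' @return A `timescale_prediction` list: `lambda`, `N`,
#'   `per_protein_rate` (1/min), `characteristic_time` (s), `convention`.
#' @export
predict_fluctuation_timescale <- function(lambda, N,
                                          convention = c("reciprocal",
                                                         "half_life")) {
  convention <- match.arg(convention)
  stopifnot(lambda > 0, N >= 1)
  rate <- lambda / N
  tchar <- if (convention == "reciprocal") 60 / rate else 60 * log(2) / rate
  structure(list(lambda = lambda, N = N, per_protein_rate = rate,
                 characteristic_time = tchar, convention = convention),
            class = "timescale_prediction")
}
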