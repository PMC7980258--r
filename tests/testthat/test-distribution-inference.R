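# Distribution fitting and model selection: Laplace and truncated
# exponential MLE, Q-Q diagnostics, KS utilities, persistence times, the
# (M, N) scan, theta fitting, and the timescale prediction.

test_that("Laplace MLE matches the closed form and recovers the scale", {
  f <- fit_laplace(c(-1, 0, 1))
  expect_equal(f$location, 0)
  expect_equal(f$scale, 2 / 3)
  expect_equal(f$variance, 2 * (2 / 3)^2)
  # even n: lower median as deterministic tie-break
  f2 <- fit_laplace(c(1, 2, 3, 4))
  expect_equal(f2$location, 2)
  expect_equal(f2$scale, 1)
  # degenerate sample flagged
  expect_true(fit_laplace(rep(3, 10))$degenerate)
  # estimator recovery at n = 1e4
  set.seed(4)
  f3 <- fit_laplace(rlaplace(1e4, 0, 1.5))
  expect_lt(abs(f3$scale - 1.5), 0.05)
})

test_that("Laplace scale estimator bias is below 2% over replicates", {
  set.seed(7)
  est <- replicate(100, fit_laplace(rlaplace(1e4, 0, 1.5))$scale)
  expect_lt(abs(mean(est) / 1.5 - 1), 0.02)
})

test_that("truncated-exponential MLE matches mean, generator and a grid oracle", {
  set.seed(1)
  y <- rexp(200, rate = 1 / 3)
  f <- fit_exponential(y, lower = 0, upper = Inf)
  expect_equal(f$scale, mean(y), tolerance = 1e-6)
  # recovery against the generator through the truncation window
  big <- rexp(4e5, rate = 1 / 7.6)
  f2 <- fit_exponential(big, lower = 5, upper = 20)
  expect_lt(abs(f2$scale - 7.6), 0.3)
  expect_lte(f2$n_used, f2$n_input)
  # oracle equivalence: brute-force likelihood grid on a small sample
  small <- big[big >= 5 & big <= 20][1:50]
  loglik <- function(s)
    -50 * log(s) - sum(small) / s - 50 * log(exp(-5 / s) - exp(-20 / s))
  grid <- seq(2, 30, by = 1e-3)
  s_grid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  f3 <- fit_exponential(small, 5, 20)
  expect_lt(abs(f3$scale - s_grid), 1e-3 + 1e-3)
  # mean above the window midpoint: no MLE solution, flagged
  f4 <- fit_exponential(rep(18, 20), lower = 5, upper = 20)
  expect_false(f4$converged)
  expect_error(fit_exponential(c(1, 2, 3), lower = 5, upper = 20), "10 values")
})

test_that("exponential Q-Q maps exact quantiles to the identity line", {
  p <- (seq_len(40) - 0.5) / 40
  x <- qexp(p, rate = 1 / 3)
  qq <- qq_exponential(x)
  expect_lt(qq$max_deviation, 1e-12)
  expect_equal(qq$scale, 3, tolerance = 1e-12)
  # single heavy contamination shows up at the top quantile
  set.seed(2)
  y <- c(rexp(199, 1), 10 * max(rexp(199, 1)))
  qq2 <- qq_exponential(y)
  dev <- abs(qq2$theoretical - qq2$empirical)
  expect_equal(which.max(dev), length(y))
  # minimal run
  expect_length(qq_exponential(c(0.1, 0.4, 0.9, 1.7, 3.2))$theoretical, 5)
})

test_that("persistence phases follow the censoring and zero-attachment rules", {
  # signs (+ + + - -): both phases touch the boundary, all censored
  expect_length(extract_persistence_times(c(1, 1, 1, -1, -1)), 0)
  # signs (+ + - - - + +): one interior phase of 3 min
  expect_equal(extract_persistence_times(c(1, 1, -1, -1, -1, 1, 1)), 3)
  # zeros attach to the preceding phase
  expect_equal(extract_persistence_times(c(1, 1, -1, 0, -1, 1, 1)), 3)
  # frame interval scales durations
  expect_equal(extract_persistence_times(c(1, 1, -1, -1, -1, 1, 1),
                                         frame_interval = 0.25), 0.75)
  expect_length(extract_persistence_times(c(1, -1)), 0)
})

test_that("persistence-time distributions are reproducible across runs", {
  p <- growth_model_params(M = 2, N = 2, theta = 11, eta = 2, duration = 20)
  get_pt <- function(seed) {
    p$seed <- seed
    ts <- gen_trajectory_set(p, 700, initiation_window = 0)
    frame_idx <- seq(1, length(ts$times), by = 15)  # 15-s sampling
    unlist(lapply(seq_len(nrow(ts$lengths)), function(i) {
      sv <- smooth_velocity(ts$lengths[i, frame_idx], frame_interval = 0.25)
      extract_persistence_times(sv$velocity, frame_interval = 0.25)
    }))
  }
  a <- get_pt(101)
  b <- get_pt(202)
  expect_gt(length(a), 5000)
  expect_lt(ks_two_sample(a, b), 0.03)
})

test_that("two-sample KS matches its definition and stats::ks.test", {
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x), 0)
  expect_equal(ks_two_sample(1:10, 21:30), 1)
  set.seed(3)
  a <- rlaplace(1e5, 0, 1); b <- rlaplace(1e5, 0, 1)
  expect_lt(ks_two_sample(a, b), 0.01)
  # dual route: agreement with stats::ks.test on continuous samples
  a2 <- rnorm(300); b2 <- rnorm(400, 0.3)
  expect_equal(ks_two_sample(a2, b2),
               unname(suppressWarnings(ks.test(a2, b2)$statistic)),
               tolerance = 1e-12)
  # normalize flag compares shapes only (power-of-two scaling is exact)
  expect_lt(ks_two_sample(a2, 2 * a2, normalize = TRUE), 1e-12)
})

test_that("(M,N) scan recovers the generating cell on a small grid", {
  p <- quick_params()
  ref <- sample_stationary_velocities(p, 3e4, seed = 101)
  sc <- scan_mn(ref, M_range = 1:3, N_range = 1:3, n_sim = 8e3, seed = 7)
  expect_true(all(sc$ks >= 0 & sc$ks <= 1, na.rm = TRUE))
  expect_lte(abs(sc$best_cell["M"] - 2), 1)
  expect_lte(abs(sc$best_cell["N"] - 2), 1)
  # single-cell grid is trivially best
  sc1 <- scan_mn(ref, M_range = 2, N_range = 2, n_sim = 2e3, seed = 8)
  expect_equal(unname(sc1$best_cell), c(2, 2))
  expect_equal(unname(sc1$best_n), 2)
})

test_that("length-distribution comparison scales by the >5um median ratio", {
  set.seed(5)
  obs <- 5 + rexp(500, 1 / 8)       # all above the truncation threshold
  cmp <- compare_length_distributions(obs, obs)
  expect_equal(cmp$scale_factor, 1)
  expect_equal(cmp$ks, 0)
  cmp2 <- compare_length_distributions(obs, 2 * obs)
  expect_equal(cmp2$scale_factor, 0.5)
  expect_error(compare_length_distributions(obs, rexp(500, 10)), "above 5")
})

test_that("theta fit returns grid argmin and handles a degenerate grid", {
  set.seed(6)
  obs <- rexp(300, 1 / 8) + 5
  tpl <- growth_model_params(M = 2, N = 2, theta = 11, eta = 2, duration = 20)
  ft <- fit_theta(obs, tpl, theta_grid = 11, n_sim = 300, seed = 2)
  expect_equal(ft$theta_star, 11)
  ft2 <- fit_theta(obs, tpl, theta_grid = c(6, 11, 20), n_sim = 400, seed = 2)
  obj <- ft2$objective
  expect_lte(obj$ks[obj$theta == ft2$theta_star][1], min(obj$ks[c(1, 3)]))
})

test_that("fluctuation-timescale prediction divides the relaxation rate by N", {
  ts <- predict_fluctuation_timescale(22, 2)
  expect_equal(ts$per_protein_rate, 11)
  expect_equal(ts$characteristic_time, 60 / 11)
  expect_equal(round(ts$characteristic_time), 5)
  expect_equal(predict_fluctuation_timescale(22, 1)$per_protein_rate, 22)
  ts2 <- predict_fluctuation_timescale(22, 2, convention = "half_life")
  expect_equal(ts2$characteristic_time, 60 * log(2) / 11)
})
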