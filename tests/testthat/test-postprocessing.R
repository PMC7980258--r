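# Tabular post-processing: filters, background correction, track repair,
# smoothing, correlations, enrichment cohorts, cross-correlation and
# shaft fits.

make_records <- function(diam_um, length_um, fov = 1) {
  data.frame(fov = fov, structure_id = seq_along(diam_um), frame = 1,
             x_um = 0, y_um = 0, base_area_um2 = pi * (diam_um / 2)^2,
             length_um = length_um, straightness = 0.9)
}

test_that("snapshot filter applies strict diameter and closed length gates", {
  rec <- make_records(c(0.49, 0.50, 1.0), c(10, 10, 10))
  out <- filter_snapshots(rec)
  expect_equal(out$structure_id, c(2, 3))       # 0.49 out, 0.50 kept
  # counting fixture: 10 records, 3 below the diameter cut, 2 outside [5, 20]
  rec2 <- make_records(c(rep(0.3, 3), rep(1, 7)),
                       c(rep(10, 3), 2, 30, rep(10, 5)))
  out2 <- filter_snapshots(rec2, apply_length = TRUE)
  expect_equal(nrow(out2), 5)
  # empty input, idempotence, missing-field rejection
  expect_equal(nrow(filter_snapshots(rec[0, ])), 0)
  expect_equal(filter_snapshots(out, apply_length = TRUE),
               filter_snapshots(filter_snapshots(out, apply_length = TRUE),
                                apply_length = TRUE),
               ignore_attr = TRUE)
  expect_error(filter_snapshots(data.frame(fov = 1)), "required fields")
  rec3 <- rec; rec3$base_area_um2[1] <- NA
  expect_equal(attr(filter_snapshots(rec3), "n_rejected"), 1)
})

test_that("background correction subtracts the ring mean", {
  expect_equal(background_correct(150, 100), 50)
  expect_equal(background_correct(100, 100), 0)
  expect_true(is.na(background_correct(100, NA)))
  # negative corrected intensities are preserved
  expect_equal(background_correct(80, 100), -20)
})

test_that("track repair merges within gates, greedily and order-independently", {
  frag <- function(id, frames, x) data.frame(track_id = id, frame = frames,
                                             x_um = x, y_um = 0)
  # inside all gates: 0.5 um apart, gap 3
  tr <- rbind(frag(1, 1:5, 0), frag(2, 8:12, 0.5))
  rp <- repair_tracks(tr)
  expect_equal(nrow(rp$merges), 1)
  expect_equal(unique(rp$tracks$track_id), 1)
  # distance gate: 1.2 um apart
  expect_null(repair_tracks(rbind(frag(1, 1:5, 0), frag(2, 8:12, 1.2)))$merges)
  # gap gate: 7 frames
  expect_null(repair_tracks(rbind(frag(1, 1:5, 0), frag(2, 13:17, 0)))$merges)
  # temporal overlap forbidden
  expect_null(repair_tracks(rbind(frag(1, 1:6, 0), frag(2, 6:10, 0)))$merges)
  # chain A-B-C pairwise mergeable: single track, input-order independent
  chain <- rbind(frag(1, 1:3, 0), frag(2, 6:8, 0.4), frag(3, 11:13, 0.7))
  for (ord in list(1:9, 9:1, c(4:6, 1:3, 7:9))) {
    rp2 <- repair_tracks(chain[ord, ])
    expect_equal(length(unique(rp2$tracks$track_id)), 1)
    expect_equal(unique(rp2$tracks$track_id), 1)
  }
  # merges never create temporal overlaps
  rp3 <- repair_tracks(chain)
  expect_false(any(duplicated(rp3$tracks[c("track_id", "frame")])))
})

test_that("Savitzky-Golay smoothing is exact on cubics and scales derivatives", {
  t <- seq_len(31)
  x <- 2 + 0.5 * t - 0.1 * t^2 + 0.01 * t^3
  sv <- smooth_velocity(x, frame_interval = 1)
  inner <- 6:26
  expect_equal(sv$smoothed[inner], x[inner], tolerance = 1e-9)
  # linear ramp of 2 um/min
  sv2 <- smooth_velocity(5 + 2 * t, frame_interval = 1)
  expect_equal(sv2$velocity[inner], rep(2, length(inner)), tolerance = 1e-9)
  # derivative equals direct convolution with the sgolay filter row
  set.seed(8)
  y <- rnorm(41)
  svy <- smooth_velocity(y, frame_interval = 2)
  fm <- signal::sgolay(p = 3, n = 11, m = 1)
  k <- 21
  manual <- sum(fm[6, ] * y[(k - 5):(k + 5)]) / 2
  expect_equal(svy$velocity[k], manual, tolerance = 1e-9)
  # white noise: filtered velocity variance below finite differences
  expect_lt(var(svy$velocity[6:36]), var(diff(y) / 2))
  # short series flagged, returned unsmoothed
  sv3 <- smooth_velocity(c(1, 2, 3), frame_interval = 1)
  expect_true(sv3$flagged)
  expect_equal(sv3$smoothed, c(1, 2, 3))
})

test_that("per-fov Spearman averaging matches stats::cor and is rank-invariant", {
  set.seed(11)
  rec <- data.frame(fov = rep(1:2, each = 30),
                    a = rnorm(60), b = rnorm(60))
  rec$b <- rec$b + 0.8 * rec$a
  sm <- spearman_matrix(rec, c("a", "b"))
  oracle <- mean(c(cor(rec$a[1:30], rec$b[1:30], method = "spearman"),
                   cor(rec$a[31:60], rec$b[31:60], method = "spearman")))
  expect_equal(sm$mean["a", "b"], oracle)
  expect_equal(diag(sm$mean), c(a = 1, b = 1))
  # invariance under a monotone transform within each fov
  rec2 <- rec; rec2$a <- exp(rec2$a)
  sm2 <- spearman_matrix(rec2, c("a", "b"))
  expect_equal(sm2$mean, sm$mean)
  # constant variable: fov excluded from that cell
  rec3 <- rec; rec3$a[1:30] <- 1
  sm3 <- spearman_matrix(rec3, c("a", "b"))
  expect_equal(sm3$n["a", "b"], 1)
})

test_that("enrichment buckets match a hand-worked single-fov fixture", {
  # 4 records, 2 channels; top halves (strictly above the median):
  # ch1 median 2.5 -> records 3, 4 enriched; ch2 median 25 -> records 2, 4
  rec <- data.frame(fov = 1, structure_id = 1:4, frame = 1, x_um = 0,
                    y_um = 0, base_area_um2 = 1,
                    length_um = c(4, 6, 8, 10), straightness = 1,
                    intensity_a = c(1, 2, 3, 4),
                    intensity_b = c(10, 30, 20, 40))
  el <- enrichment_length_change(rec, c("intensity_a", "intensity_b"))
  # counts: r1 = 0, r2 = 1, r3 = 1, r4 = 2; fov mean length = 7
  expect_equal(el$mean_change[el$n_enriched == 0], 4 / 7 - 1)
  expect_equal(el$mean_change[el$n_enriched == 1], mean(c(6, 8)) / 7 - 1)
  expect_equal(el$mean_change[el$n_enriched == 2], 10 / 7 - 1)
  # permutation null: shuffling lengths breaks the association
  tab <- gen_intensity_table(8, 500, diag(3), 0.15, seed = 6)
  perm <- tab$records
  set.seed(1)
  perm$length_um <- sample(perm$length_um)
  el0 <- enrichment_length_change(perm, channels3)
  expect_true(all(el0$ci_lo <= 0 & 0 <= el0$ci_hi))
})

test_that("cohort ECDFs split per-fov percentiles as expected", {
  set.seed(12)
  rec <- gen_intensity_table(4, 300, diag(2), 0, seed = 2,
                             channels = c("a", "b"))$records
  # 50/50 thresholds partition each channel into complementary halves
  co <- cohort_ecdf(rec, c("intensity_a", "intensity_b"), hi = 0.5, lo = 0.5)
  n_half <- co$both_high$n + co$both_low$n
  expect_lte(n_half, co$all$n)
  expect_gt(co$both_high$n, 0)
  # independent intensities: cohorts agree within KS noise
  co2 <- cohort_ecdf(rec, c("intensity_a", "intensity_b"))
  ks <- ks_two_sample(co2$both_high$lengths, co2$all$lengths)
  expect_lt(ks, 1.63 * sqrt(1 / co2$both_high$n + 1 / co2$all$n))
  # planted effect: both-high cohort stochastically larger
  tab <- gen_intensity_table(6, 800, diag(2), 0.5, seed = 3,
                             channels = c("a", "b"))
  co3 <- cohort_ecdf(tab$records, c("intensity_a", "intensity_b"))
  expect_gt(mean(co3$both_high$lengths), mean(co3$both_low$lengths))
  # low-n cohorts flagged
  few <- rec[1:12, ]
  co4 <- cohort_ecdf(few, c("intensity_a", "intensity_b"))
  expect_true(co4$both_high$low_n)
})

test_that("cross-correlation peaks at the planted lag with the sign convention", {
  set.seed(13)
  v <- rnorm(200)
  # intensity equal to |v|: perfect correlation at zero shift
  cc <- cross_correlate(list(list(velocity = v, intensity = abs(v))),
                        max_shift = 5)
  expect_equal(cc$mean_corr[cc$shift == 0], 1, tolerance = 1e-12)
  # I(t) = |v(t + k)|: intensity precedes velocity, peak at shift -k
  k <- 3
  tr <- list(velocity = v[seq_len(150)],
             intensity = abs(v[seq_len(150) + k]))
  cc2 <- cross_correlate(list(tr), max_shift = 6)
  expect_equal(cc2$shift[which.max(cc2$mean_corr)], -k)
  # independent white noise: correlations near zero
  trs <- lapply(1:30, function(i)
    list(velocity = rnorm(120), intensity = rnorm(120)))
  cc3 <- cross_correlate(trs, max_shift = 4)
  se <- (cc3$ci_hi - cc3$mean_corr) / qt(0.975, cc3$n - 1)
  expect_true(all(abs(cc3$mean_corr) < 3.5 * se))
  # short trajectories are skipped
  cc4 <- cross_correlate(list(list(velocity = rnorm(5),
                                   intensity = rnorm(5))), max_shift = 6)
  expect_true(all(cc4$n == 0))
})

test_that("shaft profile fits recover exact decays and bootstrap coverage", {
  z <- seq(0, 10, length.out = 12)
  f_exp <- shaft_profile_fit(z, exp(-z / 3), type = "exponential")
  expect_equal(f_exp$estimate, 3, tolerance = 1e-9)
  f_lin <- shaft_profile_fit(z, 5 - 0.2 * z, type = "linear")
  expect_equal(f_lin$estimate, -0.2, tolerance = 1e-9)
  # non-positive values excluded from the log-linear fit, count reported
  y <- exp(-z / 3); y[4] <- -1
  f2 <- shaft_profile_fit(z, y, type = "exponential")
  expect_equal(f2$n_excluded, 1)
  # 66% residual-bootstrap interval covers the truth in >= 60% of sims
  set.seed(14)
  cover <- mean(replicate(100, {
    yy <- exp(-z / 3) * exp(rnorm(12, sd = 0.1))
    ff <- shaft_profile_fit(z, yy, type = "exponential", n_boot = 200,
                            seed = sample.int(1e6, 1))
    ff$ci[1] <= 3 && 3 <= ff$ci[2]
  }))
  expect_gte(cover, 0.6)
})
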