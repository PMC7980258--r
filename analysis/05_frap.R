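#!/usr/bin/env Rscript
# FRAP recovery analysis: four-ROI normalization and single-exponential
# fitting across the physiological half-time range, plus the
# velocity-intensity cross-correlation on synthetic trajectories.

suppressPackageStartupMessages(library(filodyn))
dir.create("results", showWarnings = FALSE)

rows <- NULL
for (ht in c(5, 10, 15, 25)) {
  fits <- lapply(1:15, function(i) {
    sc <- gen_frap_trace(rate = log(2) / ht, mobile_fraction = 0.8,
                         bleach_depth = 0.9, acq_bleach_rate = 0.002,
                         noise_sd = 0.02, seed = 100 * ht + i)
    fit_recovery(normalize_frap(sc$trace))
  })
  med_ht <- median(vapply(fits, `[[`, numeric(1), "half_time"))
  med_rec <- median(vapply(fits, `[[`, numeric(1), "percent_recovery"))
  rows <- rbind(rows, data.frame(true_half_time_s = ht,
                                 fitted_half_time_s = med_ht,
                                 percent_recovery = med_rec))
}
cat("FRAP half-time recovery (median over 15 traces per condition):\n")
print(rows, digits = 3)
write.csv(rows, "results/frap_recovery.csv", row.names = FALSE)

# cross-correlation: intensity fluctuations leading velocity by 2 frames
set.seed(8)
trs <- lapply(1:50, function(i) {
  v <- rnorm(150)
  list(velocity = v[1:120], intensity = abs(v[1:120 + 2]) + rnorm(120, 0, 0.3))
})
cc <- cross_correlate(trs, max_shift = 8)
cat(sprintf("Cross-correlation peak at shift %+d frames (r = %.2f)\n",
            cc$shift[which.max(cc$mean_corr)], max(cc$mean_corr)))
write.csv(cc, "results/cross_correlation.csv", row.names = FALSE)
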