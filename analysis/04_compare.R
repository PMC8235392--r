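#!/usr/bin/env Rscript
# Stage 4: per-temperature group comparison of Py (Mann-Whitney U, two
# sided) in the layout of the published comparison table, plus the
# time-normalized drip-loss t-test.

library(thawspec)

out <- "results/analysis"
fits_csv <- file.path(out, "cole_fits.csv")
if (!file.exists(fits_csv)) stop("run analysis/02_fit_cole.R first")

fits <- read.csv(fits_csv)
py <- py_by_temperature(fits)
tab <- comparison_table(py)
write.csv(tab, file.path(out, "comparison.csv"), row.names = FALSE)

message("Py comparison (fast vs slow thaw), MWU two-sided p per temperature:")
for (lab in unique(tab$temperature_label)) {
  rows <- tab[tab$temperature_label == lab, ]
  message(sprintf("  %-8s fast %5.2f  slow %5.2f  p = %.4f", lab,
                  rows$mean[rows$group == "fast_thaw"],
                  rows$mean[rows$group == "slow_thaw"],
                  rows$p_value[1L]))
}

drip_csv <- file.path(out, "drip_loss.csv")
if (file.exists(drip_csv)) {
  drip <- read.csv(drip_csv)
  loss <- drip_loss_percent(drip$initial_weight_g, drip$final_weight_g,
                            drip$storage_hours, normalize_hours = 20)
  tt <- two_sample_t(loss[drip$treatment == "fast_thaw"],
                     loss[drip$treatment == "slow_thaw"])
  message(sprintf("drip loss (normalized to 20 h): t = %.3f, p = %.4f", tt$t,
                  tt$p_value))
}
message("wrote comparison.csv")
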