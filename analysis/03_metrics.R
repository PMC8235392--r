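#!/usr/bin/env Rscript
# Stage 3: scalar impedance descriptors -- magnitude and phase per
# frequency, and the impedance change rate (ICR) along each thawing
# trajectory at the lowest grid frequency, where membrane damage expresses
# most strongly.

library(thawspec)

out <- "results/analysis"
spectra <- file.path(out, "spectra.csv")
if (!file.exists(spectra)) stop("run analysis/01_simulate.R first")

cohort <- read_spectra_csv(spectra)
metrics <- cohort_metrics(cohort)
write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

icr <- metrics[!is.na(metrics$icr) & metrics$frequency_Hz ==
                 min(metrics$frequency_Hz), ]
for (g in unique(icr$treatment)) {
  v <- icr$icr[icr$treatment == g]
  message(sprintf("ICR per degree C at %.0f Hz, %s: median %.4f (IQR %.4f)",
                  min(metrics$frequency_Hz), g, median(v), IQR(v)))
}
message("wrote metrics.csv (", nrow(metrics), " rows)")
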