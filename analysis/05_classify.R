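#!/usr/bin/env Rscript
# Stage 5: train the two-layer LSTM thawing-method classifier on the
# 180-spectrum cohort (9 scheduled temperatures x 20 samples), once per
# input channel (reactance X, resistance R), with a stratified 80/20 split.

library(thawspec)

out <- "results/analysis"
spectra <- file.path(out, "spectra.csv")
if (!file.exists(spectra)) stop("run analysis/01_simulate.R first")

cohort <- read_spectra_csv(spectra)
for (ch in c("X", "R")) {
  res <- classify_cohort(cohort, ch, lstm_config(seed = 11L))
  write_classifier_json(res$model, file.path(out, sprintf("model_%s.json", ch)))
  pred <- predict_classifier(res$model, res$features$x)
  write.csv(data.frame(sample_id = res$features$groups,
                       temperature_C = res$features$temperature_C,
                       label = as.character(res$features$labels), pred),
            file.path(out, sprintf("predictions_%s.csv", ch)),
            row.names = FALSE)
  message(sprintf("%s-channel: held-out accuracy %.4f, loss %.4f (best epoch %d of %d)",
                  ch, res$report$heldout_accuracy, res$report$heldout_loss,
                  res$report$best_epoch, nrow(res$report$history)))
}
message("wrote model_[XR].json, predictions_[XR].csv")
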