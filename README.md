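# thawspec

Bioimpedance analysis of freeze-thaw membrane damage in muscle tissue.

Freezing preserves meat but ice crystals rupture cell membranes, and the
thawing protocol (fast water-bath vs slow air thawing) modulates the
damage. Intact membranes are capacitors that block low-frequency current,
so multi-frequency electrical impedance spectroscopy senses membrane
integrity directly. `thawspec` implements the full analysis chain for
such experiments, for food scientists and bioimpedance researchers:

* **Cole-model fitting.** Each 36-point complex spectrum (10 Hz - 510 kHz)
  is fitted with the single-dispersion Cole model
  `Z(w) = Rinf + (R0 - Rinf) / (1 + (i w tau)^alpha)`
  by weighted complex nonlinear least squares (circle-fit initialization,
  Levenberg-Marquardt refinement), yielding the membrane-integrity index
  `Py = (R0 - Rinf) * 100 / R0`.
* **Impedance descriptors.** Magnitude/phase, relative storage change,
  fresh-vs-thawed R and X indices, and the impedance change rate (ICR)
  along a thawing trajectory.
* **Group statistics.** Per-temperature two-sided Mann-Whitney U tests on
  Py (exact enumeration with midrank ties at small n, tie-corrected
  normal approximation otherwise), comparison tables with count / median /
  mean / SD / IQR per group, drip-loss t-tests.
* **Thawing-method classification.** A from-scratch two-layer LSTM (batch
  normalization, dropout, softmax head, Adam, gradient-checked
  backpropagation) that labels single spectra as fast- or slow-thawed.
* **A calibrated synthetic generator.** Lumped thermal model with a
  latent-heat plateau, membrane-damage dynamics, and noisy Cole spectra,
  calibrated so group-level Py statistics match the published
  per-temperature values -- the test bed for every stage.

## Worked example

```r
library(thawspec)

# a synthetic cohort: 10 fast- + 10 slow-thawed samples, spectra at every
# 0.5 C from 0-4 C plus a next-day measurement, Py calibrated per group
cohort <- generate_cohort(simulator_config(seed = 1))

fits <- fit_cole_cohort(cohort)          # Cole parameters + Py per spectrum
tab  <- comparison_table(py_by_temperature(fits))
subset(tab, temperature_label == "4")[, c("group", "mean", "sd", "p_value")]
#>       group     mean       sd   p_value
#>   fast_thaw 15.79951 5.057937 0.0113297
#>   slow_thaw 10.01725 4.270344 0.0113297

# classify thawing method from single reactance spectra (180 = 20 x 9)
res <- classify_cohort(cohort, "X", lstm_config(seed = 11))
res$report$heldout_accuracy
#> [1] 0.9722222
```

The 4 C row says: fitted mean Py is about 15.8 for water-bath thawed
samples versus 10.0 for air thawed ones -- fast thawing leaves more intact
membranes -- and the difference is significant (MWU p = 0.011). The
classifier separates the two treatments from a single reactance spectrum
with 97% held-out accuracy on this cohort.

The same workflow as a narrated sequence of stages lives in `analysis/`
(`01_simulate.R` ... `05_classify.R`, outputs under `results/analysis/`),
or as one orchestrated, checksummed run:

```r
run_pipeline(pipeline_config("results/run", seed = 1))
```

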