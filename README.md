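# calsig

Kinetic analysis, classification and population comparison of intracellular
calcium signals recorded with fluorescent indicators.

## What problem this solves

Calcium-imaging experiments ask whether different stimuli (or
concentrations, or cell types) evoke *distinguishably different* calcium
responses. Answering that needs more than a significance test: per-cell
traces must be normalized and summarised by kinetic parameters, long
recordings must be sorted into response classes, and — because parameter
distributions are heterogeneous and right-skewed — two populations must be
compared by *how different* their distributions are, not merely whether a
difference is improbable under a null. `calsig` implements that pipeline
for anyone working with per-ROI fluorescence time series (high-content
screens, coverslip imaging):

* **Normalization & kinetics** — F/F₀ against a 20 s pre-stimulus baseline;
  responder screening at a strict 1.045-fold threshold; peak amplitude
  (F<sub>max</sub>/F₀), 10–90% rise time, latency to 10% of peak, and
  trapezoidal AUC, with linear-interpolated threshold crossings.
* **Spike detection & classification** — a centered 50-sample moving
  average is subtracted from the trace; runs of the detrended series above
  0.4 lasting ≥ 5 s are spikes; responses are classified as single spike
  (SS: n = 1, AUC < 500), burst (BS: n > 1, ISI·n ≤ 300, AUC > 1000),
  repetitive (RS: n > 1, ISI·n > 300) or sustained (SU: n = 1, AUC > 500),
  with rule gaps labelled UNCLASSIFIED.
* **Population comparison** — the difference metric
  *D* = ½ Σᵢ |Aᵢ − Bᵢ| between unit-normalized histograms on shared bins
  (the total variation distance between the binned distributions; 0 =
  identical, 1 = disjoint), calibrated against unit-SD Gaussian surrogates
  offset by known multiples of SD; plus an enumeration-exact two-sided
  Fisher test for class-count tables.
* **Synthetic data** — a generator for all four response archetypes with
  ground-truth labels, right-skewed parameter populations and Gaussian
  surrogate samples, so the entire pipeline is testable without imaging
  data.

## Worked example

Simulate a labelled population at the long-term acquisition settings
(2 Hz, 20 min, stimulus at 60 s), classify it, and compare populations:

```r
library(calsig)

sim <- simulate_cells(n_per_class = 25, seed = 42)   # SS/BS/RS/SU x 25
res <- classify_population(sim$traces)
res$table
#>           SS           BS           RS           SU UNCLASSIFIED
#>           25           25           25           24            1
mean(res$cells$label == sim$truth$class_label)        # 0.99

head(res$cells[, c("cell_id", "spike_count", "mean_isi_s", "auc", "label")], 3)
#>   cell_id spike_count mean_isi_s      auc label
#> 1  SS_001           1         NA 40.79081    SS
#> 2  SS_002           1         NA 29.76546    SS
#> 3  SS_003           1         NA 30.39339    SS
```

One SU cell lands in UNCLASSIFIED — the rules have deliberate gaps and a
small unclassifiable remainder is expected behaviour. Each classified row
carries the evidence for its label: `SS_001` has a single spike and a
baseline-subtracted AUC of ≈ 41 fold·s, far under the 500 fold·s sustained
boundary.

Calibrate the difference metric on Gaussian surrogates and compare it with
the analytic total variation distance `1 − 2Φ(−δ/2)`:

```r
cal <- gaussian_calibration(offsets_sd = c(1, 2, 3), seed = 1)
round(cal[, c("offset_sd", "mean_d", "analytic_tv")], 3)
#>   offset_sd mean_d analytic_tv
#> 1         1  0.380       0.383
#> 2         2  0.680       0.683
#> 3         3  0.864       0.866
```

So a population shift of one noise-SD yields D ≈ 0.38. For scale from the
other end, two draws from the *same* distribution at screen-scale n sit at
control-level difference:

```r
a <- generate_population(2000, "lognormal", location = log(20), scale = 0.5, seed = 11)
b <- generate_population(2000, "lognormal", location = log(20), scale = 0.5, seed = 12)
sample_difference(a, b)
#> [1] 0.0595
```

Class proportions between two conditions are compared exactly:

```r
fisher_exact_2x2(matrix(c(30, 10, 14, 26), 2, byrow = TRUE))
#> [1] 0.0006476793
```

A command-line front end wrapping the same functions
(`extract`, `classify`, `compare`, `calibrate`, `simulate`) is installed at
`system.file("cli", "calsig.R", package = "calsig")`.

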