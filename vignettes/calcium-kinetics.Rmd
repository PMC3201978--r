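---
title: "Methods: kinetic analysis and population comparison of calcium signals"
author: "calsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic analysis and population comparison of calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calsig)
```

## The analysis problem

Cells loaded with a fluorescent calcium indicator (e.g. fluo-4) and exposed
to a receptor agonist produce per-cell fluorescence time series whose shape
varies enormously between cells: a single transient, a burst of transients,
repetitive oscillations, or a sustained plateau. `calsig` takes such
per-cell traces (already reduced from images to one intensity series per
ROI), a stimulus-addition time, and a configuration of thresholds, and
produces:

1. per-cell kinetic parameters (peak amplitude, 10–90% rise time, latency,
   area under the curve) for short recordings (~100 s at 8 Hz);
2. a four-class response classification (SS/BS/RS/SU) for long recordings
   (~20 min at 2 Hz), via detrend-and-threshold spike detection;
3. population-level comparison of parameter distributions through a
   normalized-histogram difference metric *D*, calibrated on Gaussian
   surrogates, plus an exact Fisher test for class-count tables.

## Normalization and the responder rule

Fluorescence is expressed as F/F₀, where F₀ is the arithmetic mean
intensity over the baseline window `[stim_time − 20 s, stim_time)`. The
window is half-open at the stimulus: the sample at the nominal addition
time belongs to the response, not the baseline. Normalization makes every
downstream quantity invariant under uniform rescaling of the raw
intensities, so camera gain and indicator loading drop out (loading effects
on kinetics themselves are a separate question and are not corrected for).

A cell is a **responder** when its post-stimulus ratio exceeds 1.045-fold
— strictly; a trace peaking at exactly 1.045 is not a response. The fixed
threshold corresponds to roughly three standard deviations of typical
baseline noise; `responder_mode = "adaptive_3sd"` switches to a per-cell
`1 + 3·SD(baseline ratio)` threshold for data whose noise differs from
that regime.

Cells with calcium signals *before* the stimulus cannot be attributed to
it. Lacking a separate printed criterion, the same responder threshold is
applied to the pre-stimulus samples: any baseline ratio above it flags the
cell as excluded. Flagged cells are retained in all outputs with
`excluded = TRUE`; nothing is silently dropped. Note that with the
synthetic generator's default multiplicative noise (SD 0.02) the fixed
threshold sits at only 2.25 noise SDs, so over a long pre-stimulus stretch
the flag trips frequently; this is the rule faithfully applied to noisier
data, not a defect, and the adaptive mode or a shorter baseline avoids it.

## Kinetic parameters

With A = peak − 1 the baseline-subtracted amplitude:

* **peak** — maximum post-stimulus F/F₀; the *earliest* time attaining it
  on a tie;
* **latency** — time from stimulus to the first crossing of `1 + 0.10·A`;
* **rise time** — time between the first crossings of `1 + 0.10·A` and
  `1 + 0.90·A`;
* **AUC** — trapezoidal integral from the 10% crossing to the end of the
  recording.

Percent-of-peak levels are fractions of the baseline-subtracted amplitude,
not of the absolute ratio; otherwise "10% of peak" would sit below baseline
for any peak under 1.11-fold. Crossings are searched from the stimulus up
to the peak and located by linear interpolation between samples, first
crossing wins; a step sitting exactly on the stimulus is clamped so latency
is never negative. On a linear ramp these conventions are exact: a ramp
from 1 to 2 over 10 s gives rise time 8.0 s and latency 1.0 s.

The AUC integrand is configurable because usage varies: `raw_ratio`
(default) integrates F/F₀ itself, appropriate for short recordings where
the whole integral is dominated by the response; `baseline_subtracted`
integrates F/F₀ − 1. For *classification* (below) the baseline-subtracted
integrand is the default regardless: over a 20-minute recording a quiet
baseline alone integrates to ≈1100 fold·s, more than the 1000 fold·s burst
boundary, so the raw reading would make the single-spike class (AUC < 500)
unsatisfiable. The class boundaries are only coherent for the
baseline-subtracted integral, and `classify_population()` exposes the
choice as `classify_integrand`.

## Spike detection and classification

Slow drifts and plateaus are removed by subtracting a centered moving
average of **50 adjacent samples** from the trace. The window is specified
in samples, not seconds: at the 2 Hz frame rate of long-term recordings it
spans 25 s, wide enough that a transient lasting tens of seconds survives
detrending, while at 8 Hz it spans 6.25 s. (Specifying 6.25 s at all rates
was considered and rejected: at 2 Hz such a window subtracts most of a
realistic transient — rise ~2 s, decay ~5 s — leaving its detrended
excursion above the 0.4 threshold for under 5 s, so virtually no
physiological spike would pass the minimum-width rule.) At the trace edges
the window shrinks symmetrically rather than padding, which keeps a
constant trace at exactly zero and — because a symmetric average of a line
is the line — zeroes a pure linear trend exactly.

Spikes are maximal contiguous runs of detrended values strictly above 0.4
lasting at least 5 s (first to last supra-threshold sample). The spike time
is the run maximum (earliest on ties); the mean interspike interval (ISI)
uses spike times rather than onsets, as peaks are the more noise-robust
landmark after detrending. Raising the threshold or widening the minimum
width can only remove spikes, never add them.

Responding cells are classified from (spike count n, mean ISI, AUC):

| class | rule |
|---|---|
| SS (single spike)      | n = 1 and AUC < 500 |
| BS (burst of spikes)   | n > 1 and ISI·n ≤ 300 and AUC > 1000 |
| RS (repetitive spikes) | n > 1 and ISI·n > 300 |
| SU (sustained)         | n = 1 and AUC > 500 |

The rules are applied verbatim, including their gaps: n = 0, AUC exactly on
the 500 boundary, or a tight multi-spike train without burst-level AUC all
map to UNCLASSIFIED rather than being forced into a nearest class. A small
unclassifiable remainder is the expected behaviour of this rule set, not an
error state.

## The difference metric D

Two unit-mass histograms A and B on n shared bins are compared by

$$D = \tfrac{1}{2}\sum_{i=1}^{n} |A_i - B_i|,$$

the total variation distance between the binned distributions: 0 for
identical populations, 1 for non-overlapping ones, symmetric, and obeying
the triangle inequality. Unlike the Kullback–Leibler divergence
(deliberately not implemented), it is untroubled by empty bins, which are
ubiquitous in binned biological data.

**Binning.** The bin rule is the one genuinely open choice. The default is
50 equal-width bins spanning the pooled range of the two samples under
comparison. Coarsening bins can only merge opposing mass and therefore
never increases D, while very fine bins inflate D through sampling noise
(with k bins and m points per sample the noise floor grows like
√(k/m)); 50 bins at the sample sizes of large imaging screens keeps that
floor near 0.05–0.09 while resolving the distribution shapes, and it
reproduces the Gaussian calibration anchors below to within ±0.03. The bin
count is a parameter everywhere and is reported in every result object.

**Gaussian calibration.** To anchor interpretation, pairs of n = 5000
samples from unit-SD normal distributions (means 5 and 5 + δ) are binned on
shared edges and D is averaged over 10 replicate draws. As bins refine and
n grows, D(δ) approaches the analytic total variation distance between the
two densities, `1 − 2Φ(−δ/2)` = 0.383, 0.683, 0.866 at δ = 1, 2, 3 SD; at
the default settings the package obtains ≈0.38, 0.68, 0.86. Replicate
averaging (rather than a single draw) stabilises the estimate; a single
draw is available by setting `n_seeds = 1`. As an empirical yardstick, two
populations drawn from the *same* distribution at screen-scale n land
around D ≈ 0.05–0.1, so values in that range indicate baseline variation
rather than a meaningful difference, and reliable single-trial
discrimination between two stimuli would require D approaching 1.

**Class-count comparison.** Differences in class proportions are tested
with a two-sided exact Fisher test computed by direct enumeration: all 2×2
tables with the observed margins are enumerated and those no more probable
than the observed table (within a 1e−12 tie tolerance) are summed. This is
the probability-ordering convention for two-sidedness — stated explicitly
because conventions differ between implementations. A zero margin returns
p = 1 with a warning.

## The synthetic generator

`generate_trace()` builds archetype responses from a fast-rise (2 s linear)
/ exponential-decay kernel — chosen not as a biophysical model but because
every quantity the downstream rules consume (threshold crossings, widths,
areas) has a closed form for it. Class defaults at the long-term
acquisition settings (2 Hz, 20 min, stimulus at 60 s) sit well clear of
every class boundary:

| class | construction | ISI·n | AUC (fold·s, baseline-subtracted) |
|---|---|---|---|
| SS | one amplitude-3 transient, τ = 6 s | — | ≈ 20–35 |
| BS | five transients 35 s apart on a slowly decaying envelope (4 fold, τ = 400 s) | 175 | ≈ 1600 |
| RS | eight amplitude-3 transients 120 s apart | 960 | ≈ 180 |
| SU | 2-fold plateau held to the end | — | ≈ 2300 |

Noise is multiplicative Gaussian on intensity (SD 0.02 by default, a
photon-scaling heuristic), and a small linear multiplicative drift
(2×10⁻⁵ s⁻¹) is added specifically to exercise the detrending stage. The
baseline intensity (100 a.u.) is arbitrary since the analysis is
scale-invariant. `simulate_cells()` adds mild per-cell lognormal amplitude
scatter (σ = 0.08) and uniform 0–20 s onset jitter so populations are not
degenerate. `generate_population()` draws right-skewed (lognormal or
gamma) kinetic-parameter samples directly, emulating the skewed parameter
histograms characteristic of large screens, and
`generate_gaussian_surrogate()` supplies the idealized calibration samples.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: stochastic ISI variability within a
train, secondary calcium waves and intercellular (gap-junction/paracrine)
coupling, photobleaching beyond a linear drift, indicator saturation and
buffering, and mechanical mixing artefacts. Tests against it demonstrate
that the pipeline implements its stated rules and recovers known ground
truth, not that the four archetypes exhaust real response shapes.

## Numerical conventions and problem sizes

Ties break earliest (peak time, threshold crossings, run maxima).
Histogram bins are left-closed with the last bin closed; unit mass is
enforced to 1e−9. Integration is trapezoidal on the native (possibly
non-uniform) time grid, with the interpolated 10%-crossing point as the
first node. All randomness is `set.seed`-driven and every generator is
byte-reproducible given its seed.

The test suite runs at deliberately modest sizes: label-recovery uses 4
archetypes × 50 cells at 2 Hz / 20 min (≈ 480k samples end-to-end),
calibration uses 10 replicate pairs of n = 5000, the Fisher implementation
is swept against full enumeration over every 2×2 table with total count
≤ 30 (≈ 44,500 tables), and metric properties are checked over hundreds of
random histograms. These sizes give sub-percent Monte-Carlo error on every
asserted quantity while keeping the whole suite fast.

## Known limitations

* The classification thresholds (500/1000/300) are taken as given in
  fold·s and seconds; they are only meaningful for the baseline-subtracted
  AUC and recordings of roughly 20 minutes.
* The pre-stimulus exclusion rule reuses the responder threshold; with
  noise well above ~1.5% it becomes conservative (many flags), and the
  adaptive mode should be preferred.
* D depends on the binning; comparisons are only meaningful between D
  values computed with the same rule, which is why every result records
  its bin count.
* The pipeline consumes per-ROI traces; segmentation and pixel-to-trace
  reduction are upstream concerns.
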