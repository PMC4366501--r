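---
title: "Methods: detecting and testing micron-scale clustering of parallel fibre activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing micron-scale clustering of parallel fibre activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfclust)
```

# The problem

Cerebellar granule cells send parallel fibre (PF) axons through the
molecular layer, crossing Purkinje cell dendrites orthogonally. Whether the
PFs activated by a sensory stimulus are scattered at random or clustered on
the micron scale matters for dendritic integration: clustered input is a
far more effective trigger of dendritic spikes and synaptic plasticity than
dispersed input. With sparse calcium-indicator labelling, the activity of
individual neighbouring PF axons can be imaged in vivo, and three
statistical questions follow:

1. **Co-activity.** Do more fibres respond per imaging window than expected
   if fibres were recruited independently?
2. **Spatial structure.** Are the responding fibres closer together than
   complete spatial randomness (CSR) predicts?
3. **Mechanism.** Does the trial-to-trial variability of fibre pairs reveal
   shared presynaptic (mossy fibre) drive?

`pfclust` implements the full chain — event detection on fluorescence
traces, response classification, the binomial co-activation null, the
nearest-neighbour Monte Carlo CSR test, the coupling analysis, and the
labelling-density calibration — together with a ground-truthed synthetic
generator so every stage can be validated without raw data.

# The synthetic generator

`simulation_config()` fixes the study conditions. Defaults emulate sparse
in vivo PF recordings:

| parameter | default | meaning |
|---|---|---|
| `p_response` | 0.028 | fraction of labelled fibres responding to the stimulus |
| `spontaneous_rate_hz` | 0.4 | event rate in spontaneously active fibres |
| `frac_spontaneously_active` | 0.19 | fraction of fibres with spontaneous activity |
| `burst_size_dist` | P(1..4) = .10/.35/.40/.15 | events per evoked burst (mean 2.6) |
| `max_intraburst_freq_hz` | 172 | cap on instantaneous burst frequency |
| `latency_mixture` | N(10, 2) & N(22, 3) ms, equal weights | bimodal response latency |
| `event_amplitude_dff` | 0.50 ± 0.25 | transient amplitude (ΔF/F), floored at 0.05 |
| `noise_sd_dff` | 0.07 | baseline noise, giving event SNR ≈ 7 |
| `frame_rate_hz` / linescan | 32 / 1000 | population frame rate / linescan rate |
| `decay_tau_s` | 0.3 | transient decay constant (typical of OGB-1 in boutons) |
| `n_fibres_per_fov` | 4–21 | labelled fibres per 56 µm imaging window |

Choices where only peak locations or ranges are published: the latency
components' spreads (2 and 3 ms) and equal weights; intra-burst intervals
drawn uniformly in `[1/f_max, 3/f_max]` (consistent with two-to-three-event
bursts without committing to an ISI distribution); the amplitude floor of
0.05 ΔF/F (keeps drawn amplitudes positive); the 0.3 s decay constant (a
realistic single-bouton indicator decay; only ratios of decay to frame
interval matter for detection); and a per-trial response reliability of 0.5
for responsive fibres (responses to repeated stimuli show clear failures;
the value is exposed as `coupling$trial_reliability`).

Three point-pattern regimes are generated: CSR (uniform), regular
(jittered lattice, 10% of spacing — the labelled-fibre layout tends toward
regular spacing), and a Thomas cluster process (uniform parents, Gaussian
offspring displacement). Offspring falling outside the region are redrawn
from the same parent: the point count stays exact at the cost of a slight
inward bias for offspring of edge parents.

Shared-driver structure is generated by `simulate_correlated_binary()`:
units in a group fire together through a common Bernoulli driver
(probability `p_drive`, per-unit reliability `r`), plus an independent
background channel with rate `b` solved from
`p_drive·r + (1 − p_drive·r)·b = p_marginal`, so the marginal per-unit
rate is held at `p_marginal` for any coupling structure. The same
machinery is used at the fibre level (which fibres are responsive at all;
marginal 0.028) and at the trial level (which trials a responsive fibre
responds on; marginal `trial_reliability`).

**What the generator does not emulate:** movement artefacts, shot-noise
statistics and slow photobleaching (noise is i.i.d. Gaussian), indicator
saturation in bursts (amplitudes sum linearly), axial drift between fields
of view, and segmentation errors. Passing tests therefore validate the
statistical machinery under the stated noise model, not robustness to every
failure mode of real two-photon data; the Fourier high-pass covers slow
drift when it is present.

# Event detection

The detector follows the varying-baseline thresholding idea with three
numerical choices that matter:

* **Baseline**: rolling 20th percentile over a 2 s window. A low quantile
  tracks slow drift while ignoring the (positive-going) transients.
* **Noise scale**: `mad(diff(residual))/√2`. The residuals themselves are
  contaminated by transient decays (at 0.4 Hz and τ = 0.3 s roughly 15% of
  samples are elevated, inflating a plain MAD by ~35%); first differencing
  leaves white noise scaled by √2, touched only at the rare onset frames,
  which the MAD ignores.
* **Qualification**: an excursion above `threshold_sd` (default 2) noise
  s.d.s counts as an event only if it carries integrated evidence: some
  window of 2–8 consecutive frames must reach a windowed mean of
  `evidence_z` (default 4) in z-units. Plain 2 s.d. thresholding marks
  ~`pnorm(-2) ≈ 2.3%` of pure-noise frames, i.e. dozens of false events per
  two-minute trace; requiring integrated evidence exploits the fact that a
  real transient decays over many frames while a noise spike does not. The
  expected number of spurious events is bounded by the union bound
  `n_frames · 7 · pnorm(-evidence_z)` (≈ 6 per 2-min trace; realised rate
  ≈ 0.5 because a qualifying excursion must also contain a 2 s.d.
  crossing).
* **Hysteresis**: a triggered event ends only when the signal falls below
  `hysteresis_sd` (default 1) noise s.d.s, so a decaying transient
  re-crossing the threshold is not split into spurious "echo" events.

At the in vivo SNR regime (amplitude 0.50 ΔF/F over 0.07 noise, SNR ≈ 7)
the detector recovers >99% of isolated events with >95% precision and
sub-frame median onset error (`scripts/acceptance.R` recomputes this).
Under the full amplitude dispersion (0.50 ± 0.25, floored) part of the
events fall below the 2 s.d. criterion itself — an event of amplitude
0.1 ΔF/F is undetectable by *any* detector honouring that criterion — so
recovery is reported both ways: near-complete for events meeting the
criterion, necessarily partial overall. Two genuinely distinct events
closer than roughly one decay time are merged at 32 Hz; burst structure is
resolved from 1 kHz linescans instead.

Per-trial responses apply the event criterion inside
`[stimulus, stimulus + 0.2 s)` (the window covers both latency peaks with
margin at 32 Hz framing). The fibre-level responder rule — the
stimulus-triggered average must exceed 2 s.d. of its own 0.5 s pre-stimulus
baseline — is a max-over-window test and is anticonservative as an
automated screen (~20% false-responder rate on pure noise at these window
sizes); in this package ground-truth responder flags come from the
generator, and the STA rule is reported as the screening heuristic it is.

Burst decomposition differentiates the lightly smoothed linescan trace and
takes local maxima above a noise-scaled threshold (3.5 robust s.d.s of the
differenced trace) as event steps, with a 4 ms refractory spacing (just
under the fastest observed ~5.8 ms burst period). The smoothing-induced
onset shift is corrected by `(smooth_frames − 1)/2` samples, calibrated on
synthetic bursts (residual bias ≈ +0.5 ms at 1 kHz). Burst size recovery
is exact in ≥95% of synthetic trials at SNR 8; the latency histogram and a
two-component Gaussian mixture (EM via mclust, deterministic model-based
initialisation) recover the 10/22 ms bimodality within 2 ms; components
closer than three pooled s.d.s are flagged "not bimodal".

# Co-activity against the binomial null

If fibres were recruited independently, the number responding among `n_i`
labelled fibres in window `i` would be Binomial(`n_i`, `p`). The pooled
expected histogram is the sum of the per-window mass functions, and the
observed counts are compared by Pearson's χ² with tail bins pooled from
the top down until every expected count is at least `min_expected = 1`
(Cochran's minimum-expectation criterion), degrees of freedom = bins − 1.
Pooling to the textbook "expected ≥ 5" would collapse the table to two
bins here (expected counts fall off steeply at p ≈ 0.03) and discard
precisely the upper tail in which shared drive shows up; with the ≥ 1 rule
the test holds its size (rejection 0.045 at α = 0.05 over 1,000 null
experiments; p-values uniform by Kolmogorov–Smirnov) and detects a
shared-driver population (groups of 3, reliability 0.8) at p < 0.01 in
essentially every 85-window experiment. `p` is estimated from the same
dataset (responders over labelled fibres) by default, or supplied
externally.

Spacing is tested by comparing active-pair with all-pair distances within
windows (Mann–Whitney; the exact null is used below 50 observations
without ties, the tie-corrected normal approximation otherwise), and by a
pointwise 99.9% bootstrap envelope around the all-pairs CDF: subsets of
the all-pair distances of the size of the active-pair sample are resampled
with replacement (≥ 10,000 replicates), and the active CDF is judged
against the pointwise quantile band.

# The CSR Monte Carlo test

The test statistic is the mean nearest-neighbour distance (NND). Each of
`n_replicates` (default 10,000) replicates draws the same number of points
uniformly in the same rectangle; the two-sided p-value is
`2·min(r_low + 1, r_high + 1)/(n_replicates + 1)`, capped at 1, where the
ranks count replicates with mean NND at or below/above the observed value.
The add-one convention avoids p = 0; the direction is "clustered" when the
observed statistic falls below the null median, "regular" above. No edge
correction is applied — the null is simulated in the identical bounded
region, so edge effects cancel by construction. Rigid translations leave
the test invariant, and a fixed seed makes the result bit-reproducible.

Region conventions: in vivo, the recorded window (or bounding rectangle);
for slice anatomy, the bounding width of the labelled fibres times the
molecular-layer thickness. An `area_multiplier` of 2 reproduces the
doubled-area robustness check: genuine clustering survives region
enlargement (the observed mean NND is unchanged while the null mean grows),
whereas apparent regularity need not. Maps spanning several fields of view
are stitched by translating each field by its recorded offset and merging
duplicate fibres closer than 1 µm (below inter-fibre distances of
interest).

Calibration at the study geometry (15 points in a 56 × 150 µm strip,
2,000 replicates per test) puts the rejection rate at α = 0.05 within
[0.036, 0.064] over 1,000 experiments, and 5 × 3-offspring Thomas patterns
with σ = 3 µm are detected as clustered in >99% of runs.

# Coupling from trial-to-trial variability

For each within-window pair of co-active fibres, Pearson's correlation of
the binary response sequences (equal to the φ coefficient of the 2 × 2
table) is computed and its two-sided p-value — from the t-distribution on
`n − 2` degrees of freedom — is used as the pair's *probability of
independence*; below 0.05 the pair is *coupled*. The t-approximation on
200-trial binary data holds its nominal size (false-positive rate
0.0506 over 10,000 independent pairs); for short rasters a seeded
permutation option (≥ 10,000 shuffles, add-one p) is provided. Pairs in
which a fibre responded on all or no trials carry no variability
information and are flagged *indeterminate* — excluded from the
coupled-fraction denominator rather than counted as independent, which
would inflate the independent class. No multiple-comparison correction is
applied across pairs (the analysis reports the number of tests instead);
the coupled *fraction* is the quantity of interest, and its ~5%
false-positive floor is part of the reported expectation. Distance
dependence is summarised by Spearman's rank correlation of independence
probability with pair distance and a Mann–Whitney comparison of coupled vs
independent pair distances; the clustering of the *independent* pairs is
tested against all labelled pairs with the same distance machinery.

# Density calibration

In a section extending 1 µm along the fibre axis, a labelled fibre
contributes on average `1/3.7` boutons (boutons every 3.7 µm), so bouton
density × 3.7 estimates the labelled-fibre density, and dividing by the
PF packing density (5.5 µm⁻², midpoint of the published 5–6 range) gives
the labelled fraction. Sections thicker than the bouton spacing would
double-count fibres and are rejected. The generator inverts this model
exactly (Poisson bouton counts at the closed-form expectation), and the
round trip is unbiased to within 2 standard errors over 100 maps. The
expected labelled-PF count per Purkinje cell is the fraction times 150,000
fibres per dendritic tree, rounded to the nearest integer (0.38% → 570),
checked for plausibility against direct counts with a one-sample t-test.
The per-map fractions and their pooled mean are both reported, since
averaging per-region estimates and pooling counts differ slightly when map
areas differ.

# Problem sizes and reproducibility

All stochastic routines accept explicit seeds and restore the caller's RNG
state. The shipped analysis (`analysis/01_simulate.R` …
`06_density.R`) uses 85 fields of view, 10 two-minute traces, and
2,000–10,000 Monte Carlo replicates per test; the test-suite calibrations
use 1,000 experiments for size checks, 100–200 for power checks, and
10,000 pairs for the coupling floor — sizes at which the binomial
confidence intervals quoted above are decisive. `scripts/acceptance.R`
re-runs the whole chain from scratch at these sizes from a single
command-line seed.

# Known limitations

* The detector assumes positive-going transients on an additive Gaussian
  baseline; multiplicative noise and saturation are out of scope.
* At 32 Hz, events within roughly one decay time merge; burst statistics
  require linescan-rate data (the package refuses burst decomposition
  below 500 Hz).
* The CSR test uses the mean NND only — it is sensitive to aggregation
  and regularity but not to all departures from CSR (no Ripley's K by
  design, matching the published procedure).
* Coupling is restricted to pairs within one field of view (only those
  share trials); cross-window coupling is invisible.
* Distances are 2D sagittal-plane Euclidean; depth differences within the
  thin imaging window are ignored.
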