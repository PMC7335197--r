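---
title: "Methods: trial-based analysis of thalamocortical axon calcium signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based analysis of thalamocortical axon calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalaxon)
```

## The problem

Two-photon imaging of GCaMP6s-expressing thalamocortical axons in mouse
somatosensory cortex produces, per session, a set of ROI *segments* — small
pixel masks with a raw fluorescence trace and an accompanying neuropil trace —
recorded in 9 s trial epochs at 30 Hz while the animal performs a go/no-go
two-whisker discrimination: licking after C2 whisker stimulation is rewarded,
licking after B2 stimulation is punished with a timeout, and 20% of trials
carry no stimulus. The analysis questions are: which axons respond
significantly to which whisker and with what latency; how whisker-selective
each axon is; how C2- and B2-tuned axons are laid out in space; and how much
of the signal is locked to the animal's licking rather than to the stimulus.

Three axon classes with distinct physiology motivate the contrasts built into
the package: lemniscal first-order axons (VPM, sharply tuned, short latency,
strong lick-locked transients), paralemniscal first-order axons (POm-FO,
broader and slower, evoked responses enhanced on lick trials), and
higher-order cortex-recipient axons (POm-HO, weakly tuned, slowest, likewise
lick-enhanced).

Everything runs on synthetic sessions with known ground truth; no imaging
data are required. The same functions apply unchanged to real ROI traces
organized in the same structures.

## Pipeline

### Segment merging

A single axon appears as several disconnected segments. Segments whose raw
full-session traces have Pearson correlation above 0.8 are linked, and
connected components (single linkage) form putative axons; this matches the
"sets of correlated segments" notion and needs no cluster-count choice.
Merged traces are pixel-count-weighted averages, and the neuropil signal —
each segment's neuropil trace times its estimated coefficient, which we take
as input rather than estimate — is subtracted with the same weights.

Two interpretation points were open and are settled as follows. Correlation
is computed on *raw* traces, before neuropil subtraction: that is the signal
available at this pipeline stage, and the shared neuropil is weak relative to
evoked transients, so it does not create spurious merges at the 0.8 level
(verified: on default synthetic sessions the recovered partition matches
ground-truth parentage with adjusted Rand index 1.0). Single linkage can in
principle chain distinct axons; the threshold of 0.8 over full sessions makes
that vanishingly rare in practice, and the interactive manual stitching used
on real data is out of scope.

### Baseline, noise and normalization

Slow drift (bleaching, slow neuropil changes) is estimated as the signal
*mode* in consecutive 3000-frame segments — about 100 s, long enough that
baseline frames dominate — followed by a least-squares polynomial of order 5
through the (segment center, mode) points, evaluated at every frame.
The per-segment mode is the **half-sample mode**: recursively keep the half
of the sorted sample with the smallest range. It is parameter-free (a
histogram mode would depend on bin width) and ignores sparse positive
transients entirely, so the baseline is invariant to transient amplitude.
Two numerical consequences are worth knowing. First, the half-sample mode has
slow (n^-1/3) convergence on Gaussian data, so individual segment modes
scatter by ~0.25 SD at 3000 frames; the polynomial fit averages this out at
session scale (tests use 90,000–100,000-frame traces, where baseline RMSE
stays below 0.15 noise-SD under 5% transient contamination). Second, on
*noiseless* smooth monotone input the value-distribution mode sits at the
flattest point of a segment, not at its center, so exact polynomial traces
are recovered only to within the per-segment excursion; with any symmetric
noise present the mode recenters on the curve. Traces shorter than 3000
frames form a single segment, and the polynomial order is capped at
(number of mode points − 1) with a warning.

Because GCaMP fluctuations are nonnegative, fluctuations *below* the baseline
are noise alone: assuming symmetric Gaussian noise, the noise SD is the RMS
of negative residuals (the SD of the mirrored set). The normalized trace is
(trace − baseline) / noise SD. Adding a constant or scaling the trace leaves
the normalized signal unchanged.

For evoked analyses, trials are grouped by condition × lick (plus a pooled
group) and z-scored against the pooled distribution of the 0.5 s pre-response
quiet window across the group's trials. Pooling across trials (rather than
per-trial 15-frame windows, which would be unstable) is our reading of the
"distribution" formulation; a group whose pre-window SD is zero is marked
invalid and excluded.

### Significance, latency, selectivity

Values are noise-normalized and pre-window z-scored, so under the null each
bin is standard normal and the per-bin statistic over n trials is
mean·sqrt(n) with an upper-tail normal p (a z-test, not a t-test — the null
variance is 1 by construction). −log10(p) is computed on the log scale so it
does not saturate when p underflows. A response is significant when
−log10(p) > 10 in at least 3 consecutive bins within the 2 s response
window — the consecutive-bin requirement exploits slow GCaMP6s dynamics and
makes the null false-positive rate negligible (0 calls in 10,000 simulated
null axons). Latency is the first bin with −log10(p) > 5, a softer threshold
so onset is not clipped; it is reported only for significant responses.

The whisker selectivity index is (C2 − B2)/(C2 + B2) of mean z over the 2 s
response window; negative windowed amplitudes are floored at zero first so
the index stays in [−1, 1], and when both floored amplitudes are zero the
index is undefined and the axon is excluded from selectivity summaries.
|WSI| ≥ 0.75 defines "tuned".

The early-window comparison contrasts lick vs no-lick amplitudes over
[0, 0.266) s — the last full 30 Hz frame before the 0.29 s mean reaction
time — with a paired two-sided Wilcoxon across axons (p = 1 by convention
when all differences are zero); 0.2 s and 0.4 s windows are exposed as
robustness checks. "Lick trials" means lick = TRUE regardless of reward;
reward delivery itself is not modeled as a signal.

### Spatial maps and ellipse overlap

Each pixel inherits its axon's windowed condition amplitudes and WSI; pixels
claimed by more than one axon are excluded rather than averaged (rare, and
avoids double counting). The tuning map is built from **no-lick** trials:
licks are much more frequent on rewarded C2 trials, so pooled-trial WSI of
lick-transient-carrying axons is biased toward C2, whereas the no-lick map
isolates sensory tuning — consistent with gating sensory responsiveness on
the no-lick condition.

Strongly tuned pixel populations (WSI > 0.75 for C2, < −0.75 for B2) are
summarized by 90% confidence ellipses: semi-axes sqrt(λᵢ·q) from the
eigendecomposition of the coordinate **covariance** matrix, q the χ²(2 df)
quantile at 0.9. (The source formulation mentions a correlation matrix, but
a correlation matrix discards scale and leaves the intersection *area*
ill-defined; the covariance ellipse is the standard construction and is what
we implement.) The overlap index is the intersection area over the mean
ellipse area — 0 for disjoint, 1 for identical domains. Intersection is
computed by Sutherland–Hodgman clipping of 512-vertex polygonal boundaries;
clipping two convex polygons is exact, the only approximation is the
polygonization (relative area error ~2·10⁻⁵ at 512 vertices), and the result
is validated against a 10⁶-point Monte-Carlo rejection oracle to 1%.

### Lick timing

Per-trial response latency is the time at which the running sum of the
rectified z-scored signal, over a 3 s window from the response-window onset,
first reaches 50% of its total (ties broken toward earlier bins; trials with
no positive mass are excluded). Rectification is required for the running sum
to behave as a cumulative distribution; the raw-z variant is exposed behind a
switch. A median-mass latency is deliberately insensitive to a small early
stimulus-locked component when a later lick-locked component dominates.
Latencies are correlated (Pearson, two-sided p, flagged at p < 0.05) with
first-lick reaction times on non-rewarded B2 lick trials only, where licking
patterns are comparable across trials. Event-triggered averages (mean ±
s.e.m. around event times) serve spontaneous-lick and bout-offset analyses.

### Session inclusion and orchestration

Behavioral performance is (hits + correct rejections) / stimulus trials;
sessions are included when performance is *strictly* above 0.6.
`run_pipeline()` chains simulate → merge → normalize → z-score → response
statistics → spatial overlap → lick timing from one master seed and writes
CSV tables with a provenance header (package version, seed, trial count,
frame rate), so every output row is traceable to a seed and configuration.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* **Task schedule** — 9 s trials, stimulus at the end of a 2 s quiet window,
  2 s response window, 80% stimulus trials split evenly C2/B2, and a minimum
  4.5 s inter-trial gap giving a minimum inter-stimulus interval of exactly
  13.5 s; pre-trial licking delays a trial start with probability 0.3 by up
  to 3 s (the delay parameters are exposed; real lick-bout structure is
  richer and not modeled). The stimulus command is 5 contiguous single-period
  40 ms sine pulses (200 ms support), sampled at bin midpoints so support and
  per-pulse zero mean are exact.
* **Behavior** — lick probabilities 0.85 / 0.35 / 0.10 for C2 / B2 / none
  (a trained animal; gives ~0.7–0.75 fraction correct, above the 0.6
  inclusion bar), reaction times normal(0.29, 0.18) truncated to
  (0, 2] s, drawn by inverse CDF.
* **Calcium events** — per-condition evoked amplitudes follow
  A_C2 = A(1 + w)/2, A_B2 = A(1 − w)/2 so the WSI of noiseless amplitudes
  equals the true selectivity w exactly, making recovery tests sharp. Events
  are convolved (exact sparse addition) with a peak-normalized GCaMP6s kernel
  (1 − e^(−t/0.18 s))·e^(−t/1.8 s); the time constants follow published
  GCaMP6s kinetics and are configurable. Event amplitudes are expressed in
  units of the axon's noise SD and carry per-trial multiplicative gamma
  jitter (CV 0.7, mean 1, independent across axons) — trial-to-trial
  variability is a real feature of calcium responses, and it is also what
  keeps similarly tuned axons from correlating above the 0.8 merge threshold.
* **Class phenomenology** — VPM-like: |w| in 0.8–1, latency 40–70 ms,
  amplitude 6–10 noise-SD, lick-locked transients of gain 4–6 at the reaction
  time, no lick gain modulation, and C2-/B2-preferring axons laid out in two
  disjoint spatial clusters. POm-FO-like: bimodal |w| 0.6–0.9, latency
  120–180 ms, multiplicative lick gain 1.4–1.7 on evoked amplitude, no lick
  transients, spatially intermingled. POm-HO-like: |w| < 0.3, latency
  150–250 ms, lick gain as POm-FO. These ranges were chosen once to mirror
  the qualitative class contrasts; they are configuration, not fitted values.
* **Nuisance structure** — 3rd-order polynomial drift (coefficients within
  ±3 fluorescence units over the session), a shared slow neuropil trace added
  per segment with coefficient 0.5–0.8, and Gaussian noise split into shared
  and independent components per segment,
  σ²_shared = ρ·σ², σ²_indep = (1 − ρ)·σ² with ρ = 0.9, so within-axon
  segment correlation is ρ by construction (above the merge threshold) while
  the per-segment noise SD equals the configured σ.
* **Frame conventions** — 0-based frames, time 0 at trial start, half-open
  windows [start, end); traces are trial-concatenated (no inter-trial frames
  recorded), so trial k's stimulus onset sits at frame k·270 + 60 while
  wall-clock onset times keep the inter-trial gaps.

What the generator does **not** emulate: pixel movies and motion artifacts
(the unit is the ROI trace, as emitted by upstream segmentation), estimation
of neuropil coefficients, response failures or adaptation across trials,
correlated noise between different axons, lick-bout substructure, and
orofacial video (reaction times are inputs). Passing tests therefore
demonstrate correctness of the analysis under the stated generative
assumptions — trial-locked sparse events, symmetric noise, slow smooth
drift — not robustness to every artifact of real imaging.

## Problem sizes and reproducibility

The test suite and the acceptance script run, by choice, at desk scale:
10,000 null axons for the false-positive suite; 200 axons × 30 trials per
condition for power/latency/WSI recovery (detection power 1.0, median latency
error 1 bin, WSI correlation ≈ 0.99); 100,000-frame traces for baseline and
noise recovery; 100 random ellipse pairs against 10⁶-point Monte-Carlo; and
100-axon single-class sessions of 100 trials for the class contrasts
(overlap index, lick-timing correlation, early-window modulation, lick-trial
WSI shift). All randomness flows from explicit integer seeds; identical
seeds give bit-identical trial tables, traces and result tables.

## Known limitations

* Headline real-data population values (e.g. overlap-index means, group
  p-values) depend on biological effect sizes and sample sizes not
  reproducible from synthetic sessions; the package asserts the *directions*
  and the recoverability of its own ground truth instead.
* Single-linkage merging inherits the usual chaining risk if applied to data
  whose cross-axon correlations approach the threshold.
* The half-sample mode's noiseless-input bias (above) is irrelevant for real
  noisy recordings but visible in idealized simulations.
* The z-test assumes the pre-window distribution is a valid null for
  post-stimulus bins; strong pre-stimulus events (e.g. kernel tails from the
  previous trial at very short inter-trial gaps) would violate this, which
  the 13.5 s minimum inter-stimulus interval makes negligible here.
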