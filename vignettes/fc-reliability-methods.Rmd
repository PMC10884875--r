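---
title: "Methods: test-retest reliability of functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional connectivity (FC) — the Pearson correlation between BOLD time
courses of distinct brain units — is only useful as an individual-difference
measure insofar as it is reliable: measured twice in the same person, it
should give the same answer. Reliability varies regionally across the
cortex, depends on scan length, head motion and signal quality, and is
modulated by what the participant is doing in the scanner. This package
implements the analysis chain needed to quantify those effects on densely
sampled multi-session data (many sessions per subject, rest plus several
task states), and a synthetic BOLD generator with planted ground truth so
that every stage of the chain can be validated against a known answer.

## Reliability statistics

Two complementary statistics are implemented.

**FC test-retest correlation (FC-TRC).** Sessions are split into two halves
(with ten sessions: 1–5 versus 6–10). One connectome is built per half from
the concatenated, per-run mean-centered frames. For each unit $u$, FC-TRC is
the spatial Pearson correlation between $u$'s connectivity row in the first
half and the same row in the second half, excluding the self-entry from both
vectors. Raw correlation values are correlated directly, without Fisher
z-transformation: the statistic is defined as the spatial correlation of the
two connectomes, and the z-transform is a monotone map that would change the
value while adding no information at the typical |r| range involved. FC-TRC
is a per-unit map in $[-1, 1]$.

**Edge-wise ICC(2,1).** For each connectome edge, the subjects × halves table
of edge weights is decomposed by the two-way random-effects ANOVA. With $n$
subjects and $k = 2$ halves,

$$\mathrm{ICC}(2,1) \;=\; \frac{MS_R - MS_E}
 {MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}
 \;=\; \frac{\sigma^2_\lambda}{\sigma^2_\lambda + \sigma^2_\pi + \sigma^2_\epsilon},$$

the between-subject edge variance over the total of the subject
($\sigma^2_\lambda$), half/rater ($\sigma^2_\pi$) and residual
($\sigma^2_\epsilon$) components. The method-of-moments components can come
out negative in small samples; they are reported as computed, with a flag,
and truncation at zero is an explicit option rather than silent behavior,
so that aggregate summaries are not biased upward invisibly.

ICC values are conventionally banded as poor, fair, good, excellent. The
printed convention leaves the intervals (0.59, 0.6) and (0.74, 0.75)
unassigned; the classifier here closes them deterministically as poor
$(-\infty, 0.4]$, fair $(0.4, 0.6)$, good $[0.6, 0.75)$, excellent
$[0.75, \infty)$, so that every finite value has exactly one band.

## Preprocessing

The temporal cleaning chain shapes everything downstream, so it is part of
the package even though spatial preprocessing (registration, surface
mapping) is not.

* **Motion censoring.** Framewise displacement (FD) is the sum of absolute
  frame-to-frame differences of the six rigid-body parameters, rotations
  converted to arc length at a 50 mm head radius. Frames with FD above
  0.20 mm are censored. Censoring is logical: the mask composes
  monotonically (hence is idempotent) and frames are dropped only when a
  statistic extracts them.
* **Detrending and confound regression.** Per unit, an intercept, linear
  and quadratic trend plus any confound columns (and, by default, the
  global signal) are removed by OLS *fit on retained frames only*, so that
  high-motion frames cannot leverage the fit, with the projection then
  applied to the full grid.
* **Band-pass.** A zero-phase forward–backward order-2 Butterworth filter
  at 0.01–0.08 Hz, applied on the full frame grid with censored frames
  linearly interpolated first. Filtering before dropping frames avoids
  spectral leakage from gaps; interpolating the censored frames prevents
  motion spikes from ringing through the IIR filter. Statistics afterwards
  use retained frames only.
* **Volume matching.** When states are compared, every subject × state
  series is truncated to the global minimum retained total of a reference
  state (conventionally the shortest task), keeping the earliest frames —
  the tie-break has to be fixed somehow, and "earliest" is reproducible and
  favors no state. This removes scan length as a confound between states.

The pipeline order is clean-then-parcellate. The two operations commute
only when all confounds are global signals; with per-unit trend fits they
do not, and the order is therefore fixed and tested rather than left to
the caller.

## Task regression

Task-evoked responses are modeled with finite impulse response (FIR) bases:
one free regressor per post-stimulus time bin, no assumed hemodynamic
shape. The standard design table is: motor conditions (left/right hand,
left/right foot, tongue) at 7 bins × 2.2 s (15.4 s window); language
sustained blocks at 1 bin × 121 s, block cues at 1 bin × 2.2 s, and trial
events at 8 bins × 1.5 s (12 s window); memory stimulus × repetition
conditions at 8 bins × 1.5 s.

Designs are built on a 0.1 s microtime grid and box-car averaged onto the
frame grid, so a 1.5 s bin under a 2.2 s frame contributes the fraction of
the frame it covers. The microtime convention is a genuine free choice
(packages differ); fractional-coverage averaging was chosen because it is
exact in the limit of fine microtime and has no phase bias. GLMs are fit
per unit by OLS with row deletion of censored frames; the per-condition
parameter estimate (PE) is the uniform average of that condition's bin
betas (weight $1/n_{\text{bins}}$, e.g. 0.125 for 8 bins). Aggregation
run → session → subject → group is unweighted fixed-effects averaging of
PEs; mixed-effects inference on statistic images is out of scope because
only PE magnitudes feed the downstream attribution model. Residual series
from the FIR fit define task-residualized connectomes.

## Consensus networks

Parcels are assigned to functional networks from a group-averaged
connectome: diagonal zeroed, edge-density thresholds of 2, 3, 4 and 5%
applied (keeping the largest-weight edges by signed value, preserving their
weights), two-level community detection on each thresholded graph
(map-equation/Infomap by default, with a deterministic modularity optimizer
as an alternative), and a consensus across thresholds: the co-assignment
probability matrix is thresholded at 0.5 and re-clustered iteratively until
all clusterings agree (cap 20 iterations). The 0.5 threshold is the
standard consensus-clustering default; the density grid uses integer
percents because only the 2–5% range is conventionally fixed, not the step.
Communities beyond the expected network count are treated as ambiguous and
their parcels reassigned to the modal network among their spatial
neighbors, falling back to the globally largest network for isolated
parcels (counted and reported).

## Attribution models

Regional signal properties are computed per unit: tMean (temporal mean),
tSD (temporal SD) and tSNR (their per-run ratio), each computed per run over
retained frames and averaged run → session → subject without frame
weighting (a frame-weighted option exists). tSNR averages the per-run ratio
rather than taking the ratio of averages — the two differ, and the per-run
convention is asserted in tests. tMean and tSNR are computed on the raw
(pre-cleaning) series: after detrending the mean is ~0 by construction, so
computing tMean post-cleaning would be vacuous. tSD is offered on both, raw
by default. The absolute scale of tMean is arbitrary (no mode
normalization is modeled), so only its spatial and cross-state structure is
meaningful.

Maps are linked by parcel-wise OLS (slope, $R^2$, uncorrected two-sided p,
standardized β, with the identity $\beta_{std}^2 = R^2$ checked for simple
regression), optionally excluding low-reliability networks; by
network-wise standardized βs; by a Spearman monotone-trend diagnostic for
relationships too nonlinear for a line; and by a per-parcel linear mixed
model

$$\text{reliability} \sim \text{tMean} + \text{tSD} + \text{PE} + (1 \mid \text{participant}),$$

fit by REML with all predictors standardized globally across the fitting
table (not per subject) and PE fixed at 0 for rest. The model is fit once
per parcel, with subjects × states as observations, yielding β maps per
predictor; singular fits are flagged per parcel rather than failing the
map.

## The synthetic generator

The generator emulates the structure of a densely sampled precision-fMRI
study: 9 subjects × 10 sessions at TR 2.2 s, one rest plus two motor, two
language and three memory runs per session by default. Its signal model is

$$Y = \mu + \mathrm{diag}(s)\,(L z) + \text{evoked},$$

with $\mu, s$ per-parcel mean/SD profiles, $L$ a Cholesky factor of the
subject's planted correlation matrix, and $z$ unit-variance Gaussian noise
with AR(1) autocorrelation (coefficient 0.4) so that realistic
autocorrelation survives the band-pass. The planted structure is a block
correlation matrix — within-network correlation 0.35, between-network 0.05
by default — perturbed per subject by symmetric Gaussian edge noise
(SD 0.06) and projected back to a positive-definite correlation matrix by
eigenvalue clipping at $10^{-6}$ and rescaling to unit diagonal (the
simplest reproducible projection). The stable subject perturbation is what
gives ICC a recoverable target. Evoked responses are FIR regressors times
per-bin amplitudes, added only in each task's engaged parcels, so the
variance added outside engaged parcels is exactly zero. Motion traces have
baseline FD ~ |N(0.05, 0.02)| mm with spikes of U(0.25, 1.0) mm at a
configurable probability, encoded into the six parameters so that
recomputing FD from them reproduces the trace exactly. Per-parcel mean/SD
profiles default to deterministic ramps over 600–1000 a.u. and 5–30 a.u. —
order-of-magnitude plausible free parameters, not estimates from any real
dataset. The memory task's jittered inter-stimulus interval is sampled
uniformly over its stated range, since only the range is conventionally
specified; synthetic schedules follow block structure, not printed total
durations, where the two cannot be reconciled exactly.

Everything is deterministic: each run's seed is a fixed integer function of
the study seed and the (subject, session, state, run) indices, so the same
specification reproduces every file bit-identically.

What the generator does *not* emulate: spatial structure (no voxels,
surfaces or registration errors), physiological noise, signal dropout,
scanner drifts beyond polynomial trends, or distance-dependent motion
artifacts. Validation on this generator therefore demonstrates that the
statistics recover what they are defined to recover under the stated noise
model — not that real acquisitions satisfy that model.

## Validation sizes and numerical choices

The test suite and the acceptance script validate at deliberately modest
problem sizes, chosen as the smallest instances at which each property is
cleanly identifiable: oracle-equivalence checks on 4–50-frame toy matrices
(agreement to $10^{-10}$); ICC recovery at 20 subjects × 200 edges for
between/total ratios 0.2/0.5/0.8 (±0.05); FC-TRC scan-length monotonicity
at retained lengths 250/1,000/4,000 frames and 30 parcels; task-engagement
locality and task-regression attenuation on the default 9 subjects at 40
parcels and two sessions; mixed-model recovery at 9 subjects × 4 states;
and consensus recovery of a planted 17-network structure at 102 parcels.
Dense-scale analyses (tens of thousands of units) use the same code paths
on larger matrices.

Other numerical conventions: connectome diagonals are stored as 1 and
excluded from all statistics; zero-variance units become missing rows
(never silent zeros) and are excluded pairwise from row correlations with
the exclusion count logged; density-threshold ties at the cutoff break by
lexical (row, column) order; communities are labeled by descending size
with ties by smallest member id.

## Known limitations

Vertex-level community detection, alternative reliability coefficients
(ICC(1,1), ICC(3,1), identification rates), spatial-autocorrelation-aware
inference (spin tests), hemodynamic-shape bases, and prewhitening are out
of scope. Statistics reported from the real study this design emulates
depend on cluster-scale preprocessing of the actual acquisitions and are
not reproducible from synthetic data; the package validates the methods,
not those numbers.
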