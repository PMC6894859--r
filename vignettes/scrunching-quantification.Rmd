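---
title: "Quantifying planarian oscillatory gaits from length traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planarian oscillatory gaits from length traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrunchr)
```

## The behavioral readout

Freshwater planarians normally glide on beating cilia with an essentially
constant body length. Noxious stimuli switch them to *scrunching*, a
muscle-driven escape gait of repeated body-length oscillations, and a
disruption of cilia beating produces *peristalsis*, a second oscillatory
gait of smaller amplitude. A single-worm recording is therefore reduced
to one signal — body length over time — and an oscillatory gait is
described by four parameters computed over a window of consecutive
cycles:

* **frequency** $f$ — oscillation cycles per second, estimated as the
  number of cycles divided by the trough-to-trough span of the window;
* **maximum elongation** $A$ — per cycle, (peak − trough)/peak, with the
  lower of the two bounding troughs; averaged over the cycles of the
  window;
* **relative speed** $v = f \times A$ in body lengths per second, an
  exact identity by construction;
* **asymmetry** $a$ — the fraction of cycle time spent elongating,
  $\sum_k (t^{peak}_k - t^{start}_k) / \sum_k (t^{end}_k - t^{start}_k)$
  (time-weighted across the window rather than averaged per cycle).
  Values above 0.5 — elongation slower than contraction — are the
  hallmark that separates scrunching from near-symmetric peristalsis.

Two conventions here were genuinely open. Maximum elongation could also
be computed from the global window extremes; the per-cycle mean was
chosen because the global version conflates distinct cycles under noise
(the two agree exactly on noise-free periodic traces). Frequency uses the
trough-to-trough span rather than the mean of reciprocal periods because
the two are identical on clean data and the span is less sensitive to a
single misplaced trough.

## The synthetic recording generator

No raw recordings ship with the package, so the generator is the
reference instrument: it produces length traces (and optionally rendered
image stacks) with exact ground truth. The oscillation is a cosine-eased
ramp between trough and peak: within a cycle of period $1/f$ the
elongation phase occupies a fraction $a$ and the contraction phase the
rest, each following $\tfrac12(1-\cos\pi x)$. This keeps peaks
differentiable — so peak detection faces realistic, rounded extrema as in
real traces — while the ground-truth parameters remain exact. Gliding is
a constant trace; an optional gliding lead-in precedes oscillation onset,
which mirrors recordings that begin before the stimulus takes effect and
gives the baseline-normalization step a genuine gliding segment.

Defaults follow the characterized regimes: the scrunching presets use the
published per-species parameters (D. japonica 0.72 Hz / 0.52 / 0.59,
S. mediterranea 0.40 / 0.44 / 0.62), the peristalsis preset 0.26 / 0.23 /
0.50, recordings default to 10 frames per second, and body length is
100 px. The published plots are normalized, so the absolute peak length
is unconstrained by the study; `peak_factor = 1.2` (peak at 1.2 gliding
lengths) was fixed once as a visually typical excursion. Noise is
additive i.i.d. Gaussian per frame (SD as a fraction of gliding length),
the simplest model consistent with the small jitter of real traces;
`noise_sd = 0.02` is used in the recovery checks.

Rendered frames draw a dark worm on a light background as an elliptically
tapered body along an optionally sinusoidally bent spine — an exact
ellipse silhouette when straight. The taper matters: the moment-based
equivalent ellipse of an elliptical silhouette has major axis equal to
the body length, whereas a capsule (rectangle with round caps) would read
12–15% long under the same measurement. Real worm silhouettes taper
toward head and tail, so the ellipse is also the more faithful shape. The
worm drifts across the frame at a configurable speed (default 0.3 body
lengths/s) so that the automatic background — the per-pixel temporal
median of the stack — never contains the worm; clips must be long enough
that no pixel is worm-covered in half its frames. Bends are static per
frame with no self-occlusion, matching the restriction of the analysis to
straight-line locomotion.

What the generator does *not* emulate: latency and desensitization time
courses (onset/offset dynamics of real exposures), head-turning and other
non-oscillatory behaviors, mucus trails, illumination drift, multi-worm
scenes, and non-Gaussian segmentation artifacts. Passing tests therefore
certify the measurement chain — given a length signal of the stated
family, parameters are recovered — not robustness to every pathology of
real video.

## From images to a length trace

The extraction chain is deliberately the standard one: background
subtraction (absolute difference against an explicit raster or the
temporal median), Otsu thresholding (a fixed threshold is available for
reproducibility), retention of the largest 8-connected component above
`min_area` (labeling is implemented in-package because the available
library routine is 4-connected), and the intensity-equivalent ellipse via
image moments: the reported length is $4\sqrt{\lambda_{\max}}$ of the
pixel-coordinate covariance matrix, the same "fit ellipse" measurement
common imaging software reports, with a closed-form oracle. Frames where
segmentation fails become trace gaps filled by linear interpolation
(leading/trailing failures are dropped; more than `max_invalid_fraction`
= 20% failures abort), preserving the uniform time grid that cycle
detection requires. Frames whose minor/major axis ratio exceeds
`bend_ratio_max` = 0.35 are flagged as bent, and the analysis-window
selector refuses cycles that overlap flagged spans, because the
straight-line length underestimates a bent worm. Pixel centers sit at
integer coordinates, frames are 0-indexed, and time is index/fps.

Traces are normalized by the average gliding length: the mean over a
gliding window, either given explicitly or chosen automatically as the
lowest-variance sliding window (default width 3 s), which on a
gliding-then-scrunching recording lands inside the gliding segment.

## Cycle detection and parameter readout

Detection runs on a boxcar-smoothed copy of the trace (centered moving
average, default 0.3 s, edges truncated) and proceeds in three steps:
strict alternating extrema (plateaus collapse to their midpoint,
endpoints count), zigzag pruning of adjacent extremum pairs whose
amplitude falls below `prominence_frac` = 0.10 of the median length, and
a minimum peak spacing `min_period_s` = 0.5 s. The defaults separate the
characterized amplitude regimes (0.23–0.52) from the noise floor and
admit frequencies up to 2 Hz; both are configurable. Cycles are assembled
trough → peak → trough, and the analysis window is the earliest run of at
least `min_cycles` = 4 consecutive clean cycles, matching the convention
of cropping a recording to its first sustained stretch of straight-line
oscillation; with no qualifying run the trace is reported as
insufficient oscillation, which downstream becomes a gliding call.

Extremum values and times are then *refined on the raw trace* with a
two-sided parabola: $y = v - c_L (t - t_p)^2$ left of the apex and
$y = v - c_R (t - t_p)^2$ right of it, the apex position scanned on a
0.05-sample grid and the three remaining coefficients solved by least
squares in a window that scales with the detected cycle length (±2 to ±6
samples). Two numerical facts force this choice. First, reading values
off the smoothed trace biases sharp troughs upward by up to ~0.07 body
lengths at the fast regimes — boxcar attenuation grows with curvature —
so values must come from raw samples. Second, an asymmetric gait has
different curvatures on the two sides of every extremum (elongation slow,
contraction fast), which biases the usual single-parabola vertex toward
the flatter side by a constant fraction of the frame interval; at 10 fps
that error alone consumes the asymmetry error budget. The kinked model is
unbiased in exactly this situation. Level-crossing timing schemes were
rejected on first principles: every level-occupancy functional of a
waveform whose phases are time-symmetric is invariant under time
reversal, so such schemes cannot carry any asymmetry information at all.

Scrunch *counts* (used for amputation-style assays) discard any cycle
whose peak precedes the end of the initial monotone contraction from
t = 0, since the immediate post-stimulus contraction is not a scrunch.
Population summaries report mean ± SD per parameter with the population
speed averaged over per-worm speeds, never the product of means; reported
values are rounded to two decimals half-up, the convention of the
published tables.

## Gait classification

The study distinguished gaits by comparing the four parameters with
published reference values; the package makes that decision rule explicit
and deterministic. A packaged reference table carries the per-species
scrunching references (from amputation experiments) and the
S. mediterranea peristalsis reference as mean ± SD with N. A summary is
classified as:

1. **gliding** if oscillation was insufficient or maximum elongation is
   below `amplitude_floor` = 0.10 — oscillations that small are within
   the noise of gliding recordings;
2. otherwise the gait whose centroid minimizes the standardized Euclidean
   distance $d_g = \sqrt{\sum_k ((x_k - \mu_{k,g}) / \sigma_{k,g})^2}$
   over the four parameters;
3. a species without its own peristalsis reference borrows the other
   species' entry (amplitude and asymmetry dominate that comparison, and
   no species-specific alternative exists);
4. near-ties ($|d_s - d_p| <$ 0.05) fall back on the scrunching
   hallmark: asymmetry above `asym_threshold` = 0.55 means scrunching.

`amplitude_floor` and `asym_threshold` are calibration constants exposed
as arguments. Welch's t-test from summary statistics (mean, SD, N per
group; Welch–Satterthwaite degrees of freedom) reproduces the
significance comparisons against references; the pooled-variance variant
of the classical student's t-test is available since the original reports
do not state which was used, and the t-tests are attached as a report —
they never drive the label.

## Behavior scoring and window tests

Scored recordings label each worm in six 15-s intervals over 90 s as
scrunching (S), non-scrunching reaction (R), or no reaction (N), by two
blind reviewers. Aggregation averages the per-label counts across
reviewers within each replicate and interval, converts to percent of
worms, then reports mean and sample SD (n−1) across replicates; percent
reacting counts S or R and thus never falls below percent scrunching.
Interval $k$ covers $((k-1)\cdot 15, k\cdot 15]$ seconds, so the "15–30 s"
window is interval 2 (a "16–30 s" spelling is accepted as the same
interval) and "31–45 s" is interval 3.

The early-window comparison counts outcome-positive worms per condition
(positive = carrying the outcome label in any interval of the window),
averages the two reviewers' counts — which can be half-integers — and
rounds half-up before forming the 2×2 table, since the exact test needs
integers; floor and ceiling are available because the original rounding
is not documented, and for the same reason the original per-window
p-values are not treated as reproducible targets. The Fisher test itself
is implemented from the hypergeometric distribution: the two-sided p sums
the probabilities of all tables with the observed margins whose
probability does not exceed the observed one (within relative tolerance
1e-7), the odds ratio is the sample ratio $ad/bc$, and a table with a
zero margin is degenerate with p = 1. An exhaustive enumeration over all
2×2 tables with margins ≤ 12 serves as its oracle. Under identical
generating conditions the discrete p-value is conservative rather than
concentrated at 1 — the null property asserted by the tests is
$P(p \le \alpha) \le \alpha$, with the median p above 0.5.

## qPCR support

Primer efficiency comes from the standard serial-dilution curve: the OLS
slope of Ct against log10 dilution gives efficiency
$(10^{-1/\text{slope}} - 1) \times 100$, used as a quality-control range
(roughly 87–116% in the characterized assays), not as a correction.
Knockdown uses plain ΔΔCt: technical replicates are averaged on the Ct
scale (standard practice; the alternative is not documented in the
original protocols), ΔCt = target − housekeeping within each sample and
biological replicate, ΔΔCt against the control population per replicate,
and relative expression $2^{-\Delta\Delta Ct}$. The reported value is the
mean of per-replicate relative expressions ("mean of all replicates" is
read on the expression scale; averaging ΔΔCt first is available as an
option), and knockdown percent is one minus that mean. ΔΔCt is invariant
to any per-replicate plate offset, which the synthetic Ct generator
deliberately injects.

## Problem sizes and numerical checks

The shipped checks run at the study's scale: parameter recovery uses 10
simulated worms per characterized regime at 10 fps, 30 s, noise SD 0.02,
requiring frequency, elongation and speed within 5% and asymmetry within
0.03 for at least 9 of 10 worms; the image pipeline renders noise-free
stacks at maximum elongations 0.2, 0.45 and 0.6 and requires the
normalized trace within 0.03 of truth everywhere; knockdown recovery runs
200 seeds at each of four true expression levels with Ct noise 0.1 and
requires a mean error under five percentage points. Oracle equivalences
(moment ellipse vs. brute-force covariance, Fisher vs. enumeration,
t-test vs. quadrature of the t density) hold to numerical precision.

## Known limitations

Lengths are straight-line major axes: strongly and persistently bent
worms are flagged and excluded rather than measured along the midline.
One trace receives one label — there is no time-resolved gait-switching
segmentation, and desensitization time courses are out of scope. The
classifier is a fixed-rule nearest centroid, not a learned model, and
inherits the reference table's coverage (no D. japonica peristalsis
reference exists). Scoring utilities take labels as input; the package
does not score videos into S/R/N automatically.
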