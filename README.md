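# scrunchr

Quantification and classification of planarian oscillatory gaits from
single-worm recordings or body-length time series.

Freshwater planarians glide at constant body length, but noxious stimuli
trigger *scrunching* — a muscle-driven escape gait of large, asymmetric
body-length oscillations — while disrupted cilia beating produces
*peristalsis*, a smaller, near-symmetric oscillation. Telling these gaits
apart quantitatively is the core task in planarian behavioral
pharmacology and neurotoxicology screens. `scrunchr` is for researchers
who have such recordings (or length traces extracted from them) and want
the standard four-parameter gait readout, plus the surrounding assay
statistics, in a tested, scriptable form.

Over a window of consecutive oscillation cycles the package computes:

- frequency *f* (cycles s⁻¹): cycles over the trough-to-trough span;
- maximum elongation *A*: per-cycle (peak − trough)/peak, averaged;
- relative speed *v* = *f* × *A* (body lengths s⁻¹), an exact identity;
- asymmetry *a*: fraction of cycle time spent elongating,
  Σ(tᵖᵉᵃᵏ − tˢᵗᵃʳᵗ)/Σ(tᵉⁿᵈ − tˢᵗᵃʳᵗ); *a* > 0.5 is the scrunching
  hallmark.

A summary is labeled gliding / peristalsis / scrunching by a standardized
nearest-centroid rule, d(g) = √Σₖ((xₖ − μₖ,g)/σₖ,g)², against a packaged
per-species reference table, with Welch t-tests against the references as
a report.

The package covers the full chain:

- **Simulation** (`gait_params()`, `generate_length_trace()`,
  `render_worm_stack()`): synthetic traces and 8-bit image stacks for all
  three gaits with exact ground truth — the test bed standing in for raw
  videos.
- **Extraction** (`subtract_background()`, `segment_worm()`,
  `fit_ellipse_major_axis()`, `extract_length_trace()`,
  `normalize_by_gliding()`): temporal-median background, Otsu threshold,
  largest 8-connected component, moment-based equivalent-ellipse length
  (4·√λmax of the pixel covariance), normalization by the average gliding
  length.
- **Gait metrics** (`smooth_trace()`, `detect_cycles()`,
  `select_window()`, `summarize_gait()`, `count_scrunches()`,
  `batch_summarize()`, `quantify_trace()`).
- **Classification** (`reference_gaits()`, `classify_gait()`,
  `classify_batch()`, `t_test_vs_reference()`).
- **Behavior scoring** (`score_table()`, `aggregate_scores()`,
  `fisher_exact()`, `compare_windows()`, `latency_summary()`): 15-s
  interval scoring with reviewer averaging and exact window tests.
- **qPCR** (`primer_efficiency()`, `ddct_knockdown()`,
  `simulate_ct_records()`): standard-curve efficiency and ΔΔCt
  knockdown.

## Worked example

Simulate a D. japonica-style scrunching recording (0.72 Hz, A = 0.52,
a = 0.59, 2% length noise, 5 s of gliding before onset), normalize,
quantify and classify:

```r
library(scrunchr)

params <- gait_preset("scrunching_dj", noise_sd = 0.02, duration_s = 30,
                      gliding_lead_s = 5, seed = 11L)
sim     <- generate_length_trace(params)
trace   <- normalize_by_gliding(sim$trace, "auto")
summary <- quantify_trace(trace)
summary
#> <gait_summary 'sim_scrunching_seed11'> 18 cycles in [5.1, 30.0] s
#>   frequency 0.724 Hz, max elongation 0.519, speed 0.376 BL/s, asymmetry 0.579

classify_gait(summary, reference_gaits(), "D_japonica")
#> <gait_classification> scrunching (D_japonica)
#>   distances: scrunching 0.43, peristalsis 10.47
#>   flags: peristalsis_reference_from_S_mediterranea
```

The recovered parameters sit within a few percent of the generating
values (0.72 / 0.52 / 0.374 / 0.59); the summary is 0.43 reference SDs
from the scrunching centroid and more than 10 from peristalsis, so the
trace is labeled scrunching. The flag records that, lacking a
D. japonica peristalsis reference, the S. mediterranea entry supplied
that centroid.

qPCR knockdown from a synthetic Ct table with true relative expression
0.27 (2 biological × 3 technical replicates, Ct noise 0.1):

```r
kd <- ddct_knockdown(simulate_ct_records(0.27, ct_noise_sd = 0.1, seed = 11L),
                     "target", "housekeeping", "control", "rnai")
kd
#> <knockdown_result> relative expression 0.264 (knockdown 73.6%) over 2 bio replicate(s)
```

A thin command-line wrapper with the same functionality ships at
`inst/scripts/scrunch.R` (subcommands `simulate`, `extract`, `quantify`,
`classify`, `score`, `qpcr`, `run`; every run writes a provenance JSON
next to its outputs).

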