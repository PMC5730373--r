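---
title: "Quantifying pulsatile metabolic signaling in single cells with metapulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile metabolic signaling in single cells with metapulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapulse)
library(dplyr)
```

## Scope

metapulse analyses time-lapse recordings of fluorescent metabolic reporters in
single cells: an AMPK activity FRET reporter, a nuclear NADH redox sensor
(Peredox-type), an Akt kinase-translocation reporter and a geminin (GMNN)
cell-cycle marker. The package covers the full path from multichannel frames
and nuclear label masks to population statistics:

1. ratiometric index extraction from images (`derive_masks()`,
   `extract_channel_means()`, `compute_index()`, `normalize_ampk_offset()`);
2. pulse detection and scoring on index traces (`detect_pulses()`,
   `pulse_score()`, `summarize_pulses()`);
3. oscillation classification, period estimation and adaptation kinetics
   (`classify_oscillatory()`, `mean_period()`, `time_to_baseline()`,
   `adaptation_fraction()`);
4. dual-reporter phase shifts, phase locking and correlation analysis with a
   random-pairing null (`phase_shift()`, `is_phase_locked()`,
   `correlation_by_cell()`, `random_pairing_null()`);
5. group comparison with notched boxplots and Kruskal-Wallis tests
   (`boxplot_summary()`, `compare_pulse_scores()`,
   `cell_cycle_window_scores()`).

Because microscopy data of this kind is rarely shareable in raw form, the
package ships a seeded synthetic generator (`simulate_traces()`,
`render_synthetic_frames()`) whose presets encode the kinetic regimes reported
for glycolytic and mitochondrial perturbations of mammary epithelial cells.
Every analysis stage is tested against these synthetic populations.

## Reporter indices

With background-subtracted channel means per cell (nuclear mean over the
eroded nuclear mask, cytoplasmic mean over an annular "donut" mask):

- **NADH index** = nuclear T-Sapphire / nuclear YFP. Rises with the
  cytosolic NADH:NAD+ ratio, i.e. with glycolytic activity.
- **Akt index** = cytoplasmic RFP / nuclear RFP of the translocation
  reporter. Rises when Akt is active (reporter exported from the nucleus).
- **AMPK index** = inverted cytoplasmic CFP/YFP FRET ratio. The raw ratio
  falls with AMPK activity, so the index is `c - raw` with the offset `c`
  chosen per experiment so that the lowest index is approximately 0.

Indices are pure channel ratios, so they are invariant to any common scaling
of the camera gain (`affine safety`), and the imaging pipeline reproduces
programmed values on noiseless rendered fixtures to better than 1e-6
(round-trip tests).

Mask construction follows standard practice for nuclear-marker segmentation:
nuclei are eroded by 1 µm (at least one pixel) before computing nuclear means
so cytoplasmic pixels cannot leak in; the cytoplasmic donut spans from the
nuclear boundary dilated 2.5 µm out to 3.5 µm. An alternative inner rim at
the perimeter of the eroded nucleus is selectable
(`derive_masks(inner = "eroded_perimeter")`); neither variant is privileged,
as both are defensible readings of common practice. Donut pixels claimed by
two cells are assigned to the nearer nucleus — a deterministic,
orientation-independent tie-break. Cells whose nucleus is annihilated by
erosion are flagged and excluded.

The offset `c` for the AMPK index is the 99th percentile of the raw ratio per
experiment, computed with the inverse-ECDF quantile (R type 1): for small
experiments this is the literal maximum, so the lowest index is exactly 0,
while for hundreds of cells it is robust to stray single-pixel outliers,
matching the "approximately 0" convention. Adding a constant to all raw
values leaves the normalized index unchanged.

## Pulse detection

The detector mirrors the sliding-window two-cutoff design that is standard
for these reporters. The trace is first smoothed with a centered moving
average (span 3 samples by default; span 6 recommended for the noisier NADH
reporter). At every sample the local minimum `m` and maximum `M` within a
centered 40-min window define

- an upper cutoff `m + f_hi (M - m)` with `f_hi = 0.7`, and
- a lower cutoff `m + f_lo (M - m)` with `f_lo = 0.3`.

A pulse is an excursion that rises from below the lower cutoff to above the
upper cutoff and falls back below the lower cutoff; with the default
fractions an excursion must traverse at least 40% of the local range. The
peak is the excursion maximum (earliest sample on plateaus), the pulse
baseline is the trace minimum between the previous pulse's end (or the trace
start) and the peak, and the amplitude is peak minus baseline. Windows are
truncated near the trace ends. The detector is invariant to additive offsets
and, with the amplitude floor rescaled, equivariant under positive scaling;
a brute-force scan oracle reproduces it exactly in the test suite.

**Amplitude floor.** Range-relative cutoffs fire on pure noise wherever a
window contains no real signal, so detected pulses below `min_amp` are
suppressed. The default floor is 4 times a noise-scale estimate computed
from first differences of the *raw* trace: within blocks of 40 successive
differences the scale is `1.4826 median|diff| / sqrt(2)` (the MAD calibration
for a differenced Gaussian series), and the floor uses the minimum over
blocks. The blockwise minimum matters: on a trace that oscillates with an
18-min period sampled every 3 min, a *global* difference-based estimate is
dominated by the oscillation itself and would exceed the pulse amplitude,
silencing the detector on exactly the dynamics it exists to measure. The
quietest 2-hr block — typically the pre-treatment baseline — isolates the
measurement noise instead. The floor, cutoffs, window and span are all
exposed as parameters and config keys.

## Per-cell summaries

- **Pulse score** = sum of detected pulse amplitudes divided by the recording
  length, in index units per hour. Increases with both pulse frequency and
  amplitude; a flat trace scores zero.
- **Mean period** = average peak-to-peak spacing, defined only for cells
  with at least 5 pulses.
- **Oscillatory cell** = at least 5 successive pulses spaced at most 1 hr
  apart (`longest_pulse_run()` >= 5).
- **Time to baseline**: the baseline is the mean smoothed index over the
  hour before treatment; the response amplitude `A` is the post-treatment
  maximum within 2 hr minus baseline; the return time is the first time
  after that maximum at which the smoothed index drops to
  `baseline + 0.25 A`. Sustained plateaus never return (`NA`). The
  adaptation window is measured from the treatment time (not from the peak);
  this is configurable because the convention is genuinely ambiguous.
- **Adaptation fraction** = fraction of cells, among those alive through the
  window, returning within 2 hr.

## Phase and correlation analysis

For a dual-reporter cell, `phase_shift()` estimates the common period from
each channel's mean peak-to-peak spacing, detrends both channels by
subtracting a 2-hr moving average, cross-correlates them over lags within
1.5 periods, refines the best lag by parabolic interpolation, and folds
`|lag| / period` into [0, 0.5] cycles. Folding is deliberate:
cross-correlation of near-periodic signals cannot distinguish lead from lag
beyond half a cycle, so directional statements (which reporter drops first)
are a matter of construction or annotation, not estimation.

`is_phase_locked()` operationalizes 1:1 cycle correspondence: pulse counts
agreeing within 10%, nearest-peak lags concentrated around a stable offset
(at least 90% within half a period of the consensus), and a circular
standard deviation of the lags below 0.15 period. The lags are treated as
angles `2 pi lag / period` and dispersion is measured circularly because an
anti-phase pair — the biologically central case, with AMPK peaking opposite
Akt — has raw nearest-peak lags that flip sign between plus and minus half a
period; linear statistics would misclassify every anti-phase cell as
unlocked. All three thresholds are parameters.

`correlation_by_cell()` reduces each cell to one number: the Pearson
correlation of the two detrended channels ("time-dependent correlation" is
interpreted as whole-trace correlation after moving-average detrending;
windowed alternatives were rejected because they are less reproducible and
the target display shows one value per cell). The negative control pairs
channel A of one cell with channel B of a *different* cell
(`random_pairing_null()`, seeded, mismatched by construction): any
population-level structure (shared treatment response, imaging drift)
survives random pairing, so only cell-intrinsic covariation separates the
matched distribution from the null.

## Group statistics

`boxplot_summary()` uses linear-interpolation quartiles, whiskers at the
most extreme values within 1.5 IQR of the box, and median notches of
half-width `1.57 IQR / sqrt(n)` — two samples whose notches do not overlap
differ in median at roughly the 5% level. `compare_pulse_scores()` runs the
omnibus Kruskal-Wallis test (with tie correction) plus all pairwise
two-group Kruskal-Wallis tests, Bonferroni-corrected (raw p times the number
of pairs, capped at 1); the pairwise two-group Kruskal-Wallis is equivalent
to a Mann-Whitney test up to tie handling. `cell_cycle_window_scores()`
aligns cells at the G1-to-S transition — provided induction times, or the
first upward crossing of 20% of the per-cell GMNN maximum — scores pulses in
10-hr windows on either side, and compares the paired scores with a
two-sided Wilcoxon signed-rank test. The 20% threshold and the paired test
are this package's choices; the alignment concept itself does not prescribe
either.

## The synthetic generator

`simulate_traces()` draws per-cell parameters from seeded substreams keyed
by `(seed, cell index)` (populations are order-independent and bit-for-bit
reproducible) and renders each cell as

> baseline + raised-cosine pulse train + Gaussian measurement noise (sd
> 0.05) + Gaussian random-walk drift (sd 0.002 per sample),

sampled every 3 min over 24 h with treatment at 120 min, truncated at the
cell's death time. The raised-cosine kernel `0.5 (1 - cos 2 pi u)` is the
simplest smooth unimodal pulse with compact support; overlapping events sum.

Preset kinetics (all overridable):

| preset | kinetics |
|---|---|
| `ia_high` | 18-min period, all cells oscillatory, death 12-24 hr post-treatment |
| `ia_mid` | 24-min period (a 20-hr span holds 50 cycles), 97% oscillatory, oscillatory cells sustained >= 20 hr |
| `ia_low5` | 30-min period, 55% oscillatory |
| `ia_sub` | no oscillation; modest sustained elevation |
| `oligo_glc*` | initial pulse peaking 40 min post-treatment; adapting fraction 0.85 / 0.20 / 0.07 / 0 for 17 / 3.4 / 1.7 / 0 mM glucose; non-adapters plateau at 60% of the initial amplitude; recurring pulses every 150 min (jitter sd 25 min, duration 1-2.5 hr, first two synchronous, then per-cell phase diffusion of 10 min per cycle) |
| `cccp` | logistic rise (30-min half-time) to a sustained plateau, no pulses |
| `baseline_*` | Poisson pulses at 1.2 / 1.0 / 0.3 / 0.25 per 10 hr (no GF / EGF / insulin / EGF+insulin), each AMPK pulse mirrored by an inverted Akt dip |
| `dual_ia` | NADH, Akt, AMPK channels; Akt delayed 0.25 cycles after NADH, AMPK anti-phase to Akt; 95% of cells phase-locked, the rest get independent per-channel phase diffusion |
| `cellcycle_EGF` | GMNN induction uniform in 5-15 hr; AMPK pulse rate 2:1 before:after induction |

Where a preset parameter is not pinned by a published value, the simplest
choice consistent with the described behaviour was made once and kept:
per-cell periods are normal with a 5% coefficient of variation; event
amplitudes vary by 10% event-to-event; oscillation phase at onset is uniform
within a cycle. The oligomycin burst duration is reported variously as 1-3 hr
and 2-4 hr in different contexts; the preset uses uniform 1-2.5 hr and
exposes the range as a parameter rather than guessing which applies.

`render_synthetic_frames()` turns traces into multichannel image stacks plus
ground-truth nuclear label masks: uniform nuclear discs and cytoplasmic
annuli whose channel intensities are set so the index formulas recover the
programmed values exactly before optional camera noise. Segmentation and
tracking are deliberately out of scope — synthetic masks carry persistent
labels, and real data must arrive pre-tracked.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: cell movement, division and segmentation or
tracking errors; photobleaching and focus drift; non-Gaussian shot noise;
amplitude trends within a cell; interactions between cell cycle and
perturbation responses; and any mechanistic feedback between the three
reporters (waveforms are phase-constructed, not generated by a dynamical
model — mechanistic modeling of the glycolysis-AMPK-Akt network is a
non-goal).

## Numerical choices and degenerate inputs

- Moving averages shrink symmetrically at trace ends; an even smoothing span
  is reduced to the next odd width.
- Plateau peaks take the earliest sample; quantile conventions are type 7
  for boxplots and type 1 (inverse ECDF) for the AMPK offset.
- Traces shorter than the detection window yield an empty pulse list with a
  warning, not an error; constant traces yield no pulses, a zero pulse
  score and an undefined period.
- Zero-pixel mask regions produce missing channel means; non-positive
  denominators produce missing indices; missing values propagate rather
  than masquerading as zeros.
- `detect_pulses()` discards an excursion still above the lower cutoff when
  the trace ends: an unfinished rise is not a pulse.
- Test and acceptance problem sizes: populations of 100-200 cells at 3-min
  sampling over 22-26 hr, the scale at which the binomial spread of
  preset fractions (about 3 percentage points at n = 200) sits comfortably
  inside the documented tolerances.

## Known limitations

- The peak-to-peak period estimator is biased upward when individual cycles
  are missed; frequency-domain estimators are out of scope by design.
- The phase-locking criteria are a reproducible surrogate for what was
  historically a partly manual call; absolute locked fractions depend on the
  chosen thresholds, which is why all three are exposed.
- The AMPK offset makes indices comparable only within an experiment group;
  cross-experiment absolute comparisons require shared calibration
  conditions.
- Replicate structure is carried as a label only; no mixed-effects modeling
  across replicates is attempted.
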