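# metapulse

Pulse and oscillation analysis for single-cell metabolic reporter traces.

Live-cell biosensors make cellular energy management visible one cell at a
time: an AMPK activity FRET reporter, a nuclear NADH redox sensor reporting
glycolytic activity, and an Akt kinase-translocation reporter. Under
metabolic stress — glycolytic inhibition by iodoacetate (IA), mitochondrial
ATP-synthase inhibition by oligomycin, uncoupling by CCCP — individual cells
show dynamics that population averages erase: fast periodic AMPK/NADH/Akt
oscillations (periods of tens of minutes), slower recurring pulses with
glucose-dependent adaptation, sustained plateaus, and sparse spontaneous
fluctuations modulated by growth factors and cell-cycle phase. metapulse is
for researchers who need to quantify those kinetics reproducibly: it turns
multichannel frames or long-format trace tables into per-cell pulse
statistics, oscillation calls, phase relationships and group-level tests.

## What it computes

**Reporter indices** from background-subtracted channel means over eroded
nuclear masks and cytoplasmic "donut" masks:
NADH index = nuclear T-Sapphire / YFP; Akt index = cytoplasmic / nuclear
RFP; AMPK index = the inverted cytoplasmic CFP/YFP FRET ratio, offset so the
experiment minimum is ~0.

**Pulse detection** with a sliding-window two-cutoff detector: within a
centered 40-min window with local range [m, M], a pulse must rise from below
m + 0.3 (M − m) to above m + 0.7 (M − m) and fall back. Per cell it reports
the **pulse score** (sum of pulse amplitudes per hour of recording), the
**mean period** (average peak-to-peak spacing, cells with ≥ 5 pulses), the
**oscillatory** classification (≥ 5 successive pulses ≤ 1 hr apart),
**time to baseline** after a perturbation, and the population **adaptation
fraction**.

**Phase structure** of dual-reporter cells: cross-correlation phase shifts
folded into [0, 0.5] cycles, 1:1 phase-locking calls with circular lag
statistics, and per-cell correlations against a seeded random-pairing null.

**Group statistics** in the field's reporting conventions: notched boxplot
summaries (notch half-width 1.57·IQR/√n) and Kruskal-Wallis tests with
Bonferroni-corrected pairwise comparisons; paired pre/post pulse scores
around the GMNN (geminin) G1-to-S transition.

A seeded synthetic generator (`simulate_traces()`, 15 presets) reproduces
the statistical structure of these experiments — periods, prevalences,
adaptation fractions, phase lags, death windows — so the whole pipeline is
testable without any imaging data, and `render_synthetic_frames()` builds
image + mask fixtures whose programmed indices the imaging stack recovers
exactly.

## Worked example

```r
library(metapulse)
library(dplyr)

tr <- simulate_traces("ia_high", n_cells = 50, seed = 1)   # 20 uM IA regime
s  <- summarize_pulses(tr)
head(select(s, cell_id, n_pulses, pulse_score, mean_period_min,
            longest_run, oscillatory), 4)
#>   cell_id   n_pulses pulse_score mean_period_min longest_run oscillatory
#> 1 cell_0001       52        1.89            16.9          52 TRUE
#> 2 cell_0002       72        1.99            18.2          72 TRUE
#> 3 cell_0003       70        1.97            18.9          70 TRUE
#> 4 cell_0004       53        1.92            17.5          53 TRUE

mean(s$oscillatory)                              # 1   (all cells oscillate)
mean(s$mean_period_min[s$oscillatory])           # 17.9 min mean period
```

Each row is one cell: `cell_0002` carried 72 detected pulses with an 18.2-min
average spacing and a pulse score of ~2 index units per hour — a fast,
sustained oscillator, as expected at a high IA dose. Comparing conditions:

```r
sc <- bind_rows(
  summarize_pulses(simulate_traces("oligo_glc17", 40, seed = 2)),
  summarize_pulses(simulate_traces("cccp",        40, seed = 3)))
cmp <- compare_pulse_scores(sc)
glance(cmp)
#>   n_groups H_statistic df  p_value
#> 1        2        59.3  1 1.38e-14
tidy(cmp)
#>   group1 group2      statistic    p_raw    p_adj significant
#> 1 cccp   oligo_glc17      59.3 1.38e-14 1.38e-14 TRUE
```

Pulsatile oligomycin responses score far above the sustained CCCP plateau,
and `autoplot(cmp)` draws the corresponding notched boxplots.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/scripts/metapulse-cli.R simulate --preset ia_high --n-cells 50 --seed 1 --out sim
Rscript inst/scripts/metapulse-cli.R pulses --traces sim/traces.csv --out out
```

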