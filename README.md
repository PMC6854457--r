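# opmtheta

Source localisation of deep theta power changes from wearable
optically-pumped magnetometer (OPM) arrays — an end-to-end, fully
synthetic test bed for the analysis chain used in OPM studies of
hippocampal function.

## What it does, and for whom

OPMs are cryogen-free magnetic sensors worn on the scalp. They sit much
closer to the brain than cryogenic MEG sensors, but they are
magnetometers, so environmental interference is the central obstacle —
especially for weak, deep sources such as hippocampal theta (4–8 Hz).
`opmtheta` is for methodologists who want to test, under fully known
ground truth, whether the standard OPM analysis chain recovers a deep
two-condition theta effect:

1. **Simulation** — a conducting-sphere head, a 21-channel scalp array in
   a virtual scanner-cast plus a 4-channel reference array behind the
   head, a band-limited theta dipole at hippocampal depth whose power
   *decreases* during "scene imagery" trials relative to "counting"
   trials (amplitude ratio 0.7), structured environmental interference
   (uniform field + gradient, coherent across arrays) and white sensor
   noise, for three virtual participants with jittered geometry and
   realistic trial accounting (35/61/45 analysable trials per condition).
2. **Preprocessing** — baseline correction, trial-wise synthetic
   gradiometry (OLS regression of scalp channels on the references), and
   a zero-phase 5th-order Butterworth band-pass at 4–8 Hz.
3. **Beamforming** — a scalar unit-gain LCMV beamformer on a 3 mm source
   grid: pooled two-condition covariance (whole 0–3 s epochs), diagonal
   loading `λ = 0.05`, per-voxel maximum-power orientation
   (`u = argmin u'L'C⁻¹Lu`), weights `w = C⁻¹l / (l'C⁻¹l)`, and per-trial
   band power `w'Cₜw`.
4. **Statistics** — per voxel, on log trial powers: the signed two-sample
   t (scene − counting; negative = theta decrease) and the two-group
   ANOVA `F = t²`, df `(1, n₁+n₂−2)`.
5. **Group inference** — 9 mm Gaussian smoothing, p conversion, the
   maximum-p conjunction across participants (rejects "no participant
   shows an effect"), Benjamini–Hochberg FDR at `q < 0.005`, 6-connected
   cluster/peak reporting.
6. **Stability** — per participant, trials are resampled with replacement
   and the beamformer image recomputed (100×); repeatedly drawing one
   image per participant and rerunning the whole conjunction (500×)
   yields a map of the percentage of conjunctions in which each voxel was
   significant.

The methods vignette (`vignettes/opmtheta-methods.Rmd`) documents the
models, defaults and design choices in detail.

## A worked example

```r
library(opmtheta)

study <- run_study(seed = 42)
glance(study)
#> # A tibble: 1 × 8
#>   n_participants n_analysed n_sig_voxels n_clusters peak_stat
#>            <int> <chr>             <dbl>      <int>     <dbl>
#> 1              3 35/61/45            783          2      87.6
#> # ℹ 3 more variables: true_voxel_significant <lgl>, all_decrease <lgl>,
#> #   min_decrease_pct <dbl>

tidy(study)          # cluster table: size, peak (mm), peak statistic
study_recovery(study)$recovered
#> [1] TRUE

autoplot(study$participants[[2]]$F)   # axial slices of the F map
```

`run_study(seed = 42)` simulates the full three-participant study and
analyses it. In this run the conjunction mask holds 783 significant
voxels (q < 0.005) in 2 clusters; the 652-voxel cluster containing the
planted source peaks at (34.5, 10.5, −13.5) mm — 5 mm from the true
location (29.3, 9.8, −13.7) mm — with minimum-F statistic 87.6, every
significant voxel shows a theta *decrease* in every participant
(`min_decrease_pct = 100`), and the true source voxel itself is
significant — the study "recovers" the planted effect. Per-participant F
values at the source fall in the tens, the scale reported for real
hippocampal theta contrasts.

A command-line driver mirrors the stages
(`simulate`/`preprocess`/`localize`/`conjoin`/`bootstrap`/`report`/`run-all`):

```sh
Rscript inst/cli/opmtheta.R run-all --config config.json --out out/
```

writing NIfTI maps, TSV cluster reports and a structured run log.

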