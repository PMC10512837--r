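# cardiomotion

Quantitative-ultrasound estimation of segmental and transmural left-ventricle
(LV) myocardial motion from raw radio-frequency (RF) frame sequences — the
measurement chain used in myocardial elastography to detect infarct-induced
wall-motion deficits in small-animal models, for researchers working with
high-frequency cardiac RF data (or validating trackers without any).

## What it computes

**Displacement tracking.** Between successive RF frames `F^pre` and
`F^post`, a matching block (4λ × 7 pitches; λ = fs/f0 samples) centered at
each node of an overlap-defined grid is compared with all candidate blocks
within a search margin; the displacement is the lag maximizing the
zero-normalized cross-correlation, refined to sub-sample precision by
parabolic interpolation. Incremental axial displacements are accumulated at
fixed pixel coordinates into the cumulative axial displacement map
(CD_A, mm; positive = motion away from the probe).

**Quality metrics and overlap optimization.** Over the myocardial ROI:
`SNR = mean(D_ROI)/sd(D_ROI)`, and the displacement-compensated
cross-correlation coefficient

    DCCCC = corr( F^pre, F^postC )  over the ROI,

where `F^postC` is the post-frame warped back by the estimated field
(`F^postC(x − D_A, y − D_L) = F^post(x, y)`). DCCCC needs no ground truth;
`overlap_sweep()` scores a set of window overlaps (10–99.9 %) and
`select_optimal_overlap()` picks the start of the DCCCC plateau after
median-filtering single-point spikes.

**Segmentation.** From manually picked endocardial/epicardial key points:
spline border interpolation, basal-middle/apical landmark detection,
equal-arc-length division into six segments (A-SEP, M-ANT-SEP, B-ANT-SEP,
A-LAT, M-INF-LAT, B-INF-LAT), and stratification of each segment into 3 or
10 transmural layers via the coordinate `t = d_epi/(d_epi + d_endo)`.

**Transmural motion index.** Per segment, the mean CD_A of the 10 layers is
fitted against the layer index n = 1…10; the TMI is the fitted slope
(mm/layer) — a scalar, angle-independent summary of the
epicardium-to-endocardium motion gradient that systolic contraction
produces and transmural infarction flattens.

**Group statistics.** Exact Mann–Whitney U tests (full enumeration for the
small cohorts typical of animal studies, ties counted ½) compare segmental
CD_A and TMI between groups.

**Synthetic RF simulator.** Point-scatterer speckle with a band-limited PSF
(21 MHz-class), analytic motion models (uniform, depth-gradient,
transmural-gradient) applied at the scatterer level, and an LV-like
half-annulus phantom with border key points — so the whole chain is
validated end-to-end against exact ground truth.

## Worked example

Simulate a rat-scale LV phantom whose wall carries an imposed transmural
gradient of 0.02 mm/layer (epicardium 0.1 mm → endocardium 0.3 mm total
systolic displacement), then run the full chain:

```r
library(cardiomotion)
cfg <- default_run_config(seed = 11)
cfg$motion$epi_total_mm  <- 0.1
cfg$motion$endo_total_mm <- 0.3       # 0.1 + 10 layers x 0.02 mm/layer
report <- run_pipeline(cfg, "run_g02")
print(report)
#> <run_report> selected overlap: 30 %
#>    segment mean_cda_mm tmi_mm_per_layer
#>  B-ANT-SEP   0.1951427       0.01841011
#>  M-ANT-SEP   0.1946491       0.01876429
#>      A-SEP   0.1957138       0.01980667
#>      A-LAT   0.1926728       0.01965720
#>  M-INF-LAT   0.1944788       0.01883940
#>  B-INF-LAT   0.1955743       0.01828800
```

Every segment's mean CD_A sits near the wall average of the imposed field
(≈0.2 mm) and the recovered TMI is within 9 % of the imposed 0.02 mm/layer.
On this noiseless smooth phantom the DCCCC plateau starts at the coarsest
grid, so the selector picks 30 %; on pairs with sharp spatial motion
structure the finer grids win (see the overlap-sweep tests).
`render_figures(report)` writes the CD_A heat map (red = downward) and the
six-panel layer-profile plot with the fitted TMI lines.

A thin command-line front end wraps the same functions:

```sh
inst/cli/cardiomotion simulate --motion transmural --frames 9 --seed 1 --out seq.rds
inst/cli/cardiomotion run --seed 1 --out-dir results/ --figures
```

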