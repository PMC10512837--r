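---
title: "Methods: segmental and transmural myocardial motion estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmental and transmural myocardial motion estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomotion)
```

## Scope and model

`cardiomotion` estimates left-ventricle (LV) wall motion from sequences of
raw radio-frequency (RF) ultrasound frames, the way myocardial
elastography does it: speckle — the granular interference pattern produced
by sub-resolution scatterers — is quasi-stationary under small tissue
motion, so the displacement of a tissue patch between two successive
frames can be read off as the lag that maximizes the zero-normalized
cross-correlation (ZNCC) between a matching block in the pre-frame and
candidate blocks in the post-frame.

The chain is: block-matching displacement per successive frame pair,
Eulerian accumulation into a cumulative axial displacement map (CDA, in
mm, positive = away from the probe), semiautomatic six-segment and
layer-specific segmentation of the myocardium from manually picked border
key points, per-segment/per-layer CDA summaries, and the transmural
motion index (TMI) — the slope of the straight-line fit of the ten layer
means against layer index — plus exact Mann–Whitney comparisons between
cohorts.

Conventions everywhere: matrices are (axial sample, beam line); axial
depth and positive displacement increase away from the probe; coordinates
are mm; one RF sample spans `c/(2 fs)` of depth.

## Displacement estimation

The matching block spans 4 wavelengths axially (`fs/f0` samples per
wavelength; 16 samples at the default `fs = 4 f0`) by 7 beam lines — the
2-D block size reported to behave well under mixed deformation. The
overlap between successive matching windows sets the node-grid stride
via `shift = max(1, round(block × (1 − overlap/100)))`, so 99.9 % overlap
strides one RF sample. Search margins default to ±8 samples axially and
±2 lines laterally and must exceed the per-frame motion. Correlation is
computed on raw RF (not the envelope), which is what gives the method its
sub-sample sensitivity.

Numerical choices that matter:

* **Tie-breaking.** Equal correlation maxima go to the smallest lag
  magnitude, then the smallest axial, then lateral lag — deterministic by
  construction.
* **Sub-sample refinement.** A 1-D parabola through the peak and its two
  neighbours per axis; the offset `(s[-1] − s[+1]) / (2(s[-1] − 2 s[0] +
  s[+1]))` lies in (−0.5, 0.5); equal neighbours give 0; a peak on the
  search border is left unrefined and flagged. A peak with ZNCC exactly 1
  (a perfect match, as in noiseless integer-shift data) is never refined:
  the parabola would only add a spurious fraction from asymmetric side
  lobes.
* **Degenerate blocks.** A zero-variance block or candidate has no
  defined correlation; such lags score 0 and the node is flagged rather
  than dropped silently.
* **Borders.** Nodes whose search region would leave the frame are
  dropped, not zero-padded — padding biases edge estimates.
* **Accumulation.** Incremental fields are bilinearly interpolated from
  the node grid to the pixel grid (edge values extended), converted to mm,
  and summed at fixed pixel coordinates. This Eulerian accumulation is
  exact for uniform motion and first-order accurate otherwise; for the
  sub-wavelength per-frame motions simulated here the material-tracking
  correction is far below the tracker noise floor, so a Lagrangian mode
  is deliberately not provided.

The fast C++ matcher is contractually identical to a naive triple-loop
NCC matcher; the test suite asserts node-for-node equality against an
independent R implementation on random frame pairs.

## Displacement quality and overlap selection

Two complementary quality measures are computed over the myocardial
region of interest (ROI):

* **SNR** = mean(CDA)/sd(CDA) over the ROI, with the sample (N−1)
  standard deviation. The *signed* mean is used exactly as the
  definition prints it, so a zero-mean field has SNR 0 and negating the
  map negates the SNR; a perfectly uniform field returns `Inf` (flagged,
  not an error — it arises in noise-free synthetic data).
* **DCCCC**, the displacement-compensated cross-correlation coefficient:
  the post-frame is warped back by the estimated field and correlated
  with the pre-frame over the ROI. Compensation is realized by inverse
  mapping — output (x, y) samples the post-frame at (x + D_A, y + D_L)
  with bilinear interpolation — because forward scattering of samples
  leaves holes. Pixels whose lookup leaves the frame are excluded. The
  higher the DCCCC, the more accurate the estimate; it needs no ground
  truth, which is what makes it usable in vivo where RMSE is not.

`overlap_sweep()` scores a frame pair at each requested overlap and
`select_optimal_overlap()` formalizes the published selection logic as an
explicit rule: median-filter the DCCCC curve (width 3, endpoints kept) to
suppress single-point spikes — the kind of isolated jump at one overlap
value that should be treated as an outlier rather than an optimum — then
return the smallest overlap whose filtered DCCCC reaches (1 − 0.005) of
the filtered maximum. The plateau tolerance of 0.005 encodes the
accuracy-versus-computational-cost compromise: within half a percent of
the best attainable DCCCC, the cheapest grid wins.

## Segmentation

From manually picked endocardial and epicardial key points (base → apex →
base):

1. **Interpolation.** Chord-length-parameterized natural cubic splines
   through the key points, resampled at `n_points` equal arc-length
   positions (endpoints preserved exactly).
2. **Landmarks.** The basal middle point (BMp) is the midpoint of the two
   basal endpoints; the apical point is the border point farthest from
   the BMp. Exact distance ties (a perfect semicircle) are broken by the
   smallest index and flagged — real LV borders are elongated, so the tie
   case is degenerate by construction.
3. **Division.** Each border splits at its apex into two sub-borders;
   each sub-border into three sections of equal arc length, cut points
   linearly interpolated.
4. **Segments.** Each of the six positions closes a contour from the
   endocardial section, the reversed epicardial section and two
   cross-wall cuts; pixel centers are assigned by point-in-polygon in a
   fixed order, so boundary pixels are deterministic and the six masks
   partition the myocardium pixel-exactly. The default name mapping
   (B-ANT-SEP, M-ANT-SEP, A-SEP on the anterior sub-border; A-LAT,
   M-INF-LAT, B-INF-LAT on the posterior one) is configurable because the
   image side of each wall depends on probe orientation.
5. **Layers.** Every myocardial pixel gets a transmural coordinate
   `t = d_epi/(d_epi + d_endo)` from its distances to the two border
   polylines (t = 0 at the epicardium) and layer `floor(t · n) + 1`,
   n ∈ {3, 10}. "Equal width" is thereby realized as a distance ratio —
   exact for concentric circles (boundaries at radii 12 and 14 mm for a
   10/16 mm annulus), well-behaved for ellipses, and meaningful near the
   open base where parallel-curve constructions are not. Layers are
   ordered epicardium → endocardium and partition each segment exactly.

## Transmural motion index

The mean CDA of each of the 10 layers gives the layer profile; the TMI is
the OLS slope of the profile against the dimensionless layer index
1…10, in mm per layer. With ten points a "first-order polynomial" can
only be a fitted line, so the first derivative is the fitted slope; the
intercept is kept for diagnostics. The abscissa is the layer index, not
physical depth, which keeps TMI comparable across walls of different
thickness. Signed CDA is the default (downward and upward motion carry
physiological sign); an absolute-value mode exists and is labelled as
such in its result.

## Group statistics

`mann_whitney_u()` counts `U = Σ[a > b] + ½ Σ[a == b]` over all cross
pairs. For combined samples up to 16 — which covers the n = 7 per group
regime this method targets, where the normal approximation is poor — the
p-value is exact: all `choose(n_a + n_b, n_a)` group labelings of the
pooled values are enumerated and the two-sided p is the fraction of
labelings at least as far from `n_a n_b / 2` as the observed U. Larger
samples use the tie-corrected normal approximation with continuity
correction. No multiplicity correction is applied by default (a
Benjamini–Hochberg option exists); two-sided is the default alternative
since both motion reductions and recoveries are of interest.

## The synthetic-data generator

In vivo RF data for this application are not publicly deposited, so the
package ships a simulator that makes every stage testable against exact
ground truth. It emulates:

* **Speckle** from random point scatterers (Poisson count, uniform
  positions, Gaussian reflectivities) convolved with a separable
  Gaussian-envelope cosine PSF at a 21 MHz-class center frequency,
  sampled at `fs = 4 f0`, 0.09 mm pitch, c = 1540 m/s.
* **Motion** as analytic displacement fields — uniform, linear-in-depth,
  or a transmural gradient rising from the epicardium to the endocardium
  (the dominant feature of healthy systolic wall motion) — applied by
  moving the scatterers themselves, never by resampling frames, so
  sub-sample motion is exact at the scatterer level. The surrounding
  tissue follows the continuous clamped field, as real perivascular
  tissue does.
* **Geometry** as a half-elliptical annulus open at the base with the
  apex at maximal depth, the long-axis-view topology, with ordered border
  key points as the segmentation input.

Parameter choices, made once on physical grounds:

* **Pulse envelope sigma = 0.5/f0** (≈75 % two-way fractional
  bandwidth, a short broadband pulse of the kind modern high-frequency
  arrays produce). This is the one place the simulator deliberately
  idealizes: with long narrowband pulses, raw-RF correlation surfaces
  carry strong side lobes one carrier period away and any RF tracker
  phase-wraps at a measurable rate regardless of implementation. A short
  pulse keeps the matching problem well-posed, which is the simulator's
  job as a validation substrate; quantifying wrap rates versus bandwidth
  is a property of the physics, not of this implementation.
* **Scatterer density 200/mm²**, toward the ≥10-per-resolution-cell
  rule of thumb for developed speckle, bounded by render cost.
* **Per-frame displacements ≤ ~7 RF samples**, inside the ±8-sample
  search margin, as the defaults of the pipeline configuration enforce.
* **Rat-scale phantom** (wall ≈ 2 mm, cavity semi-axes 3.5 × 4.5 mm) in
  the default pipeline; the end-to-end experiments run 9 frames
  (8 tracked pairs), and the segmentation geometry checks use an
  r = 10 / R = 16 mm annulus at 0.05 mm pixels.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: attenuation and
depth-dependent gain, nonlinear propagation, reverberation and off-axis
clutter, electronic noise, cardiac-cycle deformation beyond the imposed
fields (no torsion, no lateral contraction in the default models), probe
or respiratory motion, and ECG gating (synthetic sequences carry an
explicit frame range instead). Results on synthetic data bound the
method's best case; in vivo performance will be worse in proportion to
these effects.

## Design choices where the design was open

* **Overlap semantics**: overlap defines the matching-grid stride (the
  window-shift definition), not merely an output subsampling of an
  always-dense field; the two coincide at 99.9 %.
* **SNR pairing**: the sweep scores the single-pair displacement map, the
  same pair DCCCC compensates, so both metrics describe one estimate;
  the cumulative-map SNR is available by calling `cda_snr()` on any
  `cda_map`.
* **Exact-match peaks are not refined** (see above); this also makes
  integer-shift recovery exact rather than merely close.
* **Persistence**: frame sequences, fields and masks are stored as RDS
  containers; key points and result tables as CSV; configuration and
  summaries as JSON. Tables are written deterministically, so one seed
  gives bit-identical outputs.
* **Problem sizes** in the tests and the acceptance script (frames of
  roughly 900 × 145 samples, 9-frame sequences, 2000-replicate null
  simulations) are the package's chosen validation scale: large enough
  that tracking, stratification and the statistics operate in their
  intended regime, small enough to re-run routinely.

## Known limitations

* Lateral displacement is estimated but carries no accuracy claim: the
  lateral resolution cell spans several pitches and the beam has no
  lateral phase to exploit. Axial motion is the quantitative output.
* Eulerian accumulation drifts for large cumulative motion (a material
  point crosses many pixels); the intended regime is sub-wavelength
  per-frame systolic motion.
* The transmural coordinate degrades gracefully but is not "equal width"
  in a differential-geometric sense for strongly eccentric walls.
* Strain (the spatial derivative of displacement) and fiber-angle
  corrections are out of scope.
* The apex detector requires an elongated border; on an exact semicircle
  it returns the first point with a tie flag rather than guessing.

## A worked example

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 11)
cfg$motion$epi_total_mm <- 0.1
cfg$motion$endo_total_mm <- 0.3   # 0.02 mm/layer imposed gradient
report <- run_pipeline(cfg, "run_g02")
report$segment_summary[, c("segment", "mean_cda_mm", "tmi_mm_per_layer")]
render_figures(report)
```

The recovered `tmi_mm_per_layer` sits within a few percent of the imposed
0.02 mm/layer in every segment; `scripts/acceptance.R` recomputes this
recovery for gradients of 0.01, 0.02 and 0.04 mm/layer along with the
tracker's shift-recovery error, the DCCCC discrimination rate, the
overlap selection, and the Mann–Whitney behaviour.
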