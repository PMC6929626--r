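---
title: "Quantifying beta-cell mass and function from simultaneous PET/ME-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-cell mass and function from simultaneous PET/ME-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memripet)
```

## The measurement problem

Two quantities decide the fate of the endocrine pancreas in diabetes and in
insulinoma models: how much beta-cell tissue there is (mass) and how well it
responds to glucose (function). `memripet` implements a joint in vivo readout
of both:

* **Mass** — a GLP-1 receptor tracer (a copper-64-labelled exendin-4
  derivative) binds beta cells specifically; its decay-corrected
  concentration, in percent injected dose per millilitre (%ID/mL), is a mass
  proxy measured by PET.
* **Function** — manganese is a calcium analogue: Mn²⁺ enters beta cells
  through voltage-dependent calcium channels that open during
  glucose-stimulated insulin secretion. Mn²⁺ shortens the longitudinal
  relaxation time T1, so its tissue concentration is readable from
  quantitative T1 maps (manganese-enhanced MRI, ME-MRI).

The central scientific signal this pipeline is built to resolve is a *time
reversal*: shortly after injection (1 h) manganese sits mainly in the
well-perfused exocrine pancreas, so the endocrine-specific PET signal and the
MR enhancement *anti*-correlate; a day later (24 h) the exocrine signal has
washed out while islets and insulinomas retain manganese, and the two
modalities correlate *positively*. Region-wise and voxel-wise Pearson
correlations of `log10(%ID/mL)` against `log10(R1)` carry that signature.

## Models and procedures

### T1 from variable flip angles

MR magnitude images are acquired with an RF-spoiled gradient-echo sequence
(TR/TE = 10/1.9 ms) at either two (4°, 22°) or three (4°, 14°, 27°) flip
angles. The steady-state spoiled-GRE signal is

$$S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

Ideal spoiling is assumed and the TE-dependent T2* decay is absorbed into
$M_0$ (TE is much shorter than tissue T2*, and the protocol provides no T2*
estimate). Plotting $S/\sin\alpha$ against $S/\tan\alpha$ linearizes the
model with slope $E_1$:

* **Two angles** determine $E_1$ exactly (closed form). This is what
  `fit_t1_vfa()` uses for two-angle stacks — no iteration, no tolerance.
* **Three angles** are fit by least squares on the linearized form, then
  polished by a one-dimensional golden-section minimization of the true
  nonlinear residual in $E_1$ (60 iterations on the bracket
  $E_1^{lin} \pm 0.2$ clipped to $(0,1)$; $M_0$ is profiled out in closed
  form). The linearized estimator is biased under noise because the
  regressor contains the noisy signal; the polish removes that bias down to
  numerical precision of the least-squares optimum.

Voxels with non-physical slopes ($E_1 \le 0$ or $\ge 1$, e.g. pure-noise or
all-zero voxels) are flagged invalid rather than clamped; validity masks
propagate through every later stage.

### R1 filtering and manganese estimation

$R_1 = 1/T_1$; only voxels with $R_1$ in the physiological window
[0.4, 10] s⁻¹ are quantified. The window is treated as a *closed* interval:
the protocol wording does not state openness, and including the boundary is
the choice that never discards a voxel for a representability accident.
Excluded-voxel counts are reported.

Manganese concentration follows from the relaxivity relation
$[\mathrm{Mn}] = \Delta R_1 / r_1 = (R_1^{post} - R_1^{pre})/r_1$, with
$r_1$ calibrated by ordinary least squares on a phantom dilution series
(`calibrate_relaxivity()`; the intercept is fitted, not forced through the
diluent rate, so an imperfect diluent blank cannot bias the slope). Two
modes exist:

* **voxelwise** — the default, on jointly valid pre/post voxels. Negative
  estimates are *preserved* and counted (they diagnose registration and
  noise problems); clipping is an explicit opt-in.
* **region_mean_24h** — at 24 h the animal is repositioned, so pre and post
  VOIs are drawn independently and the index is the difference of the VOI
  means divided by $r_1$.

### PET quantification

Reconstructed activity (kBq/mL) is referenced back to injection time with
the physical decay of copper-64, $t_{1/2} = 12.7$ h, and normalized:
$\%ID/mL = 100 \cdot A \cdot 2^{t/12.7} / D$. Whether the original
analysis corrected to injection or frame time is not stated; correction to
injection time is the default and can be disabled
(`decay_to_injection = FALSE`). Static frames are abstracted to a single
`frame_time_h`; no body-weight normalization (%ID/g, SUV) is computed.

### Multimodal correlation

PET and MR grids never match exactly after co-registration, so VOI voxels
are averaged over non-overlapping blocks of 1–8 voxels per dimension before
voxel-wise correlation (`downsample_blocks()`). Blocks are anchored at the
VOI bounding-box corner — an arbitrary but reproducible phase choice — and
blocks less than half in-mask are dropped (configurable). Registration
itself is out of scope: transforms are inputs (`resample_to_reference()`
applies rigid/affine transforms with trilinear interpolation; identity for
phantom data).

Correlations use `log10` transforms; pairs with a non-positive member are
excluded *pairwise* and counted, which is conservative and auditable where
the original procedure is silent. Group contrasts use the Welch two-sample
t test (unequal variances, Satterthwaite df) and the Wilcoxon rank-sum test
(exact p for combined n ≤ 10 without ties, normal approximation with
continuity correction otherwise). Region summaries support both mean and
median; the median is the default for correlation-figure-style analyses
(the source material mixes the two), and the choice is always recorded in
the output metadata.

### Ex vivo validation chain

Autoradiography sections (50 × 50 µm²) are quantified by spot detection:
the background is the image median, spots are 8-connected components above
`median × threshold_k` (default 2.0 — the detection procedure of the
original ImageJ analysis is unspecified, so both the factor and the minimum
size are exposed), and the islet diameter is the equivalent-circle diameter
$2\sqrt{A/\pi}$. Islet-to-exocrine ratios and the signal-versus-diameter
regression are computed per section; because the stated direction of that
regression is ambiguous, both orientations are supported and tagged.

Elemental maps (60 µm spot) are merged with an additive 8-bit colour model —
⁴⁴Ca red, ⁶⁴Zn green, ⁵⁵Mn blue, each channel independently normalized by
`floor(255 (v - min)/(max - min))`. A constant (blank) channel maps to all
zeros instead of erroring so control channels never break merging.
Endocrine enrichment is quantified as `mean(islet px)/mean(exocrine px)`.

### Secretion assay

The enhancement index is the ratio of mean triplicate insulin content at
15 mM glucose over 3 mM; the other concentrations of the series (6, 8, 10,
30 mM) are carried for dose-response curves only. Whether "enhancement"
divides condition means or averages per-replicate ratios is unstated; the
mean-of-replicates ratio is implemented (median by flag), making the index
invariant to replicate order and measurement units.

## The digital phantom

`phantom_spec()` parameterizes a voxelized mouse pancreas: an ellipsoidal
exocrine compartment, spherical islets placed by rejection sampling (the
simplest scheme that guarantees the islet count equals the connected
component count), and an optional insulinoma. Defaults are the study
conditions, fixed once:

* **Geometry** — 64³ voxels at 0.27 mm (the isotropic protocol
  resolution); 40 islets with equivalent diameters ~ N(500, 150²) µm
  truncated at one voxel. Pancreas and islet volume fractions are not
  reported by the source study, so these are realistic mouse values exposed
  in the config, not asserted facts.
* **Relaxation** — pre-contrast T1 of 1.4 s in pancreas (consistent with a
  whole-pancreas `log10(R1)×10 ≈ −1.5` at 7 T), 1.5 s in insulinoma, 0.8 s
  background.
* **Manganese** — 1 h: exocrine 0.22 mM > islet/insulinoma 0.11 mM
  (insulinoma about half the healthy-pancreas concentration); 24 h:
  islet 0.10 / insulinoma 0.09 mM > exocrine 0.04 mM. These reproduce the
  reported exocrine-early / islet-late pattern with the whole-pancreas
  ΔR1 magnitudes implied by the group means, via a default relaxivity of
  6.0 s⁻¹mM⁻¹ (a typical Mn(II) chelate value at 7 T; the study's own
  fitted value is not printed, so in real analyses the calibration is a
  required input).
* **PET** — endocrine-specific uptake (islet 12, insulinoma 16, exocrine
  4 %ID/mL at 1 h) with whole-pancreas means near the published group
  level; 3 MBq injected dose; activity decayed to acquisition time.
* **Noise** — additive Gaussian by default (the magnitude SNR of this
  regime is high enough that the Rician correction is negligible; a Rician
  option exists for realism studies). Time points are discrete labels
  (`pre`, `1h`, `24h`); no continuous kinetics — the glucose bolus given
  5 min post injection is folded into the per-timepoint Mn table because no
  kinetic model of it is reported.

Every simulator derives a stage-specific sub-seed from `rng_seed`, making
all outputs bit-identical for a fixed spec.

What the phantom does **not** emulate: partial-volume averaging at islet
boundaries beyond voxelization, B1 inhomogeneity, respiratory motion,
registration error between modalities, PET reconstruction artefacts
(resolution, scatter, positron range) and k-space effects. Passing the
pipeline's recovery and sign-pattern checks therefore demonstrates that the
quantification chain is *correct*, not that it is robust to every
real-world confound; the filter thresholds and validity machinery are where
such confounds surface in practice.

## Verification problem sizes

The test suite exercises: T1 inversion on 100 ground-truth values in
[0.1, 3] s for both protocols (noise-free, ≤ 10⁻⁶ relative); agreement of
the three-angle fit with an exhaustive 1-ms-step grid search on 1,000
voxels at 1% signal noise; end-to-end [Mn] recovery on the full 64³
phantom, noise-free and at 1% noise; the early/late correlation sign flip
on 50 seeded 64³ replicates; recovery of 20 planted autoradiography discs
of 4–20 px diameter; and 100-sample comparisons of the statistical layer
against closed-form and enumeration oracles. `scripts/acceptance.R`
recomputes the same quantities from scratch with a caller-supplied seed.

## Known limitations

* The two-angle protocol cannot flag a voxel whose noise moves it to a
  plausible but wrong T1 — with two observations and two parameters the fit
  is exactly determined; the three-angle protocol with residual reporting
  is the guard.
* The region-mean 24 h Mn index mixes compartments; it is a VOI average by
  design, not an islet-specific measure.
* Spot detection assumes spots brighter than the background median by the
  threshold factor; low-contrast islets on heterogeneous sections need a
  tuned `threshold_k`.
* Absolute elemental quantification against tissue standards is out of
  scope; elemental maps are treated as already linearly calibrated.
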