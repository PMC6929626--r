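# memripet

Quantification pipeline for simultaneous PET / manganese-enhanced MRI
(ME-MRI) studies of the pancreatic beta cell, with the ex vivo validation
chain (autoradiography, elemental mass-spectrometry imaging, insulin
secretion assays) and a seeded digital mouse-pancreas phantom that makes
every stage testable without animal data.

## The problem and who this is for

Preclinical imaging groups studying diabetes and insulinoma models want two
numbers from one session: **beta-cell mass**, read from the uptake of a
GLP-1-receptor-targeted PET tracer ([⁶⁴Cu]exendin-4), and **beta-cell
function**, read from the uptake of Mn²⁺ — a calcium analogue that enters
beta cells through voltage-dependent calcium channels during
glucose-stimulated insulin secretion and shortens T1 where it accumulates.
This package implements the full quantification chain between reconstructed
images and statistics:

* **MR**: variable-flip-angle (VFA) T1 mapping from spoiled gradient-echo
  magnitude stacks, `S(α) = M0 sin α (1−E1)/(1−E1 cos α)`, `E1 = exp(−TR/T1)`
  — closed-form inversion for two angles (4°, 22°), linearized least squares
  plus a nonlinear polish for three (4°, 14°, 27°); conversion to
  relaxation-rate maps `R1 = 1/T1` filtered to the physiological window
  [0.4, 10] s⁻¹; relaxivity calibration from a phantom dilution series; and
  manganese concentration maps `[Mn] = (R1post − R1pre)/r1`, voxel-wise or
  as the 24 h region-mean index.
* **PET**: decay-corrected percent injected dose per millilitre,
  `%ID/mL = 100 · A(kBq/mL) · 2^(t/12.7 h) / dose`.
* **Multimodal**: affine resampling onto a common grid, 1–8× block
  downsampling of VOI voxels, Pearson correlation of `log10(%ID/mL)` vs
  `log10(R1)` (region-mean and voxel-wise), Welch t and Wilcoxon rank-sum
  group statistics.
* **Ex vivo**: islet spot detection on 50 µm autoradiography scans with
  islet-to-exocrine ratios and signal-vs-diameter regression; 8-bit additive
  RGB merging of ⁴⁴Ca/⁶⁴Zn/⁵⁵Mn elemental maps; endocrine enrichment scores;
  glucose-stimulated insulin-secretion enhancement indexes (15 mM vs 3 mM).

The phantom encodes the signature the pipeline exists to detect: manganese
is exocrine-dominant at 1 h and retained by islets/insulinomas at 24 h, while
the PET tracer is endocrine-specific throughout — so the voxel-wise PET–MR
correlation flips from negative at 1 h to positive at 24 h.

## Worked example

```r
library(memripet)

spec <- phantom_spec(rng_seed = 42)       # 64³ digital mouse pancreas
lab  <- build_label_map(spec)
lab
#> <label_volume> 64 x 64 x 64 voxels
#> background   exocrine      islet insulinoma
#>     234408      26922        118        696

acq <- acquisition_params(flip_deg = c(4, 22))
fit <- fit_t1_vfa(simulate_vfa_stacks(lab, spec, "pre", acq), acq)
summary(fit)
#> VFA T1 fit (TR 10 ms, angles 4°, 22°)
#>   262144 voxels, 262144 valid, 0 invalid
#>   T1 quartiles (s):
#>     0%    25%    50%    75%   100%
#> 0.7375 0.7916 0.8021 0.8144 1.6158

r1_pre <- t1_to_r1(fit)
r1_1h  <- t1_to_r1(fit_t1_vfa(simulate_vfa_stacks(lab, spec, "1h", acq), acq))
estimate_mn(r1_pre, r1_1h, spec$relaxivity_r1)
#> <mn_map> 64 x 64 x 64 voxels, 262144 valid, 0 negative; median 0.05084 mM

voi <- pancreas_mask(lab)
pid <- percent_id_per_ml(simulate_pet_volume(lab, spec, "1h"),
                         spec$injected_dose_kBq, frame_time_h = 1)
blocks <- downsample_blocks(list(pid = pid$pid_per_ml, r1 = r1_1h$r1_s_inv),
                            voi & r1_1h$validity, factors = c(2, 2, 2))
correlate_pet_mr(blocks$pid, blocks$r1)
#> Pearson correlation (voxelwise, transform log10): r = -0.984,
#>   t(3550) = -330.454, p = 0, n = 3552 (0 pairs excluded)
```

The median quartile block (~0.80 s) is dominated by non-pancreatic tissue;
pancreas voxels sit near the 1.4 s pre-contrast T1 and shorten after
contrast. The negative voxel-wise correlation at 1 h (here r = −0.98; the
same code at the 24 h time point gives r = +0.93) is the early/late sign
flip: at 1 h manganese enhancement marks exocrine tissue, which the
beta-cell-specific tracer avoids.

Relaxivity calibration from a dilution series works on measured pairs:

```r
calibrate_relaxivity(c(0, 0.05, 0.1, 0.2, 0.4),
                     c(0.41, 0.66, 0.92, 1.93, 2.80))
#> Relaxivity calibration: r1 = 6.23 s^-1 mM^-1, intercept 0.4095 s^-1,
#>   R^2 = 0.9744 (n = 5)
```

`run_pipeline(pipeline_config(spec = phantom_spec()))` executes the whole
chain — phantom, T1/R1/[Mn], %ID/mL, correlations, sections, secretion —
and writes NIfTI volumes, TIFF sections, stamped CSV tables and a JSON run
log to the configured output directory; re-running the same configuration
is bit-identical.

See the vignette
(`vignettes/quantifying-beta-cell-mass-and-function.Rmd`) for the models,
assumptions, phantom design and numerical choices.

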