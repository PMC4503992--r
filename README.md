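# cytomech

Quantitative mechanics and imaging analytics for amoeboid tumor-cell
studies, in one tested R package. It covers the five bespoke numerical
procedures such studies chain together:

1. **Constrained traction force microscopy (TFM).** Cells plated on
   polyacrylamide gels (1, 11 or 26 kPa) deform the substrate; bead
   displacements `u` relate to the cell-exerted traction `t` through the
   Boussinesq half-space Green's tensor
   `G_ij(r) = (1+ν)/(π E |r|) · [(1−ν) δ_ij + ν r_i r_j/|r|²]`.
   `cytomech` solves the forward problem by FFT convolution and the
   inverse problem (regularized Fourier-transform traction cytometry) by
   filter-preconditioned conjugate gradients with zeroth-order Tikhonov
   regularization, optionally constrained to zero traction outside the
   traced cell contour. λ can be fixed or chosen by L-curve corner.
2. **Per-cell mechanics read-outs.** RMS traction, the first-order moment
   matrix `M_ij = ½ Σ (x_i t_j + x_j t_i) dA`, the net contractile moment
   `tr(M)` (negative for contractile cells), and the polarity ellipse:
   semi-axes `|λ₁| ≥ |λ₂|` of M, orientation of the dominant eigenvector,
   polarity `|λ₁|/(|λ₁|+|λ₂|) ∈ [0.5, 1]`.
3. **Microtubule dynamics.** Per-trace maximum length change
   `100·(max−min)/max` (%), per-cell longest-MT lengths, and exact /
   tie-corrected Mann–Whitney group comparison.
4. **3-D perinuclear quantitation.** Detector-gain normalization by
   inverting a fitted quadratic `y = a₂x² + a₁x + a₀`; Otsu nuclear and
   cytoplasmic masks; a perinuclear shell of thickness ¼ of the nuclear
   radius built by anisotropy-aware Euclidean dilation; per-compartment
   mean intensities. Plus densitometric fold-change and ratio
   normalizations.
5. **Interactome filtering and cohort survival.** Pseudo-counted fold
   enrichment with an inclusive ≥2-fold DEP cut; expression
   dichotomization at the 25th percentile, Kaplan–Meier curves, log-rank,
   Fisher exact and Wilcoxon rank-sum tests (Cox PH delegated to the
   `survival` package).

Every stage has a synthetic-data generator with known ground truth
(`simulate_traction_scene()`, `simulate_mt_traces()`,
`simulate_confocal_stack()`, `simulate_cohort()`,
`simulate_intensity_table()`, `simulate_tfm_study()`), so the whole
pipeline is testable without microscopes or clinical data.

## Worked example

```r
library(cytomech)

gel  <- gel_substrate(11e3)          # 11 kPa, nu = 0.5
grid <- grid_spec(2, c(64, 64))      # 2 um spacing, 128 x 128 um field
dip  <- dipole_spec(center = c(63, 63), axis_angle = 0,
                    force_magnitude = 100, separation = 20,
                    patch_radius = 4)
scene <- simulate_traction_scene(list(dip), gel, grid, noise_sd = 0)

trac <- constrained_inverse(scene$displacement, scene$mask, gel,
                            reg_lambda = 0)
relative_l2(trac, scene$traction)
#> [1] 0.0004425193
summarize_cell(trac, scene$mask)
#> Traction summary
#>   RMS traction        : 0.2626 Pa
#>   net force           : (-2.66e-14, -1.45e-12) pN
#>   contractile moment  : -2000 pN um
#>   polarity            : 1.000
#>   orientation         : 0.000 rad
#>   spread area         : 1424 um^2
```

The recovered field matches the ground truth to 0.04% relative L2; the
contractile moment reproduces the hand-computable dipole value (100 pN
poles 20 um apart → trace(M) = −2000 pN·um), the net force is zero to
rounding, and the uniaxial dipole reports polarity 1.

A cohort example:

```r
d <- simulate_cohort(200, hazard_ratio_low_vs_high = 3, censor_rate = 0.2,
                     seed = 8)
res <- cohort_survival_analysis(d)
res$logrank$p_value
#> [1] 4.330248e-06
```

## Command line

`inst/scripts/cytomech` dispatches `simulate tfm|mt|cohort`,
`tfm invert`, `mtdyn stats`, `enrich deps`, `cohort km` and `run`
(the simulate → invert → metrics pipeline); see `?cytomech_cli`.
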