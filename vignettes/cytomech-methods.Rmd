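---
title: "Models, numerics and design choices in cytomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in cytomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cytomech` packages the quantitative procedures used in amoeboid
cell-mechanics studies: constrained traction force microscopy (TFM) and
its scalar read-outs, microtubule (MT) length-trace statistics,
gain-normalized 3-D perinuclear intensity quantitation, interactome
fold-enrichment filtering, and expression-quartile survival comparison.
This vignette records the models, their assumptions, the tunable
parameters, and the choices made where the underlying protocols leave the
design open. Every number quoted here is computed by the test suite or
`scripts/acceptance.R`; nothing below is asserted without being
recomputed there.

## 1. Traction force microscopy

### Model

The gel is treated as a linear-elastic, isotropic, semi-infinite
half-space. The in-plane surface displacement caused by a tangential
point force is the Boussinesq solution

$$G_{ij}(\mathbf r) \;=\; \frac{1+\nu}{\pi E\,|\mathbf r|}
\left[(1-\nu)\,\delta_{ij} + \nu\,\frac{r_i r_j}{|\mathbf r|^2}\right],$$

with Young's modulus $E$ in Pa, positions in µm, and tractions in Pa
(1 Pa·µm² = 1 pN). Assumptions worth keeping in mind: infinite gel
thickness (no finite-depth correction), purely tangential tractions (no
z-component), and displacements measured at the gel surface.

**Poisson ratio.** $\nu$ defaults to 0.5, the incompressible limit
conventionally assumed for polyacrylamide; it is overridable in
`gel_substrate()`. Stated gel stiffnesses in the motivating experiments
are 1, 11 and 26 kPa.

### Discretization and the forward map

`forward_solve()` convolves the Green's tensor with `t·dA` on the node
grid, in Fourier space with 2× zero-padding per axis, so the convolution
is linear, not circular. The kernel's singular self-cell is replaced by
the analytic cell average of $G$ over one grid square
($\int_{\square} |\mathbf r|^{-1}\,dA = 4h\ln(1+\sqrt2)$ for side $h$,
and the quadratic term integrates to half of that by symmetry).

### Inversion

`fttc_inverse()` minimizes
$\|F\,t - u\|^2 + \alpha^2\|t\|^2$, where $F$ is the padded, cropped
linear-convolution operator above and $\alpha = \lambda\,s$ with $s$ the
largest singular value of the discrete kernel, making `reg_lambda`
dimensionless. A one-shot circulant Tikhonov filter is *not* sufficient
here: the displacement field of a dipole decays slowly, and truncating it
at the field of view makes the plain inverse filter err by ~10% on a
64×64 scene. The solver therefore runs conjugate gradients on the normal
equations, preconditioned by that circulant filter (which also provides
the starting iterate). On a noiseless dipole this round-trips to
machine precision; the acceptance report quotes 0.04% relative L2.

`constrained_inverse()` adds the defining feature of constrained TFM:
tractions are exactly zero outside the traced cell contour. The same CG
iteration runs with a mask projection each sweep (equivalently:
invert, zero outside the contour, forward-correct the residual).
A mask covering the whole grid reproduces `fttc_inverse()` identically,
and recovered dipole scenes balance forces to better than 1%
(criterion: < 5%).

**Choosing λ.** `select_lambda_lcurve()` evaluates the *direct filter*
solutions on a 20-point log grid (default $10^{-4}$–$1$) and picks the
corner of the (log residual, log solution norm) curve by maximum Menger
curvature. The direct filter is used deliberately: CG semi-converges and
never produces the noise-blown solutions that give the L-curve its
vertical branch. Under 5% relative displacement noise the selected λ
lands near the error minimum (~10% reconstruction error, vs ~16%
unregularized).

**Scattered beads.** Real bead displacements arrive at scattered points.
No Delaunay triangulation library is available in the supported
dependency set, so `interp_displacements()` fits a local weighted plane
through the k nearest beads per node (nodes far from any bead are zeroed).
This replaces the classical triangulation dialect; for smooth fields the
two agree to interpolation error.

### Scalar read-outs

The moment matrix is computed about the *traction-weighted centroid* and
symmetrized; the reference point is otherwise unspecified in the
literature this mirrors, and the weighted centroid makes `tr(M)` of a
clean dipole exactly $-F\,d$ (−2000 pN·µm for 100 pN poles 20 µm apart).
"Contractile moment" is taken to be trace(M), following the standard TFM
literature. Polarity is defined as $|\lambda_1|/(|\lambda_1|+|\lambda_2|)$
rather than a raw eigenvalue ratio: it is bounded in [0.5, 1], equals 0.5
iff the moments are isotropic, and does not diverge for uniaxial dipoles
(raw $\lambda_1/\lambda_2$ would). Users comparing against raw-ratio
numbers should convert accordingly. Orientation is folded to $[0,\pi)$
because traction axes are unsigned.

## 2. Synthetic traction scenes

`simulate_traction_scene()` builds ground truth from contractile dipoles:
two Gaussian force patches (sd = `patch_radius`) pulling toward their
common center. Gaussian patches, not delta functions, keep the field
band-limited on the grid; pole weights are normalized by their *discrete*
sum, so net force is zero to rounding by construction. Displacements are
the exact forward solution plus i.i.d. Gaussian noise.

The two-arm study generator (`simulate_tfm_study()`) states a world in
which: control cells are dipole pairs whose anisotropy grows with
stiffness (secondary/primary force 0.6 / 0.35 / 0.2 at 1 / 11 / 26 kPa)
and whose pole force grows with stiffness (2, 15, 30 nN — chosen so that
bead displacements stay comparable across gels, as they do in practice
when cells stiffen their pulling on stiffer substrates); "silenced" cells
are near-isotropic orthogonal pairs whose pole forces are derived so
their traction magnitude is 40% below control. Bead noise is 5 nm,
typical sub-pixel tracking precision. Per-cell lognormal force jitter
(15%) provides biological spread. With n = 20 cells/arm this reproduces
the qualitative pattern the method is used to detect: lower median RMS in
the silenced arm (Mann–Whitney p < 10⁻⁵ at each stiffness), silenced
polarity pinned near 0.5 and flat across stiffness, control polarity
rising with stiffness. A green test establishes that the pipeline
*detects a planted effect of this size*; it says nothing about effect
sizes in real cells.

## 3. Microtubule statistics

The dynamicity read-out per trace is
$100\,(L_{max}-L_{min})/L_{max}$ (%), computed over the canonical 10
frames / 30 s acquisition; other frame counts warn rather than error
because the formula is well defined for any ≥ 2 frames. Ten frames at a
3 s interval span 27 s first-to-last, the sampling convention matching a
"30 s period" description. Traces are pooled across cells for group
comparison (matching how such data are analyzed, e.g. 41 vs 35 MT), with
`cell_id` retained for per-cell aggregation.

The generator is a multiplicative lognormal random walk reflected at a
0.2 µm floor — a stand-in, since only the measurement statistic is under
test, with `dynamicity` as the per-frame log-sd. Two consequences shape
the tests: (i) `dynamicity = 0` gives exactly constant traces; (ii) the
per-cell *longest* length is a running maximum, biased upward as
dynamicity grows, so base-length recovery is asserted at `dynamicity =
0.02` (a near-stable population) where the bias is within the 10%
tolerance. That bias is a property of the statistic, not a defect.

The Mann–Whitney implementation enumerates all group assignments for
combined n ≤ 12 (ties handled by mid-ranks in the enumeration) and
otherwise uses the tie-corrected normal approximation with continuity
correction. The two-sided p is $P(|U - \mu| \ge |u_{obs} - \mu|)$, which
is symmetric in group order. At n = 12 the approximation tracks
enumeration to ~0.005 mean absolute difference (worst case ~0.015 across
random datasets — the test asserts the mean, because the worst case is a
property of the normal approximation itself).

## 4. Gain normalization and perinuclear shells

The detector model is $y = a_2x^2 + a_1x + a_0$, with $y$ the recorded
and $x$ the underlying intensity, fitted by least squares to calibration
pairs (matched acquisitions at e.g. 600/700/800 V); three distinct pairs
are interpolated exactly. `normalize_intensity()` inverts the quadratic
per voxel, keeping the root on the strictly increasing branch inside the
curve's valid range; non-invertible voxels are flagged NA and excluded
from means, never silently clamped. All images are mapped to a common
reference gain; which gain is the reference is a config choice, since the
direction of normalization is a convention.

Segmentation (`segment_masks()`) uses Otsu global thresholds (256-bin),
the largest 6-connected component, and 3-D hole filling for the nucleus;
the exact cleanup recipe of published mask definitions is not reprinted
anywhere, so this standard dialect was adopted, with the threshold
channelled through a replaceable function. The nuclear radius estimate is
the equivalent-sphere radius $(3V/4\pi)^{1/3}$. The perinuclear shell is
the set of voxels with anisotropy-aware Euclidean distance
$0 < d \le f\,R$ from the nuclear mask, built by FFT dilation with an
ellipsoidal ball; the "~¼ of the average nuclear radius" thickness
resolves to `shell_fraction = 0.25` exactly, and a cohort-average radius
can be supplied (`reference_radius`) for the cohort-wide reading of
"average". Distance is measured from the real nuclear mask, not a fitted
sphere, so non-spherical nuclei get a conforming shell. Cytoplasm and
shell are reported as *disjoint* compartments (cytoplasm excludes the
shell): the shell/cytoplasm ratio of an enrichment-2 phantom is then
exactly 2 on ground-truth masks, and ~1.95 through the full segmentation
at 0.4 µm voxels — the residual being boundary-voxel misassignment that
shrinks with voxel size (the suite checks the error decreases across two
resolutions; shell-volume error at 0.4 µm is ~4% against the continuous
$\tfrac43\pi(10^3-8^3)$ µm³ oracle).

The synthetic stacks use a spherical (optionally ellipsoidal) nucleus,
a surrounding cell ellipsoid of cytoplasmic baseline intensity, the
enriched shell, quadratic gain distortion and additive Gaussian noise.
They do not emulate point-spread blur, photobleaching, shot noise
statistics, or multi-cell fields (one cell per field is assumed, as in
the imaging this mirrors) — a green quantitation test therefore validates
the arithmetic and geometry, not robustness to those effects.

## 5. Enrichment filtering

Fold enrichment is $(b + p)/(c + p)$ per protein with pseudo-count $p$;
the default $p$ is the smallest nonzero intensity in the table, since how
zero-intensity controls were originally handled is unstated, and the
pseudo-count keeps every fold finite. Intensities sharing a protein id
are summed before ratioing. The DEP cut is *inclusive* (fold ≥ 2 for
"2-fold greater"). The synthetic table generator plants exact target
folds around a stated pseudo-count, so the 417-protein / 130-enriched
configuration is recovered exactly in the noiseless case.

## 6. Cohort statistics

Expression is dichotomized at the 25th percentile — "low" strictly below,
ties to "high" — using linear interpolation between order statistics
(type-7 quantiles, R's default); the convention is configurable because
the original quartile software is unknown. Kaplan–Meier and the
unweighted log-rank test are implemented directly (and verified against
`survival::survfit`/`survdiff` in the tests); Fisher's exact test sums
hypergeometric probabilities ≤ the observed table's and reports the
conditional-MLE odds ratio; Cox proportional hazards is deliberately a
thin wrapper around `survival::coxph`, since reimplementing its internals
would add risk without insight.

The cohort generator draws exponential event times whose hazard depends
on the low/high split, with a uniform censoring mechanism applied to a
Bernoulli-selected fraction — the simplest world in which the
dichotomization/log-rank machinery is exercised. Calibration holds: the
null rejection rate is ~5% over 1000 replicates and power is monotone in
the hazard ratio (>80% at HR 3, n = 200).

**Seeding note.** All generators accept `seed = NULL` to draw from the
ambient RNG stream. Replicate loops (type-I error, power) seed once and
pass `NULL`: consecutive small integer seeds produce measurably
correlated Mersenne–Twister streams, which inflated an early type-I
estimate to 8% before the single-stream design was adopted.

## 7. I/O and reproducibility

Grids, tractions, contours, traces and cohorts travel as CSV with
unit-suffixed columns (`x_um`, `tx_Pa`, …) and `#`-prefixed provenance
headers (tool version, seed, config hash). Stacks travel as multi-page
TIFF; because no TIFF package exists in the supported dependency set, a
minimal baseline writer/reader (uncompressed, little-endian, 32-bit
float, metadata as JSON in ImageDescription) is built in — it reads the
dialect it writes (plus 8/16-bit unsigned grayscale) and has been checked
against an independent TIFF implementation. Note float64 arrays are
stored as float32: round-trips are bit-exact only after quantization.
The pipeline (`run_pipeline()`) is deterministic given (config, seed);
unknown config keys are rejected before any stage runs.

## Known limitations

- Half-space elasticity only: no finite gel thickness, no z-tractions.
- Polarity convention differs from raw eigenvalue ratios (see §1).
- Shell quantitation accuracy is voxel-size limited (§4).
- The MT generator is a phenomenological random walk, not a
  dynamic-instability model; rescue/catastrophe parameters are out of
  scope.
- The cohort generator's exponential hazards and uniform censoring are
  the simplest calibration world; no covariates, no competing risks.
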