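---
title: "Models, estimators and design choices in hippomicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in hippomicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hippomicro)
```

`hippomicro` implements a surface-based analysis of hippocampal gray-matter
microstructure across development: forward biophysical diffusion-MRI models
and their estimators, a Laplace-equation coordinate system over the
hippocampal gray matter with orientation (cosine-similarity) maps, and the
statistical battery used to relate microstructural metrics to age, sex and
position along the hippocampal axes. Because the pipeline is exercised on
synthetic data with known ground truth, every stage is testable end to end;
this vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not establish about real
data.

## Signal models

All signals are normalized to the b = 0 level; b-values are in ms/&mu;m&sup2;
and diffusivities in &mu;m&sup2;/ms throughout (readers of FSL-style `.bval`
files convert from s/mm&sup2; by 10^-3^).

**Diffusion tensor.** `tensor_signal()` evaluates
S = S&#8320; exp(&minus;&lang;B, D&rang;&#7584;) with B = b gg&#7488; per
volume. `fa_md()` maps eigenvalues to mean diffusivity (their mean) and
fractional anisotropy (normalized eigenvalue dispersion); the all-zero
tensor is assigned FA = 0 by convention.

**Watson-dispersed sticks (NODDI).** The three-compartment signal is
S = (1 &minus; f~iso~)[f~in~ S~in~ + (1 &minus; f~in~) S~en~] +
f~iso~ S~iso~, with the intra-neurite compartment a set of zero-radius
cylinders ("sticks") whose orientations follow a Watson distribution with
concentration &kappa; about a mean direction &mu;, the extra-neurite
compartment a dispersion-averaged axially symmetric tensor with tortuosity
d&#8869; = d&#8741;(1 &minus; f~in~), and CSF an isotropic ball. The
parallel diffusivity is fixed at 1.7 and the CSF diffusivity at 3.0
&mu;m&sup2;/ms, the conventional values. Orientation dispersion is
summarized as ODI = (2/&pi;) arctan(1/&kappa;), extended by continuity to
ODI(0) = 1.

The dispersed-stick integral is evaluated by Legendre band convolution
(Funk–Hecke): writing the Watson density as a function of t = u&middot;&mu;
and the stick kernel as exp(&minus;bd t&sup2;), the signal at angle &alpha;
from &mu; is &Sigma;~l~ g~l~ k~l~ P~l~(cos &alpha;) over even orders
l &le; 40, with both one-dimensional integrals done by 64-node
Gauss–Legendre quadrature. Against brute-force adaptive 2-D quadrature this
is accurate to better than 10^-8^, comfortably inside the documented
10^-6^ target, and it makes the per-voxel NODDI objective cheap enough for
multi-start fitting in pure R.

**Soma and neurite spherical means (SANDI).** Fitting uses the spherical
mean (powder average) per shell, which removes orientation dependence:
S&#773;(b) = (1 &minus; f~ec~)[f~in~ S&#773;~in~ + (1 &minus; f~in~)
S&#773;~is~] + f~ec~ S&#773;~ec~. The stick spherical mean has the closed
form &radic;(&pi;/4bD) erf(&radic;bD); the extracellular compartment is an
isotropic ball exp(&minus;bD~ec~); and the soma compartment is restricted
diffusion in a sphere of radius r~s~ under the Gaussian-phase-distribution
approximation — the Murday–Cotts series over roots of the spherical Bessel
derivative, using 50 precomputed roots (20 vs 50 roots agree to better than
10^-8^ for r~s~ &le; 12 &mu;m). Gradient strength enters through
b = &gamma;&sup2;G&sup2;&delta;&sup2;(&Delta; &minus; &delta;/3). Pulse
timings are nowhere implied by the protocol's b-values alone, so they are
explicit configuration: defaults &delta; = 7 ms, &Delta; = 24 ms
(plausible for an ultra-strong-gradient system); absolute soma radii are
therefore timing-dependent, and only recovery and relative behavior are
asserted in tests. Derived maps are f~extracellular~ = f~ec~,
f~neurite~ = (1 &minus; f~ec~) f~in~,
f~soma~ = (1 &minus; f~ec~)(1 &minus; f~in~); they sum to 1 exactly.

## Estimators

**DTI** (`fit_dti()`): two-pass weighted linear least squares on the
log-signal using volumes with b &le; 1.2 (the b = 0, 0.5, 1.2 shells of the
default protocol), weights equal to squared predicted signals. Noiseless
tensors are recovered to ~10^-15^ relative error.

**NODDI** (`fit_noddi()`): multi-start bounded L-BFGS-B over
(f~iso~, f~in~, log &kappa;, &theta;, &phi;) on all volumes, with the mean
orientation initialized from the principal eigenvector of a low-b tensor
fit and &kappa;/fraction starts from a small grid. Noiseless f~in~ and ODI
are recovered within 10^-3^.

**SANDI** (`fit_sandi()`): multi-start bounded Levenberg–Marquardt on the
per-shell spherical means, bounds f &isin; [0, 1], r~s~ &isin; [1, 12]
&mu;m, diffusivities &isin; [0.1, 3] &mu;m&sup2;/ms, with the sphere curve
pre-tabulated over radius and interpolated by a natural spline (error
~10^-8^, negligible against the series itself).

*Identifiability.* With six shells of direction-averaged data the fully
free five-parameter problem (f~ec~, f~in~, r~s~, D~in~, D~ec~) is not
identifiable: profiling the noiseless objective shows an essentially flat
ridge (rms residual ~4&times;10^-5^ while f~in~ moves across [0.2, 0.5],
about fifty-fold below the shell-mean noise floor at SNR 50), and roughly a
quarter of random gray-matter parameter draws admit a *distinct* parameter
set whose forward curve is numerically identical. Unregularized estimates
therefore smear along the ridge (observed f~neurite~ bias &asymp; &minus;0.13 at
SNR 50, persisting at SNR 200). The default estimator consequently fixes
D~in~ = 1.7 &mu;m&sup2;/ms — the same convention NODDI applies to its stick
compartment, and for the same reason — which restores identifiability:
noiseless recovery across gray-matter parameter ranges is then exact to
~10^-8^, and at SNR 50 the fraction biases are within 0.05 and the soma
radius bias within 1.5 &mu;m. `free_d_in = TRUE` exposes the fully free
variant; it recovers parameters at isolated well-conditioned points but
cannot do so over random draws, which is a property of the model-protocol
pair, not of the optimizer. Rician bias is not corrected during fitting and
is documented as a known small bias source at high b.

**Peaks** (`principal_peak()`): the default orientation source is the
principal eigenvector of the fitted tensor, with near-isotropic locations
(FA &lt; 0.05) flagged undefined; an even-order real spherical-harmonic
surface can be supplied instead, maximized by dense-grid search plus
Nelder–Mead refinement. Peaks are orientations, so u and &minus;u are
identified and reported in a canonical hemisphere.

## Coordinates, surfaces and macrostructure

`solve_laplace()` discretizes the Laplace equation with the 7-point stencil
on the 6-connected gray-matter mask and solves by red-black successive
over-relaxation (&omega; = 1.9, max-update tolerance 10^-6^, iteration cap
10^5^). Dirichlet conditions are anchored on the *faces* between mask and
boundary-label voxels (ghost value 2c &minus; v), so the 0 and 1 level sets
sit on the tissue boundary rather than at label-voxel centers; background
neighbors get reflecting ghosts. A connected-components check names any
mask component that touches neither source nor sink. The discrete maximum
principle keeps interior values strictly inside (0, 1).

The validation phantom is a sector of a cylindrical annulus — a curved slab
whose anterior-posterior coordinate runs along the arc, proximal-distal
along the cylinder axis and inner-outer across the radius — so the three
coordinate gradients are exactly orthogonal everywhere. Two details make it
an exact oracle rather than an approximate one. First, the analytic depth
coordinate between two concentric cylinders is the *log-radial* harmonic
ln(r/r&#8320;)/ln(r&#8321;/r&#8320;), not the linear radial map (they agree
as the bend radius grows); the angular and axial coordinates are already
harmonic. Second, planar domain faces are aligned with voxel faces by
construction (extents are whole multiples of the voxel size), which is
exactly where the discrete Dirichlet conditions live — the straight slab
is then recovered to solver tolerance, and the curved slab to &lt; 0.013
absolute error away from a 2-voxel rim at the default 0.3 mm / 20-voxel
thickness resolution. Gradient *directions* (central differences inside,
one-sided at edges) match the analytic fields within 2&deg; away from a
5-voxel margin — wider than the field's own rim because the difference
stencil widens the boundary's influence zone.

Cosine similarity between a coordinate gradient and a diffusion peak is
taken in absolute value: diffusion peaks are antipodally symmetric, which
also gives the documented [0, 1] range (0 orthogonal, 1 parallel).

The standard surface template is a quasi-regular 107 &times; 68 unfolded
grid with a 7-vertex notch removed at two opposite corners (tapering, as
the anterior uncus and posterior tail taper), for exactly 7262 vertices per
hemisphere; subfield labels partition the proximal-distal axis
(subiculum 0.22, CA1 0.30, CA2 0.10, CA3 0.14, DG/CA4 0.24 — the dentate
gyrus and CA4 are merged) and five long-axis bins partition the
anterior-posterior axis (uncus to tail at cuts 0.15/0.35/0.60/0.80).
Surface vertices are placed by inverting the coordinate mapping: nearest
gray-matter voxel in (AP, PD, IO) space, refined by damped Gauss–Newton on
trilinearly interpolated fields (off-mask corners dropped and weights
renormalized, so interpolation degrades gracefully at the mask edge).
Volume-to-surface sampling defaults to the enclosing method — the value of
the voxel containing the vertex, with half-open voxel boxes so a vertex
exactly on a face belongs to the lower-index voxel — with trilinear
interpolation available for smooth maps such as tissue probabilities.

Macrostructure uses deliberately simplified, monotone definitions:
subfield volume is voxel count times voxel volume; thickness is the
Euclidean distance between paired inner and outer surface vertices placed
at a laminar inset of one voxel's IO increment (estimated from the field
gradient) and rescaled by 1/(1 &minus; 2&epsilon;) — exact on an affine
slab, a proxy elsewhere; gyrification is native vertex area over unfolded
vertex area. These are named and tested as proxies, not as reproductions
of any particular surface tool's definitions.

## Statistics

The battery mirrors a cross-sectional developmental design:

- *Tiered Pearson screening* (`pearson_screen()`): two-sided correlation
  tests against age with tiers 0.01, 0.005, 0.0005; the 0.01 minimum alpha
  equals a Bonferroni family of five (one metric across five subfields) at
  family-wise 0.05 (`screening_alpha()`).
- *Nested F-tests* (`nested_f_test()`, `age_by_group_test()`,
  `age_by_parcel_test()`): full vs reduced linear models; the age-by-group
  interaction test on top of `value ~ age + parcel + group + age:parcel +
  group:parcel` and the age-by-parcel slope test dropping `age:parcel`
  from the full model. On study-shaped data (88 subjects, 5 subfields)
  these reproduce denominator df 424 hemisphere-averaged, 864 with both
  hemispheres, and numerator df 4 — pure functions of design shape.
  Treatment contrasts with subiculum/F/L references are the default;
  F-tests are coding-invariant (asserted by test). FDR correction is
  Benjamini–Hochberg within each test family.
- *Vertex-wise age contrasts* (`vertexwise_age_contrast()`): per-vertex
  OLS of `DV ~ age + sex + age:sex` on hemisphere-averaged data, reporting
  t = &beta;&#770;~age~/SE. Computed by a single shared-design matrix
  solve across vertices; degenerate vertices are masked.
- *Positional gradients* (`gradient_correlation()`): absolute Pearson
  correlation of a t-map with the unfolded AP and PD coordinates, plus the
  mean absolute t as a coarse total-effect size.
- *Spin test* (`spin_test()`): the null for correlating two surface maps
  preserves spatial autocorrelation by rigidly shifting one map in the
  unfolded rectangle with toroidal wrap-around (two uniform offsets),
  nearest-vertex resampling, and the two-sided add-one permutation
  p-value. Hippocampal maps live on a rectangle after unfolding, so
  plane shifts play the role spherical rotations play for cortical maps;
  wrap-around keeps every permutation a bijection-like relabeling at the
  cost of splicing opposite edges, which is why calibration is asserted
  empirically (fraction of p &lt; 0.05 on independent smooth fields falls
  in [0.02, 0.09], slightly conservative).

## The synthetic generator and what tests establish

`make_cohort()` draws ages uniformly by default — uniform sampling
maximizes slope-estimation power; a linearly decreasing "young-skewed"
density is available to mimic cohorts with more children than adolescents.
`make_protocol()` reproduces the 6-shell scheme (b = 0, 0.5, 1.2, 2.4,
4.0, 6.0 ms/&mu;m&sup2; with 14/30/30/60/60/60 volumes) with per-shell
electrostatic-repulsion direction sets. `make_parameter_surfaces()` builds
per-vertex ground truth as baseline + age slope &times; (age &minus; 13.5)
+ an extra male slope + a fixed AP- or PD-linear spatial pattern + vertex
noise, truncated to validity bounds with the truncation recorded in a
clamp mask so saturated vertices can be excluded from statistics; the
fraction triple is kept on the simplex with at least 2% soma signal and
sums to 1 exactly. Default effect sizes encode the qualitative
developmental profile the battery is designed to detect — neurite fraction
rising (+0.006/yr, +0.004/yr extra in males, AP-patterned), extracellular
fraction (&minus;0.006/yr) and mean diffusivity (&minus;0.008/yr,
PD-patterned) falling, soma radius slowly shrinking, ODI flat — with
baselines in the ranges reported for hippocampal gray matter (f~neurite~
&asymp; 0.15–0.30, ODI &asymp; 0.5, MD &asymp; 0.9 &mu;m&sup2;/ms). Rician
noise is the default (magnitude MRI), implemented as two Gaussian channels
of sd 1/SNR on the complex signal; the generator's mean is validated
against the closed-form Rician mean (Laguerre half-order form).

The generator emulates linear age and age-by-sex trends, smooth spatial
structure, and magnitude noise. It does *not* emulate partial voluming,
segmentation error, subject-specific anatomy, preprocessing artifacts,
non-linear development, or T2 differences between compartments (signal
fractions are not volume fractions). Passing tests therefore demonstrate
that the estimators and statistics are correct and calibrated under the
stated forward models — not that those models are unbiased descriptions of
hippocampal tissue.

## Problem sizes and runtime choices

Tests and the acceptance script run at sizes chosen to keep a desk-scale
run comfortable while preserving the study's design shape: design-df
checks at the full 88-subject shape; inverse-crime recovery at 200–300
tensor, 20–60 NODDI and 100–140 SANDI locations; SANDI bias at 500 voxels
and SNR 50; geometry on the default 0.3 mm phantom (~10^5^ gray-matter
voxels); calibration at 10^4^ Pearson replicates, 10^3^ F-null replicates
and 500 spin replicates of 99 permutations on a reduced mesh; and the
end-to-end demo at 30 subjects &times; 250 vertices with 200 spin
permutations (the full-scale 88 &times; 7262 / 2500-permutation
configuration sits behind `pipeline_config(full_scale = TRUE)`). The
demo's directional power is evaluated across the 20 parcel-level
screening tests of the two strongest configured trends (neurite fraction
up, MD down).

## Known limitations

- SANDI soma radii are apparent radii under the GPD approximation at the
  configured timings; absolute values shift with &delta;/&Delta;.
- The fully free SANDI contract is retained only as an option because the
  model-protocol pair is non-identifiable (above); real-data users should
  treat D~in~ as a convention, not an estimate.
- Thickness and gyrification are simplified monotone proxies.
- The spin-test null splices opposite edges of the unfolded rectangle;
  its calibration is asserted empirically rather than exactly.
- Estimator variance at SNR 50 is substantial per vertex; parcel averaging
  carries the statistical load, as it does in practice.
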