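---
title: "Methods: the DTI-ALPS pipeline, its simulators, and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS pipeline, its simulators, and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement model

The DTI-ALPS method rests on a geometric coincidence at the level of the
lateral ventricles: the perivascular spaces of the medullary veins run
left–right (x), while the two dominant white-matter systems there run
superior–inferior (projection fibers, z) and anterior–posterior
(association fibers, y). In either fiber region, diffusivity along x is
therefore perpendicular to the axons, and any excess of `Dxx` over the
fiber-perpendicular reference diffusivities is attributed to water movement
along the perivascular channels. The index is the ratio

$$\mathrm{ALPS} = \frac{\operatorname{mean}(D_{xx}^{proj},\; D_{xx}^{assoc})}
{\operatorname{mean}(D_{yy}^{proj},\; D_{zz}^{assoc})},$$

computed from VOI means of the scanner-frame diagonal tensor elements — not
eigenvalues. That distinction matters: eigenvalue maps would rotate with
the local fiber orientation and destroy the fixed-axis logic. The package
enforces one axis convention throughout (RAS+; x = left–right,
y = anterior–posterior, z = superior–inferior).

Assumptions inherited from the method: single-tensor diffusion per voxel,
VOIs genuinely inside coherent projection/association fiber regions, and
head alignment with the scanner axes. Violations (crossing fibers, tumor
infiltration into a VOI, oblique acquisitions) bias the index; the package
does not attempt to detect them on real data.

## Tensor estimation

`fit_tensor()` linearizes the Stejskal–Tanner equation and solves

$$\ln S_i = \ln S_0 - b_i\, g_i^\top D\, g_i$$

per voxel for the seven unknowns by least squares over all volumes. The
default is weighted least squares with a single reweighting by the squared
predicted signal, countering the heteroscedasticity the log transform
introduces (low signals carry noisier logs); one iteration keeps the
estimator deterministic and matches common DTI tooling. Plain OLS is
available and is exact on noiseless data — the suite uses that for
oracle-equivalence checks at `1e-9` mm²/s.

Numerical guards: signals are floored at `1e-6 · S0` before the logarithm;
at least six distinct encoding directions (antipodal pairs count once) and
one `b = 0` volume are required; a rank-deficient design (for example, all
directions coplanar) is an error naming the direction set. Negative fitted
diagonal elements are *kept* for ALPS extraction — clamping them would bias
the ratio in exactly the low-SNR voxels where bias matters most — and are
clamped at zero only inside `scalar_maps()`, where FA/MD are defined on
nonnegative eigenvalues (degenerate tensors get FA = 0 by convention).

## VOI geometry

The classical prescription is "four 4-voxel cubic VOIs" per subject. Four
voxels cannot tile a cube, so the package reads this literally as a
2×2-voxel in-plane square on a single slice at the ventricle level
(`edge = 2`, configurable), four VOIs total: projection and association
regions in each hemisphere. Voxel indices are 0-based and boxes half-open
in every interface. On phantoms, placement is automatic at the in-plane
centroid of each fiber band's labels; on real data the
reader-placed boxes are supplied as JSON. Multiple VOI sets per subject
(two readers) are accepted and the resulting per-hemisphere indices
averaged — the combination rule is a package choice, since consensus
procedures are rarely specified exactly.

## The phantom

`phantom_spec()` describes a block-geometry slab: per hemisphere a
CSF-filled ventricle box (isotropic 3.0e-3 mm²/s), a projection band
(diag `(α·0.63, 0.45, 1.4)`e-3) and an association band
(diag `(α·0.63, 1.4, 0.45)`e-3), embedded in grey-matter-like tissue
(0.8e-3), optionally with a spherical tumor (1.0e-3) and a PTBE shell
(1.2e-3). The noiseless index is then `1.4·α` per hemisphere: `α = 1`
emulates a healthy subject (index 1.4, matching typical control values) and
`α ≈ 0.9` a glioma-like reduction. `α` may differ by hemisphere to emulate
tumor-side impairment. The default grid is 64×64×16 at 2×2×4 mm — 4 mm
slices match the protocol the defaults are modeled on, and the grid is
small enough that a noiseless fit of the whole slab runs in seconds. The
default encoding scheme is 48 directions at b = 1000 s/mm² plus one
unweighted volume, placed by a Fibonacci spiral (deterministically rotated
per seed) — a placement whose worst-case pairwise angles are close to
electrostatic-repulsion schemes at these direction counts.

Noise is Rician, the standard magnitude-MR model: the magnitude of the
complex signal after adding i.i.d. Gaussian noise of standard deviation
`σ = S0/SNR` to both quadratures. The phantom does not simulate k-space,
eddy currents, motion, susceptibility distortion, or realistic anatomy;
passing tests demonstrate correctness of the estimators on
geometrically ideal data, not robustness to acquisition artifacts.

## The cohort generator

`simulate_cohort()` produces subject tables carrying the statistical
structure the analysis battery assumes, calibrated by default to a
published 112-glioma (35 LGG / 77 HGG) / 56-control group structure. Its
components, and the reasoning behind the non-obvious ones:

**Marginals.** Bilateral-mean ALPS and CSF volume are Gaussian per group
(glioma 1.266 ± 0.258 and 174.53 ± 34.89 cm³; control 1.395 ± 0.174 and
154.25 ± 20.89 cm³). Tumor volume, PTBE volume and Ki-67 are log-normal
because those variables are summarized as median (IQR); for a log-normal
with parameters `(μ, σ)` the median is `exp(μ)` and the IQR is
`2·median·sinh(0.6745σ)`, which `lnorm_from_median_iqr()` inverts exactly
(tumor 29.77 (36.79) cm³ → σ = 0.87; PTBE 37.48 (65.11) cm³ → σ = 1.17).

**Paired hemispheres.** The three configured ALPS SDs jointly determine
the within-subject correlation: for sides with SDs `s₁, s₂` and bilateral
mean SD `s̄`, `ρ = (4s̄² − s₁² − s₂²)/(2s₁s₂)`, which at the defaults
(0.297, 0.296, 0.258) gives ρ = 0.514 and a side-difference SD of 0.292.
The generator draws the bilateral mean first and splits it symmetrically by
a difference with mean `1.233 − 1.299 = −0.066`, so `alps_mean` is exactly
the average of the two sides. A consequence worth stating: at n = 112
pairs, a mean difference of 0.066 against a difference SD of 0.292 has
two-sided paired-t power of about 0.66 at α = 0.05, so roughly a third of
simulated cohorts do not reject — single-study significance at these
parameters is reproducible in most, but not all, replicates.

**Rank correlations.** ALPS, tumor volume, PTBE volume and CSF volume are
tied by a Gaussian copula. Spearman targets (−0.353 ALPS–tumor, −0.266
ALPS–PTBE, +0.427 tumor–PTBE) are converted to latent Pearson correlations
by `ρ_P = 2·sin(πρ_S/6)`. ALPS–CSF, tumor–CSF and PTBE–CSF default to 0:
no rank correlations are published for those pairs, and zero is the
conservative choice. The assembled latent matrix is checked for positive
definiteness at construction, with the offending eigenvalue reported.

**Covariate effects on ALPS.** Grade (LGG = 0, HGG = 1), age and Olig-2
act on the standardized ALPS latent with true multivariable standardized
coefficients β = (−0.244, −0.204, −0.317) and predictor correlations
r(grade, age) = 0.10, r(grade, olig2) = −0.1338, r(age, olig2) = 0. These
five numbers were solved jointly so that (i) the multivariable grade
coefficient equals −0.244 and (ii) the implied *univariate* standardized
coefficients `u = Σβ` match the published magnitudes (grade 0.222, age
0.228, Olig-2 0.284). The sign of the grade effect is taken as negative
(higher grade → lower ALPS) — the direction every other reported quantity
supports — and the published positive univariate grade coefficient is
treated as an artifact of an unstated coding direction. The same latent
construction makes the grade-conditional ALPS means emerge correctly
(≈ 1.35 LGG vs ≈ 1.23 HGG) without separate calibration, because the
published group summaries are mutually consistent.

Because the copula ties volumes to the ALPS *residual* (scaled by
`1/σ_ε` so the total ALPS–volume correlation hits its target), tumor and
PTBE volumes are conditionally independent of grade given ALPS. Simulated
LGG/HGG volume contrasts are therefore weaker than reported ones — coupling
volumes to grade as well would over-constrain the overall marginals the
recovery checks are defined on. This is a deliberate limitation.

**Composition.** Grade, IDH (36 mutant / 76 wild-type), sex (49 F gliomas,
27 F controls), glioma type (44/14/54) and tumor laterality (60 left /
42 right / 10 bilateral) are assigned by exact-count permutation, so every
cohort reproduces the composition exactly. Glioblastomas are confined to
the high-grade stratum. For bilateral tumors the cohort generator draws the
affected-side label at random (the published analysis does not state its
rule); in the imaging pipeline the convention is the hemisphere with the
larger tumor fraction. Olig-2 is a Gaussian expression score (50 ± 20
percentage points, unclamped to keep linear-model calibration exact).

## The statistical battery

Everything is two-tailed. The normality gate applies Shapiro–Wilk per
group and routes to the parametric branch only if *no* group rejects at
0.05; constant-valued groups route nonparametric. Two groups: Student's
pooled-variance t (the default reporting convention of mainstream SPSS-style
analyses; Welch by flag) or Wilcoxon rank-sum with the tie-corrected normal
approximation and no continuity correction. Three or more: one-way ANOVA
with Fisher's LSD post hoc (pairwise t on the pooled residual mean square,
unadjusted — that is what LSD means) or tie-corrected Kruskal–Wallis with
Dunn's z tests, whose p-values are reported raw and Holm-adjusted (use
Holm; the raw values exist because unadjusted Dunn tables are common in
clinical reports). Dunn's test is computed from the joint ranks directly
as no installed dependency provides it. Spearman matrices use average
ranks, pairwise-complete observations and the t approximation for p.
Every statistic is verified in the test suite against an independently
coded brute-force oracle on small fixed tables (1e-8), so the base-R calls
are never their own check; the gated two-group path's null rejection rate
is verified to sit in [0.035, 0.065] over 2000 Gaussian replicates.

The regression screen mirrors the two-stage convention: simple linear
regression per candidate, then one multivariable OLS on all candidates with
univariate p below the entry threshold (default 0.05). Standardized β is
the coefficient of the fully z-scored model; a condition number above 1e8
is an error naming the collinear set. Note the selection effect this
procedure carries by construction: averaging the multivariable grade
coefficient only over replicates where grade survives the univariate screen
(power ≈ 0.66 at these parameters) inflates its mean magnitude — the
replicate mean lands near −0.29 for a true −0.244. The recovery check
accounts for this with its stated ±0.10 band; users comparing calibrations
should prefer the unconditional coefficient.

## Reproducibility and problem sizes

All generators are deterministic per seed, and `run_pipeline()` writes an
MD5 manifest over every artifact so nondeterminism is detectable (NIfTI
output defaults to uncompressed `.nii`; gzip streams embed metadata that
breaks byte-identity). The recovery checks in the test suite and
`scripts/acceptance.R` use 200 replicates of the full 112/56 cohort
(seconds of runtime), 10,000-subject cohorts for marginal and copula
recovery (three standard errors / ±0.05), the default 64×64×16 phantom for
exact noiseless tensor recovery, and 32×32×8 phantoms for the α-sweep
monotonicity and noisy-fit error checks.

## Known limitations

* Block-geometry phantoms exercise the estimators, not anatomical realism;
  no partial-volume voxels exist, so VOI placement is never ambiguous.
* The tensor model is single-compartment; no preprocessing (motion, eddy,
  registration, skull stripping) is included — inputs are assumed clean.
* Cohort volumes are grade-independent by design (see above).
* Per-replicate Spearman estimates at n = 112 have a sampling SD near 0.09,
  so individual replicates scatter around the copula targets even though
  replicate means recover them closely; recovery statements in this package
  are about means unless stated otherwise.
* The paired hemispheric contrast at the calibrated parameters is
  underpowered (≈ 0.66), faithfully reflecting the configured effect size;
  it is not a defect of the paired test implementation.
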