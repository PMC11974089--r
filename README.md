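# alpsdti

Gliomas disturb the brain's fluid housekeeping: the glymphatic system —
cerebrospinal fluid (CSF) flowing along perivascular spaces and exchanging
with interstitial fluid — can be impaired by tumor growth, and that
impairment shows up both as peritumoral edema (PTBE) and as altered water
diffusion along the perivascular axis. `alpsdti` implements the imaging and
statistical pipeline used to study this in glioma/control cohorts, built
around the **DTI-ALPS index** (diffusion tensor image analysis along the
perivascular space):

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

At the level of the lateral ventricles, the perivascular spaces of the
medullary veins run left–right (x), projection fibers run
superior–inferior (z), and association fibers run anterior–posterior (y).
`Dxx_proj` and `Dxx_assoc` are the scanner-frame x-axis diffusivities in
small volumes of interest placed on the projection and association fiber
regions; `Dyy_proj` and `Dzz_assoc` are the diffusivities perpendicular to
both the fibers and the perivascular axis in the same VOIs. An isotropic
medium gives ALPS = 1; the more freely water moves along the perivascular
direction, the higher the index, so lower values indicate glymphatic
impairment.

The package provides, end to end:

* **Phantom simulation** — Stejskal–Tanner forward modeling
  (`S = S0·exp(−b·gᵀDg)`) on a block-geometry ventricle-level slab with
  projection/association fiber bands, an adjustable perivascular
  diffusivity multiplier `alpha`, optional tumor + PTBE spheres, and Rician
  noise (`phantom_spec()`, `synthesize_dwi()`).
* **Tensor fitting** — voxelwise log-linear least squares (OLS, or WLS with
  one predicted-signal² reweighting), FA/MD/direction-encoded color maps
  (`fit_tensor()`, `scalar_maps()`).
* **ALPS computation** — 2×2-voxel single-slice VOIs (four per subject,
  per the classical prescription), automatic placement on phantom label
  masks, per-hemisphere and bilateral-mean indices with
  tumor-side/contralateral labeling (`alps_voi()`, `auto_alps_vois()`,
  `alps_index()`, `subject_alps()`).
* **Volumetrics** — CSF/tumor/PTBE volumes in cm³ from integer label masks
  (`label_mask()`, `mask_volume()`, `subject_volumes()`).
* **Cohort simulation** — a Gaussian-copula generator reproducing a
  published glioma/control group structure: Gaussian ALPS and CSF marginals,
  log-normal tumor/PTBE/Ki-67 marginals parameterized from medians and
  IQRs, a paired hemispheric ALPS model, and standardized grade/age/Olig-2
  effects (`cohort_spec()`, `simulate_cohort()`).
* **Statistics** — the full battery: Shapiro–Wilk normality gating, Student
  t / Wilcoxon rank-sum, one-way ANOVA + LSD / Kruskal–Wallis + Dunn,
  paired t, Pearson chi-square, Spearman correlation matrices, and a
  two-stage univariate-screen-then-multivariable regression with
  standardized β (`cohort_report()`, `regression_screen()`, …).
* **Orchestration** — `run_pipeline()` executes phantom → fit → ALPS →
  volumes → cohort → report with an MD5 manifest for reproducibility; a
  thin CLI lives at `inst/scripts/alps-pipeline.R`.

Intended users are neuroimaging methods researchers who want a tested,
self-contained reference implementation of the DTI-ALPS analysis chain, and
statisticians who need a calibrated simulator of this kind of cohort.

## Worked example

```r
library(alpsdti)

# A noisy phantom with glymphatic impairment (alpha = 0.8) on the left
gtab    <- make_gradient_table(48, b = 1000, n_b0 = 1, seed = 7)
spec    <- phantom_spec(shape = c(32, 32, 8), snr = 30,
                        alpha = c(left = 0.8, right = 1.0), seed = 11)
phantom <- synthesize_dwi(spec, gtab)
tensors <- fit_tensor(phantom, method = "wls")
subject_alps(tensors, auto_alps_vois(phantom$labels), tumor_side = "left")
#> ALPS index: left = 1.167, right = 1.391, bilateral mean = 1.279
#>   tumor side (left) = 1.167, contralateral = 1.391
```

The noiseless index would be `1.4 * alpha` per hemisphere (1.12 left, 1.40
right): the fitted values recover the simulated left-sided impairment, with
small noise-driven deviations.

```r
# A simulated cohort at the default (study-calibrated) parameters
cohort <- simulate_cohort(cohort_spec(seed = 1))
report <- cohort_report(cohort)
print(report$comparisons[["alps_mean.group"]])
#> alps_mean: control = 1.355 ± 0.164 vs glioma = 1.247 ± 0.248
#>   Student t test: statistic = 2.952, p = 0.00361 (n = 56/112)
print(report$regression)
#> Regression screen for alps_mean (entry alpha = 0.05)
#> Univariate:
#>   term         b    beta         p   n
#>  grade -0.184332 -0.3465 0.0001824 112
#>    age -0.005223 -0.2623 0.0052160 112
#>  olig2 -0.002511 -0.2115 0.0251608 112
#> Multivariable (grade, age, olig2):
#>   term        b    beta         p   n
#>  grade -0.18001 -0.3383 0.0001981 112
#>    age -0.00420 -0.2109 0.0174307 112
#>  olig2 -0.00343 -0.2889 0.0010205 112
```

In this replicate the glioma group has a lower mean ALPS index than
controls (1.247 vs 1.355), and higher tumor grade independently predicts a
lower index — the structure the generator is calibrated to produce.

A full pipeline run (phantom, maps, VOIs, volumes, cohort, report,
manifest) from a config file:

```sh
Rscript inst/scripts/alps-pipeline.R \
  --config inst/extdata/demo-config.yaml --out demo-run
```

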