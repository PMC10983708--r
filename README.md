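# bullseyeWMH

Regional analysis of white matter hyperintensities (WMHs) in R.

WMHs — the bright lesions on FLAIR MRI that accompany ageing, small-vessel
disease and Alzheimer's pathology — are usually reduced to one global
volume. Their *spatial pattern* is more informative: periventricular, deep,
posterior and subcortical grey-matter lesion burdens have different risk
factors and different cognitive consequences. `bullseyeWMH` implements the
full regional analysis chain for researchers working with lesion masks and
covariate tables:

* **Bullseye parcellation** of the cerebral white matter: a normalized
  ventricle-to-cortex depth map
  `d(v) = d_vent(v) / (d_vent(v) + d_cort(v))` cut into 4 equidistant
  layers, crossed with 8 lobar sectors and the basal ganglia + thalamus
  (BGT), plus anterior/posterior corpus callosum — 38 parcels
  (9 regions × 4 layers + 2 CC).
* **Lesion volumetry** per parcel (ml), with exact volume conservation and
  anisotropic voxel support.
* **Correlated PCA**: per-parcel volumes are log-transformed
  (`log(V + 0.01)`), z-scored and decomposed by PCA followed by an oblique
  **oblimin (quartimin) rotation** via gradient projection, so the spatial
  components may correlate; regression-method component scores, Tucker
  congruence and component alignment utilities included.
* **Association models**: tiered (unadjusted / age-adjusted / fully
  adjusted) linear models of component scores on comorbidities, cognition
  models with **amyloid × component interactions** (likelihood-ratio test,
  adjusted-R² gain), Huber-robust refits with sandwich CIs, Wilcoxon/χ²
  group tests, and a comorbidity-count analysis stratified by hypertension.
* A **synthetic-data module**: analytic anatomy phantoms, planted spatial
  lesion patterns and simulated cohorts with known ground truth, so every
  stage has a quantitative planted-recovery test.

## Worked example

Simulate a study of 300 subjects on the default 64³ phantom, fit the
four-component correlated PCA, and check recovery of the planted patterns:

```r
library(bullseyeWMH)

sim <- simulate_wmh_study(n_subjects = 300, seed = 42)
median(sim$volumes$total_volume)   # a few ml — the usual cohort scale
#> [1] 3.2305

fit <- wmh_pca(sim$volumes, k = 4)
fit
#> Oblimin-rotated PCA of parceled WMH volumes
#>   300 subjects, 38 parcels, 4 components (oblimin rotation)
#>   variance explained (structure-based): C1 36.6%, C2 29.4%, C3 22.0%, C4 10.1%

# align fitted components with the planted templates
al <- align_components(fit, template_parcel_profiles(sim$templates))
round(al$congruence, 3)
#> [1] 0.991 0.997 0.964 0.989

round(fit$phi, 2)   # component correlations: lobar patterns correlate,
#>      C1   C2   C3   C4  # the BGT pattern stays nearly independent
#> C1 1.00 0.45 0.41 0.03
#> C2 0.45 1.00 0.45 0.08
#> C3 0.41 0.45 1.00 0.04
#> C4 0.03 0.08 0.04 1.00
```

The mean Tucker congruence of 0.985 says the rotation recovered all four
planted spatial patterns nearly perfectly. Downstream, the planted
hypertension effect on the deep component and the amyloid ×
periventricular interaction on episodic memory are picked up by the
association layer:

```r
sc <- fit$scores[, al$permutation] %*% diag(al$signs)
colnames(sc) <- c("posterior", "deep", "periventricular", "BGT")

fit_tiered_models(sc, sim$cohort, "hypertension", "deep")$fully_adjusted
mi <- fit_cognition_models(sc, sim$cohort, "episodic_memory",
                           "periventricular", interaction = TRUE)
```

`plot(fit)` draws the classic bullseye diagrams (one per component,
parcels shaded by loading, strict > 0.4 display rule).

A thin command-line wrapper with `simulate / parcellate / volumes /
decompose / associate / all` subcommands lives at
`inst/scripts/wmh-pipeline.R`; `run_pipeline()` is the programmatic
equivalent and writes CSV/JSON/NIfTI outputs plus a checksummed manifest.

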