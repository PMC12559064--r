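# perfmosaic

Automated quantification of pulmonary perfusion changes on CT pulmonary
angiography (CTPA) for chronic thromboembolic pulmonary hypertension (CTEPH).

Mosaic perfusion — patchy hyperemic and oligemic lung with centralized
perfusion — is normally graded by radiologists on ordinal scales, which is
subjective and variable. `perfmosaic` computes three reproducible per-patient
measurements from a CTPA volume and externally supplied segmentation masks
(left lung, right lung, pulmonary veins; the package consumes masks, it does
not segment):

1. **Compartment proportions.** A three-component Gaussian mixture
   `p(x) = Σₖ πₖ N(x | μₖ, σₖ²)` is fitted to the pooled both-lung
   attenuation histogram by variational Bayesian estimation (Dirichlet prior
   on π, Normal–Gamma on each μ, σ⁻²). Components ordered by mean map to
   oligemic / normal / hyperemic; the weights πₖ are the headline
   proportions, and the MAP classification mask gives voxel-count fractions
   for QC.
2. **Spatial-entropy heterogeneity.** For the hyperemic and normal
   compartments, the Shannon entropy (bits) of a 32×32×32 histogram of voxel
   coordinates over each lung's bounding box, averaged across lungs:
   0 bits = compact/absent, 15 bits = uniformly dispersed.
3. **Centralization slope.** From two anisotropy-aware Euclidean distance
   transforms, every lung voxel gets a relative hilum-to-pleura position
   ρ = d_hilum / (d_hilum + d_periphery) ∈ [0, 1]; mean attenuation in 21
   shells of ρ is fitted with a line. Negative slope (HU per unit ρ) =
   attenuation falling toward the periphery, the CTEPH centralization
   pattern.

A synthetic chest-phantom generator with exact ground truth, a
Gaussian-copula clinical-table simulator, and Spearman/Benjamini–Hochberg
correlation reporting (with Grubbs and D'Agostino screening) complete the
pipeline, so everything is testable without patient data.

## Worked example

Generate a phantom with severe perfusion changes (30/40/30 compartment mix,
−120 HU/unit imposed gradient) and run the full per-patient analysis:

```r
library(perfmosaic)
ph <- generate_chest_phantom(phantom_preset("severe", seed = 7))
pm <- analyze_patient(ph$volume, ph$seg, run_config(seed = 7),
                      patient_id = "demo")
print(pm$model)
#> <attenuation_model> 3-component VB Gaussian mixture
#>       label weight   mean   sd
#> 1  oligemic 0.2723 -960.9 28.7
#> 2    normal 0.4404 -845.4 41.6
#> 3 hyperemic 0.2873 -711.0 45.5
#>  fit: n=35550, 85 iterations, converged=TRUE
```

The six headline metrics:

```r
#> proportions  olig 0.272  norm 0.440  hyper 0.287
#> entropy_high 11.76 bits  entropy_medium 12.43 bits
#> slope_mean -106.6 HU/unit (left -113.1, right -100.1)
```

Reading the numbers: the fitted weights recover the generating 0.30/0.40/0.30
mix (component means sit below the generating values because the negative
radial gradient drags the whole histogram down); entropies near 12 bits say
the compartments are scattered in many patches rather than one blob; and the
strongly negative slope quantifies the imposed central hyperemia / peripheral
oligemia. A `"minimal"` phantom instead yields a dominant normal proportion
(≈ 0.90) and a slope near zero. Inner radial shells are structurally empty
(ρ cannot fall much below 0.5 when the hilar point lies outside a convex
lung), which `radial_profile()` reports via a warning; the fit uses the
occupied outer shells.

On real data, replace the phantom with paths:

```r
pm <- analyze_patient("ct.nii.gz", "seg.nii.gz", run_config(seed = 1),
                      patient_id = "P001", out_json = "P001.json")
```

and batch cohorts with `analyze_cohort(manifest, config)`. Correlate cohort
metrics against clinical variables with `correlation_report()`; the heatmap
(`plot_correlation_heatmap()`) masks pairs that do not survive the
Benjamini–Hochberg correction and the report header carries the data-derived
critical p-value.

A thin CLI wraps the same functions
(`inst/cli/perfmosaic analyze|cohort|phantom|clinical-sim|correlate`).

## Vignette

`vignettes/perfusion-quantification.Rmd` documents the model and its
assumptions, the parameter defaults and why, the phantom's design (and what
it does not emulate), numerical tie-breaks and degenerate-input rules, and
known limitations.
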