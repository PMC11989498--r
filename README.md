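# shadowtex

Texture analysis of posterior acoustic shadows in B-mode ultrasound.

Kidney and gallbladder stones appear on ultrasound as bright (hyperechoic)
foci with a dark posterior acoustic shadow. When the shadow is faint,
diagnosis is uncertain: readers assign diagnostic-probability classes
(50–60%, 60–80%, ≥80%) rather than a verdict. `shadowtex` quantifies the
shadow itself. An operator-placed rectangular ROI on the shadow band is
cropped to a patch; a gray level co-occurrence matrix (GLCM) $p(i,j)$ —
the joint distribution of gray-level pairs at a fixed pixel offset — is
built from the patch; and four second-order descriptors are computed:

- contrast $\sum_{i,j}(i-j)^2 p(i,j)$
- correlation $\sum_{i,j}(i-\mu_i)(j-\mu_j)p(i,j)/(\sigma_i\sigma_j)$
- energy $\sum_{i,j}p(i,j)^2$
- homogeneity $\sum_{i,j}p(i,j)/(1+|i-j|)$

Per class, each descriptor is summarised with its mean and 95% Student-t
confidence interval; a descriptor distinguishes the classes when the
three bands are pairwise disjoint (`separation_report()`). A seeded
speckle phantom generator (Rayleigh envelope + log compression, a
hyperechoic stone, a tunable shadow band) lets the whole pipeline run and
be tested without clinical data, and `clinical_reference()` ships the
published per-class reference bands for a 118-image clinical cohort.

## Worked example

```r
library(shadowtex)

# one phantom with a strong shadow, and its shadow-band ROI
ph <- generate_phantom(phantom_params(shadow_attenuation = 0.25,
                                      shadow_smoothing = 0.3), seed = 42)
patch <- extract_patch(ph$image, ph$roi, label = ">=80", disease = "kidney")
glcm_features(patch$pixels)
#> GLCM texture descriptors (204 x 59 patch, 256 levels, 1 offset, asymmetric)
#>     contrast  correlation       energy  homogeneity
#>  3.84205e+02 -1.25797e-02  4.78913e-04  1.24870e-01
```

Contrast in the hundreds, energy of order 10⁻⁴ and homogeneity near 0.1
are the magnitudes expected at 256 gray levels on shadow patches of a few
thousand pixels. A full synthetic cohort (14/23/15 kidney images across
the three classes, the clinical cohort sizes):

```r
cfg <- run_config(mode = "synthetic", out_dir = tempfile(), seed = 1,
                  diseases = "kidney", plots = FALSE)
res <- run_analysis(cfg)
subset(res$summaries, feature == "contrast")
#>   disease  feature label  n      mean    ci_low   ci_high
#> 1  kidney contrast 50-60 14 3426.3695 3399.7519 3452.9871
#> 2  kidney contrast 60-80 23 1511.9779 1502.8485 1521.1074
#> 3  kidney contrast  >=80 15  376.6771  373.5038  379.8504
res$report
#>  disease     feature separated   ordering
#>   kidney    contrast       yes decreasing
#>   kidney correlation        no increasing
#>   kidney      energy       yes increasing
#>   kidney homogeneity       yes increasing
```

Mean contrast falls strictly as the shadow strengthens and the three
confidence bands are pairwise disjoint, while correlation stays near zero
with overlapping bands — the same qualitative pattern the clinical
reference bands show (`separation_report(clinical_reference())`).

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","shadowtex.R",package="shadowtex"))')" \
    run-all --seed 1 --out out/
```

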