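# macfshape

Detection of multiple sclerosis (MS) from macular OCT by **functional-shape
(F-shape) analysis** of the ganglion cell–inner plexiform layer (GCIPL).

MS thins the macular GCIPL, concentrated in a horseshoe-shaped region
around the fovea. Sectoral methods (the ETDRS nine-sector grid) average
thickness over large regions and lose this spatial detail. `macfshape`
instead treats each eye as a *functional shape*: a triangulated patch of
the inner limiting membrane (ILM) surface `X` carrying the pointwise GCIPL
thickness as a signal `f`. A cohort of F-shapes `(X_i, f_i)` is registered
to a common mean template `(X_m, f_m)` by minimizing

```
J = γ_f ||f_m||²_L² + Σ_i [ H(X_m, p_i) + γ_ζ ||ζ_i||²_L² + γ_w A(X̃_i, f̃_i, X_i, f_i) ]
```

over the template and the per-subject transformations — momenta `p_i`
parameterizing a kernel diffeomorphic deformation by geodesic shooting
(`H = p'K(X)p` is the deformation energy), and signal increments `ζ_i`
(`f̃_i = f_m + ζ_i`). `A` is a functional-varifold dissimilarity: a
correspondence-free squared kernel norm combining a Gaussian kernel on face
centroids, the squared cosine between face normals, a Gaussian kernel on
face signals, and face areas. The **residual thickness** `f_m − f̃_i` on
the common template mesh is the classification feature: after PCA
reduction, an SVM selected by leave-one-out (LOO) grid search separates MS
from healthy eyes. An ETDRS sectoral baseline (nine sector-mean features,
same SVM machinery) is built in for head-to-head comparison.

The clinical cohort this analysis was designed around is not public, so
the package ships a synthetic generator that reproduces its statistical
structure: foveal-pit thickness topography, group means/SDs of
75.9 (6.2) µm (healthy) vs 62.9 (5.4) µm (MS) across eyes, horseshoe
thinning, smooth per-eye anatomical deformation, and measurement noise —
with ground truth for validating registration and classification recovery.

For whom: researchers working on OCT-based neurodegeneration biomarkers
who want a fully inspectable, ground-truth-validated implementation of the
F-shape pipeline, and methodologists interested in varifold-based atlas
registration on retinal surface data.

## Worked example

```r
library(macfshape)

config <- desk_study_config(seed = 1)   # 150-px lattice, ~450-vertex meshes
study  <- run_fshape_study(config)      # simulate, register, train, classify

glance(study$fit)
#> # A tibble: 1 × 7
#>   n_train n_features n_components cv_score kernel     C atlas_iterations
#>     <int>      <int>        <int>    <dbl> <chr>  <dbl>            <int>
#> 1      54        484            3    0.981 linear   0.1                4

study$test$metrics
#> <eval_metrics> n = 18 | ACC 1.000 SEN 1.000 SPE 1.000 PREC 1.000 F1 1.000 AUC 1.000

study$sectoral$metrics
#> <eval_metrics> n = 18 | ACC 1.000 SEN 1.000 SPE 1.000 PREC 1.000 F1 1.000 AUC 1.000
```

Reading the output: 54 training eyes (28 healthy + 26 MS) produced 484
residual features (the template mesh vertices), reduced to 3 principal
components by the scree rule; LOO grid search picked a linear SVM whose
cross-validation score was 0.981; on the 18 held-out eyes (9 + 9) both the
F-shape classifier and the sectoral baseline are perfect at this effect
size (a 13 µm group gap against ~6 µm between-eye SD is an easy problem
when anatomy is mild — the F-shape advantage shows up in the
pointwise-significance comparison below and under stronger anatomical
variability).

```r
autoplot(study$fit$atlas)        # objective trace of the atlas estimation
autoplot(study$fit$pca)          # scree curve
autoplot(study$test$metrics)     # ROC of the held-out eyes

residual_significance_study(config)   # %-significant vertices, residual vs raw
```

A thin command-line front end wrapping the same functions lives at
`inst/cli/macfshape.R` (`simulate`, `train`, `classify`, `sectoral`,
`report`).

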