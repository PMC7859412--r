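# ardkit

Identification and classification of **ageing-related diseases (ARDs)**
from aggregated electronic-health-record onset counts.

An ARD is a disease whose rate of first onset rises with chronological
age (as opposed to merely concentrating in some age range). Given, for
each disease, the number of patients first recorded with it at each
integer age 21–84 ($d_x$) and the number still at risk ($l_x$), `ardkit`
grades ageing-relatedness by two independent, mutually corroborating
routes:

1. **Curve clustering.** Age-specific onset rates $q_x = d_x/l_x$ are
   standardised to unit mass, $\hat q_x = q_x / \sum_{i=21}^{84} q_i$,
   and clustered by hierarchical agglomerative clustering with a full
   model-selection procedure: linkage chosen by cophenetic correlation,
   the number of clusters by the gap statistic, and the algorithm (vs
   k-means, PAM, spectral) by the Dunn index. Clusters with ≥ 3 diseases
   are "main" clusters, numbered in descending order of their members'
   median onset ages; smaller ones are "outlier" clusters.
2. **Actuarial classification.** Each curve is fit by the Gompertz model
   $q_x = \alpha e^{\beta x}$ and an exponential-quadratic
   Gompertz–Makeham model $\log q_x = \log a + bx + cx^2$. A negative
   Gompertz slope $\beta$ means onset falls with age (very low
   likelihood of being ageing-related); otherwise the adjusted $R^2$ of
   the Gompertz–Makeham fit is banded at 0.95 / 0.90 / 0.85 / 0.80.

Because cohort-scale EHR data is access-restricted, the package includes
a synthetic cohort generator (`generate_cohort()`) that draws binomially
thinned onset counts from parametric hazard families with known
ground-truth ageing-relatedness, so the full pipeline is testable end to
end. See the vignette
(`vignettes/identifying-ageing-related-diseases.Rmd`) for the models,
conventions and limitations.

## Worked example

```r
library(ardkit)

# 5 hazard families x 20 diseases each, cohort of 1e6 at age 21
cohort <- generate_cohort(cohort_config(seed = 42))
res <- run_pipeline(cohort$counts,
                    config = pipeline_config(seed = 42, k_max = 10),
                    out_dir = "ard_run")
```

The run writes `rates.csv`, `std.csv`, `assignments.csv`, `fits.csv`,
`verdicts.csv`, `crosstab_band.csv`, `cluster_medians.csv`,
`diagnostics.json`, `manifest.json` and a plain-text summary:

```
diseases analysed: 100 (clustered: 100)
selected linkage: average
selected algorithm: hierarchical_average with k = 5 (Dunn = 1.568)
main clusters: 5, outlier clusters: 0
bands: very_high=60, band_090_095=0, band_085_090=0, band_080_085=0,
low=0, very_low_beta_negative=40
```

Model selection picked average linkage and k = 5 — the number of
generative families — and the recovered labels match the families
exactly (`adjusted_rand_index(...)` returns 1). Main clusters are
ordered by onset age:

```r
res$cluster_medians
#>   main_label  n median q25 q75
#> 1          1 20     79  79  79
#> 2          2 20     72  72  72
#> 3          3 20     64  64  64
#> 4          4 20     35  34  35
#> 5          5 20     34  33  34
```

Clusters 1–3 (late-, mid-exponential and linear-rise families, oldest
median onsets) hold all 60 very-high-band diseases; clusters 4–5 (the
declining families) hold all 40 negative-β diseases — the two routes
agree on every disease:

```r
res$crosstabs$band
#>            band
#> cluster     very_high  ...  very_low_beta_negative Total
#>   Cluster 1        20                            0    20
#>   Cluster 2        20                            0    20
#>   Cluster 3        20                            0    20
#>   Cluster 4         0                           20    20
#>   Cluster 5         0                           20    20
#>   Total            60                           40   100
```

A thin command-line wrapper is included at `inst/scripts/ardkit.R`
(`simulate`, `rates`, `classify`, `run` subcommands).

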