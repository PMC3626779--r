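# icascade

Tools for testing the **inhibitory cascade (IC) model** of mammalian lower
molar development on genus-level tooth measurements — from raw
length/width tables to morphospace classification, reduced major axis
regression, the m2-share test, size-proxy correlations, and permutational
MANOVA of diet and phylogeny clustering. A seeded synthetic-data generator
simulates taxa under the cascade so the entire pipeline can be exercised
and validated without any external data.

## The model

Lower molars develop sequentially from front to back, and the size of each
developing molar reflects the balance *a* between a mesenchymal activator
and inhibition from the adjacent anterior molar. Because the effect is
cumulative along the row, relative occlusal areas follow

    (m1, m2, m3)  ∝  (1, a, 2a − 1),

with m3 lost when *a* ≤ 1/2. Two macroevolutionary predictions follow:

1. In the morphospace with axes *x* = m2/m1 and *y* = m3/m1 (occlusal
   areas, each estimated as maximum length × maximum width), taxa lie in
   the region where m2 is intermediate in size; under the strict cascade
   they fall on the line *y* = 2*x* − 1.
2. m2 occupies exactly one third of the total lower molar area,
   since a / (1 + a + 2a − 1) = 1/3 for every a ≥ 1/2.

The package tests prediction 1 by classifying each genus against the
predicted region and fitting a reduced major axis (RMA) regression — slope
sign(r)·s_y/s_x, appropriate when both axes carry error — whose 95%
confidence intervals are compared with the theoretical (slope 2, intercept
−1). Prediction 2 is tested with a two-tailed one-sample t test of genus
mean m2 shares against 100/3 %. Clustering of dietary guilds and higher
taxonomic groups in the morphospace is quantified with a one-way
PERMANOVA (Euclidean distance, pseudo-F assessed by label permutation).

## Worked example

Simulate a 132-genus dataset in which two archaic-ungulate-like groups
carry an m2 bulge (deviating from the cascade), then run the full
analysis:

```r
library(icascade)
sim <- simulate_dataset(sim_scenario("condylarth", seed = 42))
an  <- run_analysis(sim$measurements, sim$metadata, seed = 42, n_perm = 999)
an
#> Inhibitory cascade analysis
#>   128 genera (119 with both ratios) from 184 kept specimens
#>   regions: 89 intermediate / 21 m2-largest / 9 m2-smallest (74.8% predicted)
#>   RMA: slope 1.843 [1.739, 1.953], intercept -0.9454 [-1.098, -0.7925]
#>   mean m2 share 34.52% (t = 4.56, df = 118, p = 1.26e-05)
#>   PERMANOVA:
#>     phylogeny        n = 119, df = 24, F =  12.161, R2 = 0.756, p = 0.001
#>     phylogeny (5+)   n =  86, df =  8, F =  27.375, R2 = 0.740, p = 0.001
#>     diet             n = 119, df =  5, F =  19.022, R2 = 0.457, p = 0.001
#>     diet (reduced)   n = 119, df =  5, F =  19.022, R2 = 0.457, p = 0.001
```

Reading the output: of the 132 simulated genera, 2 lost m3 (a ≤ 1/2) and
were excluded by the three-molar rule, 10 specimens lacked an adjacent
molar pair, and missing measurements removed m3 ratios from a few more
genera, leaving 119 plotted in the morphospace (the exclusion log in
`an$exclusions` itemises every drop). The m2-bulge groups
populate the m2-largest region (21 genera), pulling the percentage inside
the predicted region down to 74.8% and the mean m2 share above one third
(34.52%, significantly different from 33.33%). Diet tracks the
activator/inhibitor balance in the generator, so diet clustering is strong
(R² = 0.46). The RMA slope (1.84) sits below the theoretical 2 — partly the
bulge groups, partly attenuation from measurement error (see the methods
vignette).

Individual stages are ordinary functions returning classed objects:

```r
fit <- fit_rma(an$records$x, an$records$y)
summary(fit)
#> Reduced major axis regression (analytic CIs, 95%)
#>   n = 119, r = 0.9486
#>   slope     1.843  [1.739, 1.953]
#>   intercept -0.9454  [-1.098, -0.7925]
#>   r^2 = 0.8998
#>   vs cascade line (slope 2, intercept -1): significantly different
```

`write_report(an, "report/")` writes the genus records, exclusion log,
the four result tables, region summary, convex hulls and a key-value
summary as full-precision TSVs. `plot(an)` draws the morphospace with the
predicted and fitted lines. A thin command-line wrapper with `run`,
`simulate` and `recover` subcommands ships in `inst/cli/icascade`.

Real data enter through two CSVs: a long-format measurement table
(`specimen_id,genus,tooth,length,width,source`) and a genus metadata table
(`genus,group,diet,isolated_only,molar_count`); see
`inst/extdata/demo_*.csv` for small examples.

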