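---
title: "Methods: testing the inhibitory cascade on molar proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the inhibitory cascade on molar proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icascade)
```

## The model and its two predictions

The inhibitory cascade describes sequential lower molar development: each
molar bud's growth is set by the balance `a` between a mesenchymal
activator and inhibition from the molar immediately anterior, and the
effect accumulates along the row. Relative occlusal areas are then
`(1, a, 2a - 1)`, so in the area-ratio morphospace `x = m2/m1`,
`y = m3/m1` every strictly cascade-governed taxon sits on the line
`y = 2x - 1`, and m2 is never the largest or the smallest tooth. Because
`a/(1 + a + 2a - 1) = 1/3` for every `a >= 1/2`, the cascade also pins
m2 at exactly one third of total molar area — an algebraic identity of
the model, which is why `m2_share_test()` uses exactly `100/3` percent
rather than a rounded 33% or 33.33%.

Allowing equality, the admissible ("predicted") region is
`min(1, y) <= x <= max(1, y)`. `classify_region()` therefore defines the
two violation regions by strict inequalities (`x > 1` and `y < x` for
m2-largest; `x < 1` and `y > x` for m2-smallest) and assigns every
boundary case — including three equal molars at `(1, 1)` — to the
predicted region. This boundary rule keeps an exact invariant: cascade
points are classified as predicted for *every* `a >= 0`, including the
degenerate `y = 0` (m3 lost) and `x = y = 0` (only m1) corners, which is
also why the classifiers accept zero ratios. On real-valued data the
boundary set has measure zero, so the rule costs nothing; the
`tol` argument (default 0) exposes the sensitivity of region counts to a
tolerance band as a diagnostic.

## From measurements to the morphospace

Occlusal area is estimated as maximum length × maximum width per tooth;
a tooth missing either dimension has no area, and length is never used
as an area proxy. The inclusion rules mirror standard practice for
fossil material: specimens need at least one adjacent molar pair with
both areas ((m1, m2) or (m2, m3)); taxa known only from isolated molars
are removed (intraspecific variation cannot be controlled); taxa with
fewer than three molar positions are removed. Ratios are computed per
specimen and then averaged per genus — the mean of ratios, not the ratio
of mean areas; the two differ under noise, and the per-specimen ratio is
the quantity with the biological interpretation. Each downstream
statistic reports its own N, because a genus can have `x` without `y`
(m3 unmeasurable) and still inform the m2/m1 analyses; the pipeline
never forces a single sample size.

## Reduced major axis regression

Both morphospace axes are ratios of measured quantities, so error is
symmetric between them and ordinary least squares (which attributes all
error to `y`) would be biased as a line estimator. The RMA slope is
`sign(r) * s_y / s_x` (the `n - 1` denominators cancel in the ratio) and
the intercept `ybar - b * xbar`. The analytic slope interval is the
standard SMA interval `b * (sqrt(B + 1) -/+ sqrt(B))` with
`B = F(1 - alpha; 1, n - 2)(1 - r^2)/(n - 2)`. For the intercept we use
the SMA elevation standard error,
`sqrt(s_res^2 / n + xbar^2 * SE(b)^2)` with
`s_res^2 = s_y^2 (1 - r^2)(n - 1)/(n - 2)`, on a t distribution with
`n - 2` df — the form used by allometry software; the design was open
here, and we prefer it to propagating slope endpoints because it has a
single defensible sampling model. A case-resampling percentile bootstrap
(`ci = "bootstrap"`, >= 999 replicates, mandatory seed, degenerate
resamples redrawn with a capped retry count) is available as a
cross-check; on well-behaved data the two agree closely (tested). A
perfect fit (`r^2 = 1`) returns zero-width intervals with a flag rather
than an error, since noiseless cascade data are a supported input.

Two fitted lines are compared by 95% CI overlap, parameter by parameter;
theoretical values have zero-width intervals, so comparison against the
cascade reduces to containment. This is deliberately the coarse
published-table criterion, not a formal two-sample test.

## From-scratch statistics

The Spearman correlation assigns midranks to ties, takes rho as the
Pearson correlation of rank vectors, and reports
`S = (1 - rho)(n^3 - n)/6`, which equals the classical sum of squared
rank differences when ties are absent and matches standard printed
output under ties. The p value uses the t approximation on `n - 2` df.
The one-sample t test is the textbook statistic; a zero-variance sample
(which noiseless cascade shares produce, all exactly 1/3) yields
`t = 0, p = 1` when the mean equals the reference (judged at floating
tolerance) and a flagged infinite t otherwise.

The one-way PERMANOVA partitions squared Euclidean inter-point
distances: `ss_total = (1/n) sum_{i<j} d^2`, within-group sums weighted
`1/n_g`, pseudo-F from the mean squares, `R^2 = ss_between/ss_total`.
Euclidean distance is the right dissimilarity here because the
morphospace is a plain 2-D real plane (abundance-style dissimilarities
like Bray-Curtis have no meaning for area ratios). The permutation p
value uses the `+1` correction, `(#{F* >= F} + 1)/(n_perm + 1)`, is
bit-reproducible given the seed, and an exhaustive-enumeration mode
(`exact = TRUE`, n <= 9) exists for oracle testing. For points in
Euclidean space the distance form equals the centroid form of the sums
of squares, which is what the permutation loop computes (a `rowsum` per
relabelling), keeping 1000-replicate type-I simulations cheap. The
pipeline runs four groupings: all taxonomic groups; groups with at least
five genera after pooling Carnivora with Creodonta and Primates with
Plesiadapiformes; diet; and diet with a configurable outlier list
removed. A grouping that degenerates on a small dataset (fewer than two
usable groups) is reported as skipped rather than failing the run.

## What the generator simulates — and what it does not

`simulate_dataset()` draws, per genus, a balance `a` from its group's
truncated normal (truncation at 0 by redraw, capped); a lognormal m1
area (default meanlog `log(15)`, sdlog 1 — spanning shrew-sized to large
ungulate molars); true areas from the cascade; and per specimen factors
each tooth's area into length × width via a per-tooth aspect-ratio draw
(default 1.40 ± 0.15, lower molars longer than wide). Measurement noise
is multiplicative lognormal with mean 1 and CV 5% on *each dimension* —
noise is placed on what is actually measured, so areas inherit
correlated noise (CV about 7%) and ratios about 10%, with the shared m1
denominator correlating the two axes' errors exactly as in real ratio
data. Tooth rows are deleted at 5%. A truncated normal, rather than a
lognormal, keeps `a` symmetric about 1 so that equal molars are a
natural centre, matching the observation that basal taxa sit at the
middle of the morphospace. Genera drawn with `a <= 1/2` genuinely lack
m3 and carry `molar_count = 2`, so the standard filter removes them —
the generator exercises the paper-trail of exclusions rather than
sidestepping it.

The default layout has 132 genera in 25 groups whose sizes mirror a
broad mammalian sample (17 artiodactyls down to single-genus stem taxa;
after pooling, the five-or-more analysis covers exactly 10 groups and
101 genera), with group means of `a` running from 0.65 (carnivorans)
to 2.0 (artiodactyls) so that diet tracks the balance as the cascade
literature predicts. Specimens per genus are uniform on {1, 2},
reflecting that most fossil genera contribute a single usable specimen.
Three scenarios are bundled: `conforming` (strict cascade),
`condylarth` (an m2 bulge of +30%/+25% on two archaic-ungulate-like
groups, which lands most of their genera in the m2-largest region — the
bulge condition `(1 + delta) a > max(1, 2a - 1)` is solved analytically
in the tests), and `null_diet` (diet labels permuted, severing the
diet-morphospace link for type-I simulations).

Features of real data the generator does *not* emulate: phylogenetic
autocorrelation (no tree, no signal along it), biological scatter off
the cascade line within conforming groups (real mammalian data show
r ≈ 0.6 about the RMA line; simulated conforming data are far tighter,
r ≈ 0.98), asymmetric missingness (real m3 measurements are missing far
more often than m1), and literature-vs-photo source heterogeneity.
Passing recovery tests therefore demonstrate correctness of the
estimators under the cascade's own assumptions, not robustness to every
feature of survey data.

## Numerical and reproducibility choices

All tables are written as TSV with numerics at 17 significant digits, so
write/read round-trips are bit-exact and reports are byte-identical
under a fixed seed. `run_analysis()` derives one sub-seed per PERMANOVA
from its master seed; the simulator consumes its own seed; the reported
provenance block carries the seed, a configuration fingerprint and the
package version. Degenerate inputs error early and name offenders:
unknown tooth labels, non-positive dimensions, duplicate
(specimen, tooth) pairs, specimens claimed by two genera, genera missing
from metadata (with an opt-in permissive mode that assumes three
non-isolated molars and warns — silent guessing of diet or group would
corrupt the clustering analyses, so those are never defaulted).

## Problem sizes and known limitations

The recovery simulations use 200 replicates of the 132-genus design at
5% CV for slope bias and CI coverage, and 1000 replicates at 199
permutations for the PERMANOVA type-I rate; the acceptance script uses
50 replicates for its recovery summary. These sizes give Monte-Carlo
standard errors of about 0.004 on the mean slope and 0.007 on the
type-I rate.

One limitation deserves emphasis. With truth exactly on the cascade line
plus multiplicative measurement error on both coordinates, the RMA slope
estimator is *attenuated*: it converges to
`sqrt((4u + e_y)/(u + e_x))` rather than 2, where `u` is the variance of
`a` across genera and `e_x`, `e_y` are the ratio error variances. At the
default conditions the bias is small (about -0.03, well inside the
recovery simulation's ±0.05 check) but not negligible relative to the
sampling error at n ≈ 130 — and the analytic CI, whose width shrinks as
the error-correlation inflates r, does not account for it. The coverage
of the theoretical slope 2.0 measured by the recovery simulations is
therefore well below the nominal 95% (around 0.75–0.80 at these
conditions). This is a structural property of moment-based RMA under
errors-in-variables, not an implementation defect: coverage approaches
the nominal level only as the morphospace spread grows much larger than
the measurement noise. Analyses of real data should treat the analytic
CI as an in-sample descriptive band, not a calibrated frequentist
interval for the developmental parameters; a measurement-error-corrected
estimator is out of scope here, as is any phylogenetically corrected
regression (both need inputs — error models, a resolved tree — that the
measurement tables alone do not provide).
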