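---
title: "Partial triadic analysis of tree-ring datacubes: model and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial triadic analysis of tree-ring datacubes: model and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data and the question

A ring-microdensity survey of a mapped stand produces a three-way array
$X_{ijt}$: trees $i = 1 \dots n$, ring descriptors $j = 1 \dots p$, years
$t = 1 \dots T$. The descriptors bundled by default are the 11 standard
microdensity codes (RW, LW, RD, ED, LD, MID, MAD, Co, RSD, ESD, LSD):
widths, mean densities of the whole ring and of its earlywood/latewood
parts, density extremes and contrast, and within-ring density standard
deviations. Two complementary questions can be asked of such a cube: does
the stand have a *spatial* structure of wood properties that persists
across years, and do the trees share a *temporal* trajectory? Partial
triadic analysis answers both by slicing the cube into a stack of $K$
two-way tables — one $n \times p$ table per year ($K = T$), or one
$T \times p$ table per tree ($K = n$) — and extracting what the tables
have in common.

## The three PTA steps as implemented

**Standardization.** Every column of every table is centered and scaled
*within its table*. This is what makes the method compare structures: a
year with uniformly wide rings and a year with narrow rings can still carry
the same between-tree pattern. The scale is the population standard
deviation (denominator $1/n$), the convention of the duality-diagram
software lineage of the method; under it each standardized table has
squared Frobenius norm exactly $np$, which makes the mean-correlation and
RV variants of the inter-table coefficient coincide (a tested identity).
A $1/(n-1)$ switch is exposed (`denom = "sample"`). Zero-variance columns
are an error by default (`constant = "fail"`); the `"drop"` policy removes
the descriptor from *every* table, with a warning, so the stack stays
conformable.

**Interstructure.** The vectorial correlation between two standardized
tables is, by default, the mean of the $p$ per-descriptor column
correlations (`method = "mean_cor"`); the normalized-Frobenius variant
$\langle X_k, X_l\rangle / (\lVert X_k\rVert\,\lVert X_l\rVert)$ is
available as `method = "rv"`. The $K \times K$ matrix $R$ is decomposed by
a *non-centered* PCA, i.e. a plain symmetric eigendecomposition: no row or
column centering, so the first eigenvector captures the overall agreement
among tables rather than contrasts around their mean. Table scores on
component $m$ are $\sqrt{\lambda_m}\,u_m$; the square-root-of-eigenvalue
scaling is this package's convention for the typology plot (the choice is
not dictated by the method and is recorded here rather than asserted as
canonical). Compromise weights are the first-eigenvector entries with the
majority-positive sign convention (ties broken toward a nonnegative first
entry); if some entries are still negative — possible under `mean_cor`
when some inter-table correlations are negative — they are floored at zero
with a warning, because the compromise must be a convex combination, and
the vector is renormalized to sum 1.

**Compromise.** $C = \sum_k \alpha_k X_k$. Because each $X_k$ is
column-centered and the weights sum to one, $C$ is column-centered; this
is *verified at run time* (tolerance $10^{-8}$) instead of silently
re-centered, so an inconsistent stack is caught rather than patched. The
PCA of $C$ is its SVD with uniform row weights $1/n$; inertia percentages
are squared-singular-value shares (scale-free, so the row-weight
convention does not affect them). Row scores are principal coordinates
$U D$; descriptor loadings are correlations between the columns of $C$ and
the score axes, so they live in $[-1, 1]$ and draw a correlation circle.
An optional `rescale` flag re-standardizes the columns of $C$ before
decomposition; it is off by default — the compromise columns keep the
relative strengths the averaging gave them. Axis signs are fixed by a
deterministic rule: the descriptor with the largest-magnitude loading on
an axis loads positively. PCA signs are arbitrary; reproducible output
requires *some* rule, and this one keeps the dominant descriptor readable.

**Intrastructure.** Rows of each table are projected on the unit variable
axes of the compromise PCA, $X_k V$; descriptors of each table are
projected as correlations with the unit score axes. The normalizations
were chosen against an internal anchor: a table equal to the compromise
must reproduce the compromise's own row scores and loadings exactly (a
unit test enforces this). The 95% envelope takes, for each date, the
empirical 0.025 and 0.975 quantiles of the projected tree coordinates on
axis 1, using linear interpolation of order statistics (quantile type 7 —
the default of the method's software environment; outlier counts are
sensitive to this, so the type is pinned and exposed). "Outside" is
*strict* inequality, so an all-equal degenerate set flags nothing. In the
by-year orientation the trees within a date are the rows of one table
(`across = "rows"`); in the by-tree orientation they are spread across
tables at a fixed row, so the pipeline computes the same per-date envelope
with `across = "tables"`. In both orientations the reported counts are per
tree: on how many dates did this tree escape the common model. With $r$
values per quantile group, the type-7 construction leaves at most
$5\% + 2/r$ of them strictly outside — the tested invariant.

## Moran's I correlogram

Distance classes default to equal-width bins from 0 to the maximum
inter-tree distance, the count set by Sturges' rule on the number of pairs
$P = n(n-1)/2$ (explicit breaks override; classes under 20 pairs are
flagged unreliable but still tested). For a class with binary weight
matrix $W$, $I = (n/\!\sum w)\,\sum_{h \ne i} w_{hi} z_h z_i / \sum z_i^2$
with $z$ the centered values; under exchangeability $E[I] = -1/(n-1)$.
Inference is by random permutation of the values over the points: one
seeded stream, the *same* shuffles for every class (so the class-wise
statistics are comparable across classes), two-sided add-one p-values
$p = (1 + \#\{|I^\ast - E| \ge |I_{obs} - E|\})/(n_{perm} + 1)$, then
Holm's step-down across classes. The correlogram is globally significant
when the smallest Holm-adjusted p-value is $\le \alpha$ — equivalently
$\min_b p_b \le \alpha/m$ for $m$ tested classes.

One resolution fact matters and is easy to miss: the smallest attainable
permutation p-value is $1/(n_{perm}+1)$, so the Holm global test can fire
only if $m \le \alpha\,(n_{perm}+1)$. With 199 permutations and
$\alpha = 0.05$ that means at most 10 classes; Sturges' rule crosses that
threshold near $n \approx 45$ points. The null-calibration benchmark in
the acceptance suite therefore uses 20 points (9 classes) — not as a
tuning, but because a calibration world must be one in which the test is
resolvable at all. Published-scale runs use the default 1000 permutations,
for which the threshold is 50 classes and the issue is moot.

## The synthetic world

`simulate_cube()` generates
$X_{ijt} = a_j s_i + b_j f_t + c_j g_t + \varepsilon_{ijt}$:

* $s$ — a standardized Gaussian-process realization over uniformly placed
  trees with isotropic exponential correlation $\exp(-d/\rho)$, default
  range $\rho = 15$ m on a 95 m × 60 m plot (diagonal ≈ 112 m, the scale
  of the largest inter-tree distances in stands of this kind; an
  exponential range of 15 m yields patches of roughly 30–40 m, matching
  the phenomenology the method is meant to detect). If the covariance
  factorization fails the generator falls back to a sum-of-Gaussian-bumps
  field, with a warning.
* $f$ — zero except at pulse years (defaults: five defoliation-like events
  at amplitude $3\sigma$), $g$ — a standardized linear trend.
* $a, b, c$ — descriptor loading patterns chosen once to mimic the field's
  reported structures: the spatial factor loads positively on MAD, LD, RW,
  Co, RSD (dense-latewood patches); the pulse depresses growth and
  latewood density; the trend lowers ED/MID and raises LD.
* $\varepsilon$ — i.i.d. Gaussian, default $\sigma = 0.5\,\lVert a\rVert$
  (signal-to-noise 2, the level at which the recovery benchmarks are
  stated).

What a green recovery test establishes: at SNR 2 with 60 trees × 30 years,
the by-year compromise axis recovers the planted spatial factor
(median $|cor| \ge 0.9$ over 20 seeds) and three planted pulse years are
the most extreme by-tree axis-1 dates in ≥ 90% of seeds. What it does
*not* establish: behavior under heavy-tailed noise, missing rings,
cambial-age trends, or non-stationary spatial fields — none of which the
generator emulates. Note also that the default pulse and trend loading
patterns are correlated (as in real stands, where defoliation and warming
both act on latewood), so when both are active the two leading temporal
axes mix them; `recovery_metrics()` therefore reports the best axis per
factor, and the pulse benchmark runs with the trend off.

Within a by-year table the temporal terms $b_j f_t + c_j g_t$ are constant
across trees and vanish under column centering; within a by-tree table the
spatial term vanishes likewise. The two orientations are thus sensitive to
disjoint parts of the model — the property the whole design relies on, and
the reason per-table standardization (not global) is the right
preprocessing.

## Degenerate inputs and errors

Duplicate (tree, year) rows, non-numeric descriptor cells, inconsistent
embedded coordinates, and non-increasing years are hard errors at
ingestion, with the offending key or row named. Missing cells follow an
explicit policy (`fail`, the default, since the reference analysis assumes
a complete cube; `drop-tree`; `drop-year`) and dropping is always loud.
Constant columns, zero-variance value vectors, all-coincident points,
empty p-value vectors, and all-zero compromises are errors, not NaNs.
Pipeline stages re-tag errors with the stage name (`[interstructure] ...`)
so a failure in a long run is attributable.

## Design decisions that were genuinely open

* **mean_cor vs RV as the default inter-table coefficient.** The method's
  verbal definition (mean of per-descriptor correlations) and its software
  lineage (RV) differ only in normalization, and on population-standardized
  stacks they coincide exactly, so the choice is mostly moot; `mean_cor`
  is the default because it is the definitional form. The printed inertia
  percentages of the original 149-tree survey would adjudicate; that file
  is not redistributable here, so the default is recorded as
  un-adjudicated and both variants stay exposed.
* **Compromise column re-normalization** before the PCA: off by default,
  flag provided, same adjudication caveat.
* **Quantile type 7** and *strict* envelope exceedance: pinned because the
  published outlier counts are sensitive to both; exposed as parameters.
* **Two-sided class-wise permutation tests**: correlogram significance
  marking in the field is typically sign-agnostic; a one-sided flag
  exists.
* **Table-score scaling** $\sqrt{\lambda}\,u$ in the interstructure
  typology: adopted, documented as a package convention.

## Known limitations

The package deliberately implements the *partial* triadic analysis: one
global metric, uniform row weights, no table-specific metrics (full
STATIS), no Tucker/PARAFAC decompositions, no axis rotation, and no
detrending or cambial-age adjustment of the input series. The Moran
machinery covers binary distance-class correlograms only — no Geary's c,
variograms, or spatial eigenfunction methods. Coordinates are planar
meters; there is no geodesic support.
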