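# ptacube

Partial triadic analysis (PTA) of space–time tree-ring datacubes in R.

## The problem

A microdensity survey of a mapped forest stand yields, for every tree *i*,
every annual ring (year) *t*, and a set of ring descriptors *j* (ring width,
earlywood/latewood density, density contrast, …), one number
X<sub>ijt</sub>. The dataset is a genuine three-way array —
**trees × descriptors × years** — but the standard multivariate toolbox
(PCA) handles only two-way tables, so analysts usually flatten the cube and
lose either the spatial or the temporal dimension.

PTA, the simplest member of the STATIS family of k-table methods, analyzes
the cube as a stack of two-way tables X<sub>k</sub> and extracts the
structure *common* to them:

1. **Interstructure.** After centering and scaling each column of each
   table, the vectorial correlation between two tables,
   R(X<sub>k</sub>, X<sub>l</sub>) = (1/p) Σ<sub>j</sub>
   cor(x<sub>·jk</sub>, x<sub>·jl</sub>), fills a K×K matrix. Its
   non-centered PCA gives a typology of the tables; the leading eigenvector
   (nonnegative, by Perron–Frobenius when all R > 0) is renormalized into
   compromise weights α<sub>k</sub>, Σα<sub>k</sub> = 1.
2. **Compromise.** The weighted mean table
   C = Σ<sub>k</sub> α<sub>k</sub> X<sub>k</sub> summarizes the cube and is
   analyzed by PCA (inertia fractions, correlation-circle loadings, row
   scores).
3. **Intrastructure.** Each X<sub>k</sub> is projected onto the compromise
   axes as a supplementary element; per date, the 2.5%/97.5% quantiles of
   the projected tree coordinates form a 95% envelope, and trees that fall
   outside it depart from the common model.

Sliced **by year** (one trees×descriptors table per year) the compromise is
the stand's persistent spatial structure; its axis-1 tree scores are then
tested for spatial autocorrelation with a **Moran's I permutation
correlogram** (binary distance-class weights, one shared permutation
stream, two-sided add-one p-values, Holm step-down across classes). Sliced
**by tree** (one years×descriptors table per tree) the compromise is the
temporal trajectory shared by all trees — typically a high-frequency pulse
component (defoliation-type events) plus a low-frequency trend.

The package also ships a seeded synthetic-cube generator
(`simulate_cube()`) with a known spatially autocorrelated tree factor,
pulse years, and a monotone trend, so every stage of the pipeline can be
benchmarked against ground truth.

## Worked example

```r
library(ptacube)
sim <- simulate_cube(sim_config(seed = 42))   # 149 trees x 11 descriptors x 41 years
fit <- run_analysis(sim$cube, "by_year", seed = 42)
fit
#> pta_result (by_year)
#>   interstructure inertia: 25.5%, 2.4%
#>   compromise PCA inertia: 92.9%, 1.1%
#>   envelope: 49/149 units outside at least once
#>   Moran correlogram globally significant: TRUE
recovery_metrics(fit, sim$truth)
#> recovery_report (by_year)
#>         Axis1 Axis2
#> spatial 0.997 0.004
#> Moran correlogram globally significant: TRUE
```

Reading: the years agree on a common spatial structure (all inter-year
R > 0; axis 1 of the interstructure carries 25.5% of the inertia at this
noise level), the compromise's first axis is almost pure between-tree
signal (92.9% of the compromise inertia; |cor| = 0.997 with the planted
spatial factor), about the expected ~5% of tree×date projections escape
the 95% envelope, and the correlogram detects the planted 15 m-range
patchiness (positive Moran's I in the shortest distance classes, globally
significant after Holm correction):

```r
head(as.data.frame(fit$correlogram[c("class_centers", "n_pairs", "morans_i",
                                     "holm_pvalues")]), 3)
#>   class_centers n_pairs  morans_i holm_pvalues
#> 1          3.42     255 0.5188...        0.015
#> 2         10.26     731 0.2425...        0.015
#> 3         17.10     963 0.0242...        1.000
```

The by-tree orientation extracts the shared temporal trajectory instead:

```r
fitt <- run_analysis(sim$cube, "by_tree", seed = 42)
fitt
#> pta_result (by_tree)
#>   interstructure inertia: 34.5%, 1.1%
#>   compromise PCA inertia: 82.6%, 16.4%
#>   envelope: 130/149 units outside at least once
```

`export_bundle(fit, "out/")` writes every matrix as a labeled TSV plus a
JSON summary and an MD5 manifest; a thin command-line front end with verbs
`simulate`, `fit`, `correlogram`, `report` lives at
`system.file("cli", "pta.R", package = "ptacube")`.

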