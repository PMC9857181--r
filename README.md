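# immunogradient

Spatial profiling of immune-cell density across the epithelium–stroma
interface, with a survival-modeling stack for prognostic biomarker
discovery.

## The problem

In many solid tumors — hepatocellular carcinoma (HCC) is the motivating case —
the prognostic information carried by cytotoxic CD8+ T lymphocytes is not a
single bulk density but a *profile*: how density changes as one crosses from
the stroma, over the tumor edge, into the epithelium. The same is true of the
surrounding non-malignant parenchyma, where CD8+ infiltration can reflect
ongoing inflammatory damage rather than an anti-tumoral response. This package
implements a hexagonal-grid method for extracting such interface density
profiles from digital-pathology segmentation output, and the downstream
statistics that turn them into prognostic models:

1. **Hexagonal aggregation.** Cell centroids and a tissue-class label raster
   (epithelium / stroma / background) are aggregated on a flat-top hexagonal
   grid (side 65 µm, hexagon area (3√3/2)·65² ≈ 10 977 µm²) restricted to a
   pathologist-style region annotation.
2. **Interface zone.** Hexagons are labeled by majority tissue class; the
   *edge* is the set of epithelium hexagons touching stroma (rank 0). Signed
   ranks are assigned by breadth-first search — positive into epithelium,
   negative into stroma. A five-rank interface zone (IZ) is kept, with a
   three-rank central edge: compartments S = {−2}, TE = {−1, 0, +1},
   T = {+2}, re-ranked to positions 1/2/3.
3. **Indicators.** Per compartment, the mean `m` and standard deviation `sd`
   of per-hexagon CD8+ density (cells/mm²); across the profile, the center of
   mass CM = Σ position·value ⁄ Σ value ∈ [1, 3] (computed from means and
   from SDs) and the immunodrop ID = m(S)/m(T), the stromal-to-epithelial
   density ratio. Indicators are natural-log transformed for parametric
   statistics. Reported per region with prefixes `HCC_*` (malignant) and
   `Liver_*` (non-malignant), e.g. `HCC_sd_TE`, `Liver_m_T`.
4. **Survival stack.** Log-rank-optimal cutoff dichotomization for each
   continuous variable (exhaustive scan with a 10% group-size floor),
   Kaplan–Meier estimation, univariate screens, stepwise likelihood-ratio
   Cox selection (Efron ties), leave-one-out selection stability, and a
   combined 0–5 prognostic score (1 point per poor-prognosis predictor)
   stratifying patients into low (0–1) / intermediate (2) / high (3–5) risk
   tiers.

Real cohorts of this kind are rarely shareable, so the package ships a
first-class synthetic-data module: blob-shaped epithelial islands in stroma,
inhomogeneous Poisson CD8+ point patterns whose intensity is a step function
of the signed distance to the interface, and Weibull proportional-hazards
cohorts linked to known ground-truth effects. Every stage of the pipeline is
validated against this generator.

## Worked example

```r
library(immunogradient)

# a synthetic slide: epithelial blobs in stroma, CD8 intensity 200/mm^2 in
# stroma dropping to 50/mm^2 inside epithelium
tm    <- simulate_tissue_map(3000, 3000, pixel_size_um = 2.5, n_blobs = 8,
                             blob_radius_um = 330, seed = 100)
cells <- simulate_cells(tm, lambda = c(stroma_far = 200, stroma_near = 200,
                                       edge = 100, epi_near = 50, epi_far = 50),
                        band_width_um = 100, seed = 101)
ann   <- region_annotation(matrix(c(60, 60, 2940, 60, 2940, 2940, 60, 2940),
                                  ncol = 2, byrow = TRUE), "malignant")

zone <- hex_aggregate(cells, tm, ann) |> interface_zone()
compute_indicators(zone)
#> # A tibble: 1 × 10
#>   region_label   m_S  m_TE   m_T  sd_S sd_TE  sd_T  CM_m CM_sd    ID
#>   <chr>        <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 malignant     189.  98.4  44.5  125.  109.  57.5  1.56  1.77  4.25
```

The stromal aspect sits near the generative 200 cells/mm², the epithelial
aspect near 50; the immunodrop ID ≈ 4.25 recovers the 4:1 generative ratio
and CM_m ≈ 1.56 < 2 places the density mass on the stromal side — a falling
gradient into the tumor. `autoplot(zone)` draws the compartment map,
`plot_density_profile(assign_ranks(hex_aggregate(...)))` the per-rank
boxplots.

Downstream, with a cohort table (`os_months`, `os_event`, `rfs_months`,
`rfs_event` + covariates):

```r
study <- tempfile()
simulate_study(study, n_patients = 20, seed = 1)   # slides + cohort.csv
res <- run_study_pipeline(study)                   # indicators -> models -> score
res$survival$os$model                              # stepwise-LR Cox fit
res$score$strata$survival_at                       # survival by risk tier
```

Each stage writes CSV/JSON outputs and its resolved configuration under
`<study>/results`. A thin command-line wrapper with `simulate`,
`indicators`, `survival`, `score` and `run-all` subcommands is installed at
`inst/cli/immunogradient.R`.

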