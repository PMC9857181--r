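---
title: "Interface-zone immunogradient analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-zone immunogradient analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunogradient)
```

This vignette is the package's own account of the method: what is computed,
under which assumptions, which parameters matter, how the synthetic-data
generator relates to real slides, and where the design was genuinely open.

## The measurement model

The input per slide is the standard output triad of a digital-pathology
segmentation pipeline: a table of cell centroids with a marker flag (here
CD8+/CD8−), a tissue-class label raster (epithelium / stroma /
background–debris) with a physical pixel size, and one or more region
annotations (polygons labeled malignant or non-malignant). All geometry is
in micrometers with the image convention: origin top-left, y downward.

**Hexagonal aggregation.** The annotated region is tiled with flat-top
hexagons in axial coordinates, side 65 µm by default; the hexagon area is
$(3\sqrt3/2)\,s^2 \approx 10\,977\ \mu m^2$ at $s = 65$. A hexagon belongs
to the region when its *center* lies inside the annotation polygon —
fractional clipping would complicate the geometry without changing the rank
structure that drives everything downstream. Per hexagon we count CD8+
cells (point-in-hexagon by exact axial rounding) and measure per-class areas
by assigning each raster pixel center to its hexagon, so the pixel partition
tiles hexagons exactly up to rasterization error (at 0.5 µm/px the per-hexagon
area error is below 0.5%).

**Density denominator.** Per-hexagon CD8+ density is the count divided by the
*tissue* area (epithelium + stroma) in the hexagon, in cells/mm². Using
tissue rather than total hexagon area avoids diluting densities at specimen
borders where hexagons contain background. Hexagons with tissue below 10% of
the hexagon area give unstable ratios and are excluded from density profiles
(`min_tissue_fraction`, configurable). Whether the original denominator was
total or tissue area is not observable from reported values; the choice is
flagged for sensitivity analysis and is invariant for CM and ID whenever the
two denominators are proportional.

**Edge and ranks.** Each retained hexagon is labeled by majority tissue class
(ties toward epithelium — a documented convention that matters only for
exactly balanced hexagons). The *edge* (rank 0) is the set of
epithelium-labeled hexagons with at least one stroma-labeled neighbor. An
"abrupt change in class composition" rule needs a threshold; the
majority-plus-adjacency rule is parameter-free, and produces a one-hexagon-wide
edge on the epithelium side of the boundary. Taking the edge from the
epithelium side (rather than both sides) keeps it one hexagon wide; the
alternative, mixed-composition rank-0 hexagons, would shift every rank by at
most one and is reachable by reconfiguring the zone widths. Remaining
hexagons get signed ranks by multi-source breadth-first search from the edge,
restricted to each class side: epithelium $+d$, stroma $-d$. The rank field
is a graph metric (adjacent same-side hexagons differ by at most 1), which
the tests verify against an independent shortest-path computation.

**Interface zone.** The default IZ is five ranks wide with a three-rank
central edge: compartments $S = \{-2\}$, $TE = \{-1, 0, +1\}$,
$T = \{+2\}$, re-ranked to positions 1, 2, 3. Both the TE width (odd) and
the flank depth are configurable; with TE width 1 the zone is
$S=\{-1\}, TE=\{0\}, T=\{+1\}$. Disconnected interface components are pooled
into one IZ per region — one indicator set per annotated region. A region
too thin to populate every required rank is an error naming the missing rank
rather than a silently degenerate profile.

## Indicators

Per compartment: mean $m$ and sample standard deviation $sd$ (the $n-1$
denominator; $sd = 0$ for a single hexagon) of per-hexagon density.
Whole-profile indicators on positions $p \in \{1,2,3\}$:

$$\mathrm{CM} = \frac{\sum_c p_c v_c}{\sum_c v_c} \in [1, 3], \qquad
  \mathrm{ID} = \frac{m(S)}{m(T)}.$$

CM is computed once from the compartment means (CM$_m$) and once from the
standard deviations (CM$_{sd}$); values above 2 mean density (or density
heterogeneity) is shifted toward the epithelial aspect. ID > 1 signals an
abrupt density drop across the edge into the epithelium. Degenerate cases
return missing values, never infinities: CM with an all-zero profile, ID
with $m(T)=0$.

The $[1,3]$ position convention is a stand-in with the same ordering
behavior as any affine relabeling of the three compartments: CM is
monotone-invariant under affine position changes, and ID does not depend on
positions at all.

**Log transform.** Density distributions are right-skewed, so indicators are
natural-log transformed for parametric statistics. Base $e$ is used because
reported cutoffs in this family of analyses (≈ 3.7–5.7 for cells/mm²
densities) are consistent with natural logs of plausible densities
(ln 105 ≈ 4.65). Zero-valued *density* indicators receive a pseudo-count of
ε = 1 cells/mm² before the log (so 0 maps to 0); CM and ID are logged
directly. ε is configurable; the analysis is insensitive to it whenever
compartments are non-empty of cells.

## Survival modeling

* **Optimal cutoffs.** Each continuous variable is dichotomized at the
  candidate cutoff (midpoints of consecutive sorted unique values)
  maximizing the log-rank χ², subject to both groups holding at least 10% of
  the complete cases; ties break toward the smaller cutoff. The scan is
  exhaustive by construction and is tested against a hand-coded log-rank
  scan. The reported p-value is the nominal log-rank p at the selected
  cutoff, *uncorrected* for maximal selection — the univariate screen is
  exploratory, matching a nominal 0.05 significance convention; this caveat
  is stated in the output documentation.
* **Cox models.** Partial-likelihood fits use the Efron tie correction,
  appropriate for month-resolution follow-up where ties are guaranteed.
  Monotone-likelihood fits are returned flagged (`converged = FALSE`), not
  silently. Model-level likelihood-ratio statistics are reported against the
  null model with the per-model complete-case N.
* **Stepwise selection.** Forward entry by likelihood-ratio test
  (α_enter = 0.05, largest LR first — deterministic), followed by backward
  LR removal (α_remove = 0.10) after each entry. Selection runs on complete
  cases of the full candidate set so all LR comparisons share one dataset;
  the final model is refit on complete cases of the selected variables only,
  which is why the reported N varies between models built from different
  variable sets. The entry/removal thresholds are the conventional defaults
  and configurable, since the originating analyses do not state them.
* **Leave-one-out stability.** The stepwise search is repeated on each
  leave-one-out subsample; the final set comprises variables selected in at
  least 50% of folds (configurable — "most frequently selected" fixes no
  threshold), refit on the full data.

## The combined prognostic score

Each independent predictor contributes 1 when the patient's value falls on
its poor-prognosis side, 0 otherwise. Rule directions are derived from the
sign of the multivariable log hazard ratio of the dichotomized predictor
(HR > 1 above the cutoff ⇒ above is poor). The integer sum (0–5 for five
rules) maps to risk tiers low (0–1), intermediate (2), high (3–5); the
two-rule CD8-only variant maps 0/1/2 to the same tiers. Patients missing any
rule variable are excluded from scoring (complete-case), and flagged. Tiered
survival is summarized by Kaplan–Meier curves, pairwise log-rank tests and
survival probabilities at 24 and 60 months (configurable horizons).

## What the synthetic-data generator does and does not emulate

The generator produces: (i) label rasters with blob-shaped epithelial
islands (unions of discs, optional lobes) in stroma, giving curved
interfaces that exercise the ranking; (ii) CD8+ centroids from an
inhomogeneous Poisson process whose intensity is a step function of the
signed Euclidean distance to the epithelium boundary (five bands: deep/near
stroma, edge, near/deep epithelium), plus homogeneous CD8− cells over
tissue; (iii) Weibull proportional-hazards cohorts
$h(t\mid x) = h_0(t)\exp(\beta^\top x)$ with independent exponential
censoring whose rate is calibrated on the realized event times to hit the
target censoring fraction exactly in expectation.

It deliberately does *not* model: nucleus-level morphology or stain
variation, clustered (non-Poisson) lymphocyte aggregates such as tertiary
lymphoid structures, segmentation errors, or spatial correlation between
the cell pattern and survival beyond the chosen linkage covariates. Passing
tests therefore demonstrate correctness of the *measurement and modeling
machinery* under a known generative truth — not that real tissue satisfies
Poisson or proportional-hazards assumptions.

## Numerical choices and problem sizes

* Hexagon assignment uses cube rounding of fractional axial coordinates
  (exactly the nearest-center rule; equidistant boundary points resolve
  deterministically, lexicographically smallest $(q,r)$).
* Rasters in simulations default to 2–5 µm/px; the aggregation itself is
  validated at 0.5 µm/px. Coarser rasters change per-hexagon areas by well
  under the 10% tissue floor and leave densities unbiased.
* Gradient-recovery validation uses 7 × 7 mm fields with 20 epithelial
  blobs of 480 µm radius: this yields roughly 250 T-compartment hexagons
  per slide, sized so that the immunodrop estimator's sampling error
  (dominated by the ~0.55 expected CD8+ count per epithelial hexagon at
  50 cells/mm²) gives a standard error of about 0.10 on the log scale —
  the precision required to resolve a 4:1 ratio within ±25% per slide.
  Smaller fields recover the gradient on average but with proportionally
  wider per-slide spread.
* Cohort validations use n = 1000 for coefficient recovery, 500–1000
  replicates for calibration rates, and n = 300 for risk-tier ordering,
  with the baseline scale chosen so the 60-month survivor probability falls
  mid-range where tier separation is informative.
* The end-to-end study simulation stitches a malignant and a non-malignant
  half-field per slide and links survival to the true (generative) log
  epithelial intensities, so the pipeline's measured indicators act as noisy
  proxies of the hazard-relevant truth, as in a real study.

## Known limitations

* One IZ per region: no per-nodule sub-analysis, no interface curvature or
  shape statistics.
* The edge convention (epithelium-side, majority-class) is one of several
  defensible operationalizations; alternatives shift compartment boundaries
  by at most one rank and are reachable through the zone configuration.
* Cutoff-optimized p-values are not corrected for maximal selection; treat
  univariate tables as hypothesis-generating.
* LOOCV stabilizes variable *selection*; it does not debias the
  coefficients of the final refit.
* The hexagonal grid's orientation and origin are fixed conventions; results
  can shift by fractions of a hexagon under grid translation. At 65 µm side
  length this is far below the biological variability of interest.
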