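---
title: "Neighborhood enrichment with a conditional permutation null: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood enrichment with a conditional permutation null: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

## The model

The input is a point pattern with marks: cells at planar positions
$(x_i, y_i)$ carrying cell-type labels, all in one tissue sample. For an
ordered pair of types $(A, B)$ the observed statistic is

$$ x_{\mathrm{obs}} = \frac{1}{n_A}\sum_{a \in A} \#\{\, b \in B : \lVert a - b\rVert \le d,\ b \neq a \,\}, $$

the average number of $B$ cells in the radius-$d$ neighborhood of an $A$
cell. The neighborhood enrichment score is the permutation z-value
$(x_{\mathrm{obs}} - \mu)/\sigma$, where $\mu$ and $\sigma$ summarize
$x_{\mathrm{obs}}$ over $R$ draws from a null model.

Two nulls are implemented:

* **Conditional** (the default, and the point of the package): $A$ stays
  fixed; the $n_B$ positions of $B$ are re-drawn uniformly *without
  replacement from the positions of all non-$A$ cells* (the original $B$
  positions are part of that pool). The identities of the remaining
  non-$A$ cells are irrelevant to the statistic and are not tracked.
  Because candidate positions are real cell positions, the null preserves
  the tissue's geography — cell-dense regions, holes, compartments — and
  the score measures only whether $B$ prefers or avoids $A$'s vicinity
  *given* that geography. The resulting matrix is asymmetric on purpose:
  row $A$ conditions on $A$'s architecture.
* **Full shuffle**: all labels are permuted over all positions, one
  permutation per replicate reused for every pair. This is the
  conventional fast null; its z-scores are symmetric for distinct types
  and cannot separate "B avoids A" from "A is structured and B merely
  lives elsewhere".

Assumptions worth stating: a single connected sample with shared
coordinates and units; the same $d$ across the whole tissue regardless of
local density; counting, not kernel weighting; and no edge correction —
neighborhoods truncated by the tissue border lose counts, but the null
re-draws positions inside the same border, so observed and null are
truncated alike and the z-score absorbs it.

## Parameters

* `radius` ($d$): in the units of the coordinates; **no default**, because
  the package cannot know whether coordinates are pixels or micrometres.
  The boundary is inclusive ($\le d$); a cell never counts itself (by
  identity — distinct cells at coincident coordinates do count each
  other).
* `permutations` ($R$): default 1000. Monte-Carlo noise on the score
  scales like $1/\sqrt{R}$.
* `seed`: one master seed; each ordered pair derives a sub-seed keyed by
  the *class names*, so results are reproducible, independent of record
  order (all sampling runs over cells sorted by id), and a pair's stream
  is unchanged when an unrelated class is added or removed. If no seed is
  given one is drawn and recorded in the fitted object.
* `sd_divisor`: the null standard deviation uses the sample divisor
  $R - 1$ by default; `"population"` ($R$) is available for cross-checking
  against tools that use it.
* `diagonal`: a type against itself is contradictory under the conditional
  null (the type cannot be both fixed and re-drawn), so the diagonal is
  undefined by default. `diagonal = "full_shuffle"` fills it by re-drawing
  the type's positions over all cell positions, and the policy is recorded
  in the fitted object's metadata.

Degenerate pairs are reported, never coerced: if every null replicate
yields the same value ($\sigma = 0$ — e.g. a two-class table, where the
pool equals $B$ exactly), the score is undefined with reason
`"sigma_zero"`, not $\pm\infty$; per-pair failures never abort the rest of
the matrix.

## Numerical and format choices

Neighbor counting is a blocked vectorized $O(n_A n_B)$ scan evaluating
exactly the same floating-point expression as a naive double loop, so the
two agree bit for bit (the test suite carries the double-loop oracle).
Scores are written to CSV with 17 significant digits, which round-trips
IEEE doubles exactly; undefined entries are empty fields; provenance
(radius, permutations, seed, method) travels as `#` comment lines above
the header. The matrix CSV layout (empty first header cell, rows = focal
type, columns = re-drawn type) is this package's own documented dialect.
CSV parsing accepts `.` as the only decimal separator regardless of
locale. CLI outputs are written to a temporary file and renamed, so a
failing run leaves no partial artifact.

## Winsorization of staining features

Per-cell intensity features from different tissue cores on one slide often
differ by what is, to good approximation, a positive affine map (gain and
offset from fixation and antibody-binding variation). `winsorize()`
computes the 10th and 90th percentiles (linear interpolation between order
statistics, `stats::quantile` type 7 — percentile conventions differ
between tools, so this is pinned), clamps into $[P_{10}, P_{90}]$, and by
default rescales that interval to $[0, 1]$. Pure clamping
(`rescale = FALSE`, textbook Winsorization) cannot align affine-shifted
cores — the clamped distributions still sit on different scales — so
rescaling is the default; because positive affine maps commute with
percentiles exactly, per-core winsorize-and-rescale removes such shifts to
floating-point accuracy. `normalize_features()` applies this per feature
and, by default, per sample/core; `alignment_report()` replaces a visual
overlay check with per-feature two-sample Kolmogorov–Smirnov distances
before and after.

Caveats: normalization is exactly idempotent only when $(n-1)p/100$ is
integral for both percentile ranks (otherwise interpolation against the
clamped mass shifts the anchors slightly); constant features map to 0 with
a warning; groups of fewer than two rows pass through unchanged.

## Confusion-matrix comparison

Two classifications are compared only over cells matched by id — the
methods must share one segmentation; mismatched id sets are an error
listing the offenders, not a silent intersection. Expected and predicted
axes keep independent label sets in first-appearance order, since one
method may emit a class the other never uses. Per-class recall/precision
with empty denominators, and classes missing from one axis, are reported
as missing rather than 0, so averages are not silently deflated.
`select_cells()` returns exactly the cells behind one matrix element, in
input order, for downstream spatial viewers; the selections over all
elements partition the cells.

## What the synthetic generators emulate

`generate_tissue()` composes per-class placements: uniform (complete
spatial randomness), Thomas-style parent/offspring clusters, displacement
attraction toward an earlier class, rejection-sampled inhibition,
region-restricted occupancy, and regular (stratified jittered-grid)
placement that mimics the near-constant density of packed tissue.
Window clipping re-draws the offending displacement rather than reflecting
or truncating, preserving isotropy near edges; inhibition has an iteration
cap that fails with advice instead of hanging. All generators are pure
functions of their arguments including the seed, and restore the caller's
RNG state.

The canned scenarios pin the study conditions used by the acceptance
tests:

* **CSR calibration**: three independent uniform classes of 200 cells on a
  $1000^2$ window, $d = 50$ — about 4.7 expected within-radius neighbors
  per class, a realistic mid-density regime. Scores should be mean-zero
  with roughly unit spread.
* **Attraction**: B displaced from A with $\mathrm{sd} = d/5$;
  **inhibition**: B kept at least $2d$ from a sparser A (80 cells, leaving
  roughly 8% of the window admissible, so rejection sampling is
  dependable). A third uniform class supplies the randomization pool in
  both.
* **Structured tissue (one-way repulsion)**: four fixed vessel-like discs
  ($r = 80$) in the right half-window; TAMM pack the discs as a dense
  regular infiltrate (sunflower layout, jitter sd 3); the extravascular
  space is a jittered lattice of 900 cells (jitter half a cell width,
  emulating hard-core packing) interleaved deterministically 1:2 into
  Glioma and Other, so the local tissue composition is constant.

The last design deserves its reasoning spelled out. The target pattern is
*one-way* structure: Glioma→TAMM strongly negative (TAMM live where Glioma
cannot), TAMM→Glioma near zero (around vessels, Glioma make up a typical
share of non-TAMM cells). A scenario in which Glioma and Other were
independent draws from the same distribution would make the reverse score
a calibrated standard normal — "near zero" only in expectation, exceeding
$\pm 1$ a third of the time. Real packed tissue is *more regular than
Poisson*, and that regularity is what keeps the reverse score tight; the
lattice placement, the deterministic fine interleaving of tumor and
stroma, and a neighborhood radius on the scale of the structures
($d = 100$) encode exactly that. These choices were fixed while designing
the generator, validated on a few hundred held-out seeds, and are pinned
in one place (`asymmetry_vessels()` and `generate_asymmetry_scenario()`).

* **Two-core features**: per-feature two-component normal mixtures (dim
  and bright populations, 1000 cells per core by default — typical for a
  1.2 mm core) with core 2 mapped through $a x + b$ plus small noise,
  emulating strong inter-core intensity shifts; defaults
  $(a, b) = (2, 100)$ put the cores on disjoint scales
  (Kolmogorov–Smirnov distance 1 before normalization).

What the generators do **not** emulate — and hence what passing tests do
not certify about real data: segmentation errors and doublets, spatially
varying cell density gradients within a compartment, anisotropic
structures (cords, layers), marker spillover between channels,
non-affine (nonlinear, saturating) staining distortions, and
multi-sample batch structure beyond two cores. Conclusions about such
effects need real data, not this suite.

## Problem sizes and runtime

The shipped statistical checks use 25 tables (up to 600 cells) for the
counting oracle, 50 CSR tissues at $R = 500$ for calibration, 20 seeds per
scenario for directional and asymmetry checks at $R = 300{-}500$, and
$R = 5000$ against the exhaustive 20-subset enumeration on a 7-cell toy —
sizes chosen so the whole suite runs in well under a minute on one core
while keeping Monte-Carlo noise far below the asserted tolerances.

## Known limitations

* The conditional null is per-pair ($O(K^2)$ pair fits); very large $K$
  with large $R$ multiplies accordingly, though each pair reuses one
  focal-class distance scan.
* Neighbor counting is exact $O(n_A n_B)$; for hundreds of thousands of
  cells a spatial index would be preferable. At TMA-core scales (low
  thousands) the vectorized scan is faster than index bookkeeping.
* Only radius neighborhoods are offered (no k-nearest-neighbor or
  Delaunay graphs), only z-scores are reported (replicate values can be
  kept for empirical p-values; no multiple-testing machinery is bundled),
  and no edge correction is attempted, by design.
* Winsorization aligns affine shifts exactly but nonlinear staining
  distortions only approximately; it is not a substitute for quantile
  normalization or model-based batch correction when those are warranted.
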