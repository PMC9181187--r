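---
title: "Simulated specular microscopy of the corneal endothelium: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated specular microscopy of the corneal endothelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneaSM)
```

## The problem

Endothelial cell density (ECD, cells/mm²) is the main quality criterion of
a stored donor cornea: endothelial cells do not regenerate, and grafts with
too few of them fail. Eye banks estimate ECD from specular microscopy (SM)
images of the endothelial monolayer. Two practical questions dominate that
workflow: *is this image good enough to count?* (image-quality grading) and
*how accurately does a manual count over a drawn region estimate the true
density?* (the variable-frame center method, validated against counts of
fluorescently stained nuclei).

Real acquisitions of this kind are not publicly deposited, so corneaSM
builds the entire chain on a synthetic, ground-truthed endothelium: every
analysis stage (Voronoi border reconstruction, grading, center-method
counting, nuclei detection, paired statistics) can then be checked against
a truth the generator records, with independent oracles where the spec of
an operation admits one.

## The geometric model

### Mosaic as a clipped Voronoi tessellation

An endothelial mosaic is represented by the positions of its cell centers
inside a rectangular field (default 935 × 748 µm, digitised at 1280 × 1024
px — an isotropic 0.7305 µm/px, which `generator_config()` asserts).
Borders are the Voronoi diagram of the centers; regions are clipped to the
field rectangle so the polygons tile the field exactly. Clipping is our
closure choice for boundary cells (the upstream tools do not document
theirs); it is what makes area-conservation checks exact:

```{r}
m <- tessellate(cbind(c(300, 635), c(374, 374)), field_rect())
sum(m$areas_um2) - 935 * 748
```

Adjacency requires a shared Voronoi edge longer than 1e-9 µm; degenerate
corner contacts are not neighbors, which stabilises the hexagonality
statistic under floating-point noise. The implementation (half-plane
clipping with edge-provenance labels, in C++) is verified against a
sampled-bisector oracle: two cells are declared adjacent by the oracle iff
some point of their bisector inside the field is strictly closer to the
pair than to every other center.

Morphometry follows eye-bank conventions: polymegethism is the coefficient
of variation of cell area, pleomorphism is summarised as hexagonality (the
fraction of interior cells with exactly six neighbors). Both are computed
on interior cells only — border polygons are clipped and would bias both.

### The generator: a window onto a larger sheet

`generate_mosaic()` perturbs a hexagonal lattice at the spacing that
realises the target density, `s = sqrt(2 / (sqrt(3) * ecd))` (≈ 21.5 µm at
2500 cells/mm²), with isotropic Gaussian jitter. Two modelling points
matter:

* **Random phase and orientation.** The microscope window lands at an
  arbitrary position and orientation on the endothelium, so the lattice
  phase is drawn uniformly over one unit cell and its orientation uniformly
  over the 60° symmetry period, and the lattice extends beyond the field
  before cropping to centers strictly inside. This makes the expected cell
  count of *any* window exactly density × area. We first implemented the
  naive alternative — a lattice fitted inside the field with fixed
  phase — and measured realized densities 1–4% below target (edge
  rarefaction plus phase-alignment error, worse for small windows); that
  bias is invisible to most tests but corrupts the null calibration of the
  paired SM-vs-nuclei comparison, turning a nominal 5% rejection rate into
  ~80%. The window model removes it at the source.
* **Jitter as the disorder dial.** The default `jitter_sigma = 3` µm
  (≈ 14% of the spacing at 2500 cells/mm²) yields an area CV around
  0.12–0.2 and hexagonality around 0.9 — a well-preserved stored
  endothelium. Larger jitter monotonically increases polymegethism (a
  property test checks this at σ = 2 vs 6 µm). The generator does not model
  anisotropic cells or curvature; it is a flat, isotropic stand-in.

Each cell receives one nucleus, uniformly placed in a 20%-inset of its
polygon so nuclei never sit on borders. Cell loss over storage
(`simulate_series()`) is Bernoulli thinning between sessions; survivors
keep their positions and are re-tessellated, so remaining cells enlarge and
the mosaic's polymegethism/pleomorphism rise — the geometric signature of
endothelial decay. Because removing Voronoi generators only grows the
surviving regions, recorded nuclei remain valid after every session.

### Rendering

`render_specular()` draws bright interiors, dark borders (≥ 20 gray levels
of contrast before noise), posterior folds as dark straight bands (the
simplest geometry that reproduces "count where there are no folds"
behavior), local blur patches in which borders lose contrast
(`border_distinct = FALSE` but still countable), a multiplicative
illumination ramp along the oblique-illumination direction (default 31°),
and additive Gaussian sensor noise. Ground-truth bookkeeping is exact by
construction: a cell is `visible = FALSE` iff its center lies under a
rendered band. `render_hoechst()` draws one Gaussian blob per nucleus on a
dark background. Both renderers are bit-deterministic in the config seed.
Images are written as plain-text PGM (P2) — the pre-installed stack has no
TIFF/PNG writer, and PGM converts losslessly to either.

## The analysis chain

### Variable-frame center method

A frame is a drawn simple polygon plus pointed centers; the density
estimate is `count / area`. A cell counts iff its pointed center is
strictly inside the boundary — the standard bias-cancelling edge rule for
the center method (the source protocol does not state its rule). Frames
pool by total cells over total area (`pool_frames()`), *not* by averaging
per-frame ratios: with frames of unequal area the two disagree (100 cells
/ 0.04 mm² plus 50 / 0.01 mm² pools to 3000, averages to 3750), and
area-weighting is the estimator consistent with pooling the underlying
regions. The protocol's ≥ 200 pointed cells per field is a warning policy
(`field_ecd(min_cells = 200)`, inclusive threshold), not a hard error.
Cornea-level ECD is the unweighted mean ± sample SD of the five field
estimates.

### Image-quality grading

Grading follows the four-category eye-bank scheme on per-cell flags
(`countable`, `border_distinct`) and mosaic adjacency. Countable cells are
split into contiguous groups; groups of ≥ 15 cells qualify (the minimum
variable-frame size); N is the number of qualifying cells. The category
rules, with our two operationalisations of the scheme's loose edges:

* **excellent** — some contiguous group of ≥ 50 cells, all border-distinct.
  We use components of the *distinct-cell* subgraph, so the ≥ 50 contiguous
  cells are themselves all distinct. The scheme's "as many as 150" is read
  as a counting-effort cap, not a disqualifier: a group of 200 distinct
  contiguous cells is not a worse image.
* **good** — N ≥ 50 with *zero* indistinct qualifying cells. The scheme
  asks for "sufficient" distinct borders without quantifying it; we place
  the good/fair boundary at 0% vs > 0% indistinct, which keeps the three
  analyzable categories mutually exclusive and ordered.
* **fair** — N ≥ 50 with at most 25% indistinct qualifying cells.
* **unanalyzable** — everything else (including N = 0, reported with
  indistinct fraction 0).

The classifier is property-tested for monotonicity (making a cell distinct
never lowers the grade) and checked for exact agreement with a brute-force
oracle that recomputes groups by transitive closure and applies the rules
literally, on 200 random instances.

Tabulation (`tabulate_grades()`) rounds percentages half away from zero to
whole percents, matching how such tables are printed; a column may sum to
100 ± 2 from rounding.

### Nuclei detection

`detect_nuclei()` is deliberately simple — global Otsu threshold,
4-connected components, intensity-weighted centroids — because the gold
standard must be *unbiased*, not sophisticated. At realistic densities
neighboring nuclei can touch: component areas at default SNR split cleanly
into singles (~median area) and merges (~2× median and up), so components
above 1.6× the median are divided among their smoothed local maxima, and a
component whose area implies more nuclei than it has maxima (deeply merged,
unimodal pairs) is sliced along its principal axis into the implied number
of equal-weight parts. With the default configuration this recovers the
true count to within 0.1% with recall and precision ≥ 0.99 over 20 seeds.
We initially used a 2.5× split threshold; measurement showed merged pairs
sit at ~2.1× median and were never split, biasing counts low by ~1.5%,
so the threshold was moved into the observed gap.

### Statistics

The comparison stage mirrors the reference protocol: Shapiro–Wilk on the
*paired differences* (the quantity the paired tests assume) with a 5%
non-normality threshold; paired t when normal, Wilcoxon signed-rank
otherwise; all tests two-tailed. Wilcoxon conventions are fixed in the
package: zero differences dropped, midranks for ties, exact null
distribution by convolution for ≤ 12 non-zero differences (checked against
full 2ⁿ enumeration), normal approximation with tie and continuity
corrections above. Repeated measurements across storage days use one-way
repeated-measures ANOVA (the same corneas are re-imaged, so a
subject-blocked design is the defensible reading) with Holm–Šidák
step-down adjustment of the pairwise paired comparisons,
`1 − (1 − p₍ᵢ₎)^(m−i+1)` with enforced monotonicity.

Degenerate inputs are handled explicitly: constant vectors are a
degenerate-input error for the gate; identical paired samples return
statistic 0, p = 1; constant non-zero differences skip the (undefined)
gate and fall to the Wilcoxon branch.

## The simulated study pipeline

`run_pipeline()` composes the stages into a storage study: per cornea, a
density drawn from the arm preset (1-month arm N(2299, 332²), 3-month arm
N(1831, 213²), truncated to [1000, 4000] cells/mm²), five independent
field mosaics, Bernoulli cell loss at a constant daily hazard (default
0.35%/day, ≈ 10% per month — the conventional organ-culture attrition
scale), and posterior-fold coverage declining linearly across sessions
(default 20% → 5%), which reproduces the observed pattern that more cells
become countable at later controls. The simulated observer draws the
largest fold-free strip as its counting frame and points every visible
cell in it; no imputation is done for hidden cells. The Hoechst arm counts
one nucleus per cell over the full field minus a 10-px margin. All
randomness derives from one root seed through fixed per-cornea/per-field
streams, so a report is reproducible byte-for-byte from its config.

The fold geometry and indistinct-patch statistics are *plausible but
uncalibrated* — the source material shows folds without parameterising
them. Quantities that depend on them (grade distributions, per-session
counted-cell numbers) are therefore design-dependent; only bookkeeping
(records = corneas × sessions × 5) and estimator properties are asserted.

## What a green test establishes — and what it does not

The synthetic world supports exact claims about the *analysis*: the
tessellation tiles, the classifier implements its stated rules, the
center-method estimator recovers a known density within 2%, the two
counting arms agree under the null at the nominal 5% level. It does not
validate perception: countability and distinctness are generator flags,
not properties detected from pixels; real specular artifacts (specular
drop-out, pressure rings, observer variability) are absent. Agreement
statistics measured here are therefore upper bounds on real-world
performance, and the published real-data p-values are intentionally out of
scope — the raw images they summarise are unavailable.

## Numerical choices

* Duplicate-center tolerance 1e-9 µm; coordinates are real-valued µm,
  origin at the field's top-left corner, x rightward, y downward (image
  convention).
* Adjacency edge-length threshold 1e-9 µm; tiling conservation asserted at
  1e-6 relative error.
* Voronoi cells are built by nearest-first half-plane clipping with an
  early stop once the next generator is farther than twice the current
  circumradius; ties/collinear degeneracies resolve by the ≤ 0 inside
  convention and a zero-length-edge sweep.
* Percent rounding: half away from zero (matches printed tables; R's
  `round()` rounds half to even and would print 0.5 as 0).
* Seeds: one integer per config; derived stage seeds via a fixed LCG step,
  all below 2³¹.
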