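# corneaSM

Simulation and analysis of **specular microscopy of the corneal
endothelium** — the imaging workflow eye banks use to decide whether a
donor cornea carries enough endothelial cells to graft.

## The problem

The corneal endothelium is a monolayer of non-regenerating, roughly
hexagonal cells; its density (ECD, cells/mm²) is the main quality
criterion of a stored donor cornea. ECD is estimated from specular images
by the **variable-frame center method**: an observer points the center of
every cell in a contiguous countable group, draws the group's boundary,
and cell borders are reconstructed automatically by **Voronoi
tessellation** of the pointed centers; density is pointed cells divided by
boundary area. Images are first graded by the four-category eye-bank
scheme (excellent / good / fair / unanalyzable) based on how many
contiguous cells are countable and what fraction of borders are
indistinct, and specular counts are validated against counts of
Hoechst-stained nuclei (one nucleus per cell — the gold standard).

Real acquisitions of this kind are not publicly deposited, so corneaSM
rebuilds the whole chain on a **synthetic, ground-truthed endothelium**:

* `mosaic_model` — clipped Voronoi tessellation from cell centers,
  adjacency, morphometry (polymegethism = CV of cell area, pleomorphism =
  1 − hexagonality), contiguous groups;
* `synthetic data` — jittered hexagonal mosaics with random lattice phase
  and orientation (a window onto a larger sheet), posterior-fold bands,
  indistinct-border patches, illumination falloff and sensor noise,
  specular- and Hoechst-style rendering, 5-field sampling plans,
  longitudinal cell-loss series;
* `ecd counting` — calibration, frame counting with the strict-center
  rule, area-weighted frame pooling, the ≥ 200 cells/field policy,
  cornea-level mean ± SD over five fields;
* `quality grading` — the four-category classifier and printed-table
  style tabulation;
* `nuclei counting` — Otsu thresholding, connected components,
  merge-splitting, gold-standard ECD;
* `statistics` — Shapiro–Wilk-gated paired t / exact Wilcoxon signed-rank,
  repeated-measures ANOVA with Holm–Šidák adjustment, field-of-view ratio
  arithmetic;
* `pipeline` — `run_pipeline()` composes everything into a simulated
  storage study, reproducible from one seed.

See `vignettes/endothelial-sm-pipeline.Rmd` for the models, parameter
defaults and design choices.

## Worked example

```r
library(corneaSM)

cfg <- generator_config(target_ecd = 2500, seed = 42,
                        fold_spec = list(n_bands = 2, band_width_um = 60,
                                         orientation_deg = 0),
                        indistinct_fraction = 0.05)
g  <- generate_mosaic(cfg)         # ground-truthed mosaic
g$mosaic
#> <mosaic> 1751 cells over 935 x 748 um (ECD 2504 cells/mm^2)
morphometry(g$mosaic)
#> <morphometry> n = 1599, mean area 399.8 um^2, CV 0.124, hexagonality 0.930

rs <- render_specular(g$mosaic, g$truth, cfg)   # 1280 x 1024 8-bit image
flags <- cell_flags(rs$truth$cell_id, rs$truth$visible,
                    rs$truth$visible & rs$truth$border_distinct)
grade_image(flags, g$mosaic$adjacency)
#> <grade_result> excellent (largest group 910, qualifying 1465, indistinct 3.6%)

rh  <- render_hoechst(g$mosaic, rs$truth, cfg)
det <- detect_nuclei(rh$image)
det
#> <nucleus_detection> 1751 nuclei (threshold 71)
hoechst_ecd(det, full_field_frame(), calibration())
#> <ecd_estimate:hoechst> 1679 cells / 0.67501 mm^2 = 2487.4 cells/mm^2

paired_compare(c(2209, 2100, 2350, 2180, 2290, 2410),
               c(2251, 2130, 2300, 2220, 2310, 2460))
#> <comparison> wilcoxon_signed_rank: statistic 5.5, p = 0.3438 (n = 6)
```

Reading the numbers: the generator realised 1751 cells over the 0.699 mm²
field (2504 cells/mm² against the 2500 target); the mosaic is
well-preserved (area CV 0.124, 93% hexagonal cells); with two fold bands
and 5% blur patches the image still grades *excellent* (a contiguous
all-distinct group of 910 ≥ 50 cells). Nuclei detection recovered exactly
1751 blobs — 1679 of them inside the margin-inset gold-standard frame,
giving 2487 cells/mm², within 0.7% of the mosaic's true density. The
paired comparison gated to the exact Wilcoxon test (n = 6 pairs) and found
no difference between the two arms.

A command-line surface with `simulate`, `grade`, `count`, `nuclei`,
`compare` and `run` subcommands lives at `inst/cli/corneasm.R`
(`Rscript inst/cli/corneasm.R run --arm one_month --seed 1 --out report/`).
Images are written as plain-text PGM; tables as CSV; reports as JSON.

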