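# mitoscreen

Per-cell quantification of mitochondrial health from high-content
fluorescence imaging of well plates. The package is aimed at
cell-biology groups running plate-based stress assays (oxidant
titrations, uncoupler and fission-inducer treatments) on an automated
microscope, who want a scriptable, testable alternative to interactive
pipeline tools for three standard readouts:

* **Mitochondrial H2O2** — speckles of a boronate H2O2 probe are
  enhanced with a white top-hat, detected (3–35 px), related to cells,
  and scored as the colocalized-area fraction

  `h2o2_level = |puncta ∩ mito ∩ cell| / |mito ∩ cell| ∈ [0, 1]`

* **Mitochondrial membrane potential** — the JC-10 orange/green
  aggregate-to-monomer ratio under mutual masking:

  `mmp_ratio = mean(orange over A*) / mean(green over M*)`

  where `A*` is the aggregate footprint inside the cell's monomer
  region and `M*` the monomer region under the aggregates. The ratio
  falls as mitochondria depolarize.

* **Mitochondrial morphology** — fragmentation as the leading bins of a
  grayscale granular spectrum (`g_i = 100·(I_{i−1} − I_i)/I_0`, the
  percentage of intensity removed at erosion scale `i`), and length as
  the maximal geodesic distance between skeleton endpoints (steps 1 and
  √2; no corner-cutting past axial bends).

Around these sit the shared plumbing of a plate pipeline: Operetta-style
filename parsing (`RRRCCC-F-TTTSSSCCC.tif`), bit-depth-normalized TIFF
loading, per-image quadratic illumination correction, Otsu 2-/3-class
and minimum-cross-entropy thresholding (global or adaptive),
propagation-based secondary-object segmentation, object filtering, and
condition/well/field statistics (ANOVA + Tukey HSD, Student t,
boxplot-rule outlier flags). A synthetic plate generator with full
ground truth stands in for the microscope, so everything is testable
offline.

## Worked example

Simulate a three-condition stress plate (the dose knobs raise H2O2
puncta density, depolarize mitochondria and fragment the network
together), analyze one assay end to end, and compare conditions:

```r
library(mitoscreen)

design <- validation_design(seed = 1)     # 256-px fields, 3 conditions x 2 wells
dir <- tempfile(); generate_plate(design, dir)

per_cell <- analyze_plate(dir, assay = "mmp", params = validation_params())
head(per_cell[, c("condition", "well_row", "field", "cell", "mmp_ratio")])
#>   condition well_row field cell mmp_ratio
#> 1   control        1     1    1  6.487734
#> 2   control        1     1    2  5.746745
#> 3   control        1     1    3  5.299528
#> 4   control        1     1    4  5.664052
#> 5   control        1     2    1  5.097276
#> 6   control        1     2    2  6.077518

tapply(per_cell$mmp_ratio, per_cell$condition, mean)[c("control", "low", "high")]
#>   control       low      high
#> 6.3939947 2.2928720 0.7539267

compare_groups(split(per_cell$mmp_ratio, per_cell$condition), design = "multi")
#> <comparison_result> anova_tukey over 3 groups: statistic 934.7, p = 1.94e-113 ***
#>     comparison      diff p_adj stars
#> 1 high-control -5.640068     0   ***
#> 2  low-control -4.101123     0   ***
#> 3     low-high  1.538945     0   ***
```

The mean orange/green ratio drops from ≈ 6.4 in polarized control cells
to ≈ 0.75 under strong depolarization — a monotone dose response the
ANOVA calls at `p < 0.001`. The same pattern (in the documented
directions) holds for `h2o2_level`, `fragmentation_percent` and
`mean_length_px` via `analyze_plate(..., assay = "h2o2")` and
`assay = "morphology"`.

A thin command-line wrapper covers the same flow:

```sh
exec/mitoscreen simulate --out plate_dir --seed 1
exec/mitoscreen mmp --input plate_dir --out results
exec/mitoscreen stats --input results/per_cell.csv --out results
```

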