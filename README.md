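# cellsweep

Quantifies where a fluorescently labelled organelle sits inside a single
cell. Organelles like the endoplasmic reticulum shift between the
perinuclear region and the cell periphery, or collapse asymmetrically to
one side of the nucleus; `cellsweep` measures both effects per cell, from
a 2D fluorescence image (e.g. a summed-intensity projection of a confocal
z-stack) plus nucleus/cell/neighbour-exclusion masks. It is aimed at cell
biologists comparing organelle positioning across genotypes or
treatments, and ships a synthetic-cell phantom generator with analytic
ground truth so every stage of the measurement can be validated.

## The method

About the nucleus centre, a ray is swept through 360° in 0.1° steps,
taking a bilinear line profile each time; each polar sample carries a
Jacobian area weight *w = r Δθ Δr* so that weighted sums estimate
Cartesian integrals (the correction for square pixels on a polar
lattice). Per angle, the radial axis is normalized so the cytoplasm
between the nuclear envelope *r_ne(θ)* and the cell edge *r_edge(θ)*
spans *u* = 0–100%, with the nucleoplasm mapped to −25–0 as a control
band. The area-weighted intensities become a spatial probability mass
function *p* over (θ, u) samples, from which:

* **MDR** (mean distribution radius) `= Σ p·ρ`, with ρ = u (normalized,
  %) or the raw radius (µm). Higher = more peripheral ("dispersed").
* **Asymmetry** `= |Σ_θ q(θ)·e^{iθ}|` with `q(θ) = Σ_u p`, the circular
  mean resultant length of the angular marginal, in [0, 1]. Higher =
  signal collapsed to one side of the nucleus ("clustered").

Group comparisons (two-sided t, Mann–Whitney, Kruskal–Wallis, one-way
ANOVA + Dunnett vs a reference group) operate on the per-cell metrics.

## Worked example

```r
library(cellsweep)

# one synthetic "clustered" cell: perinuclear profile with a one-sided
# angular bias (von Mises kappa ~ 3), rendered with shot + read noise
panel  <- make_phenotype_panel("clustered", n_cells = 1, seed = 42)
cell   <- panel$cells[[1]]
metrics <- quantify_cell(cell$image, cell$masks, polar_config(),
                         cell_id = cell$cell_id)
print(metrics, digits = 4)
#>         cell_id mdr_normalized mdr_raw asymmetry mean_angle domain
#> 1 clustered_001          25.03   4.379    0.7721    -0.7889   full

print(cell$truth[, c("mdr_normalized", "mdr_raw", "asymmetry")], digits = 4)
#>   mdr_normalized mdr_raw asymmetry
#> 1          24.51   4.343    0.7893
```

The measured MDR of 25.0% says the signal sits, on average, a quarter of
the way from the nuclear envelope to the cell edge (the phantom's true
value is 24.5%); `mdr_raw` is the same statistic in micrometres. The
asymmetry of 0.77 (truth 0.79) flags the strong one-sided clustering, and
`mean_angle` points at its direction. For real data, build the inputs
with `read_image_tiff()` / `read_mask()` (or `sum_project()` from a
stack) and process whole experiments from a CSV manifest with
`run_batch()`, then compare groups:

```r
tab <- run_batch("manifest.csv", polar_config())
compare_groups(tab, "mdr_normalized", "anova_dunnett", reference = "WT")
```

## Analysis workflow

The `analysis/` scripts run the full study on synthetic panels
(20 cells per phenotype) and write tables under `results/`:

1. `01_simulate_panels.R` — simulate wildtype / dispersed / clustered
   panels to disk (images + masks + ground truth).
2. `02_quantify_panels.R` — quantify every cell from the file manifests
   (`results/metrics.csv`).
3. `03_validate_pipeline.R` — analytic closed forms, intensity
   conservation and oracle agreement (`results/validation.csv`).
4. `04_compare_groups.R` — group statistics and the scatter-with-mean±s.d.
   report (`results/report/`).

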