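# cystscreen

Phenotypic analysis of 3D cyst-growth high-content screens in R.

Renal epithelial cells cultured in hydrogels form hollow cysts — an
actin-rich spherical wall around a fluid-filled lumen — and swell when
intracellular cAMP is raised with forskolin. Screening compounds for
their ability to block that swelling is a standard route to candidate
modulators of cystic disease, read out by imaging every well of a
384-well plate as a two-channel fluorescence z-stack (actin + nuclei).
`cystscreen` takes such screens from raw stacks to biology:

* **Segmentation** of individual cysts plane-by-plane with vertical
  linking, so cysts stacked above one another in the gel are counted
  separately (`detect_cysts()`), plus wall measurement, maximum
  intensity projections and nuclei counting.
* **Per-well phenotypic features**: pixel areas, perimeter,
  circularity, wall thickness and ratios, intensity statistics, object
  and nuclei counts (`featurize_screen()`).
* **Normalization & QC**: plate-median and control-anchored robust
  z-scores, percent inhibition anchored at the two control medians, and
  the replicate-adjusted Z′-factor

  Z′ = [(AVG<sub>max</sub> − 3·SD<sub>max</sub>/√n) − (AVG<sub>min</sub> + 3·SD<sub>min</sub>/√n)] / (AVG<sub>max</sub> − AVG<sub>min</sub>),

  which reduces to the classical Z′ at n = 1 (`zprime()`).
* **Hit calling**: a compound is active when its replicate-mean cyst
  size z-score is ≤ 0 — at or below the unstimulated-control median —
  at any tested dose (`call_hits()`).
* **Phenotype profiling**: features gated by between-control Z′,
  standardized 3-component PCA (PC0/PC1/PC2), and classification of
  each compound-dose as `restored`, `unchanged` or `novel` — the last
  triggered geometrically or by a low nuclei count, the signature of
  cytotoxic "novel phenotype" wells (`fit_phenotype_space()`,
  `classify_phenotypes()`).
* **Synergy**: Bliss independence on dose × dose grids, E = E_A + E_B −
  E_A·E_B, combination index CI = E/E_AB with CI < 1 synergy and CI > 1
  antagonism (`analyze_synergy()`).
* **A synthetic screen generator** (`simulate_screen()`): seed-exact
  rendering of cystic z-stacks (bright actin ring, dim lumen, scattered
  nuclei, forskolin swelling, Hill dose responses, cytotoxic
  phenotypes) with complete ground truth — the package's benchmarking
  substrate, since raw screening images of this kind are generally not
  public.

Everything tabular flows through tibbles and pipes; fitted phenotype
spaces support `tidy()`, `glance()` and `autoplot()`.

## A worked example

```r
library(cystscreen)

out <- tempfile("demo-screen")
manifest <- run_pipeline(demo_screen_config(seed = 1), demo_compounds(), out)
manifest
#> <run_manifest> seed 1, stages: simulate -> featurize -> normalize -> hits -> profile
#>   Z' (area_px_med): P1 = 0.42
#>   wells_simulated: 32
#>   objects_detected: 260
#>   wells_featurized: 32
#>   hits_called: 2
#>   features_selected: 9

readr::read_csv(file.path(out, "hits.csv"), show_col_types = FALSE)[, 1:6]
#> # A tibble: 6 × 6
#>   compound concentration_um mean_size_z n_wells evaluable dose_hit
#>   <chr>               <dbl>       <dbl>   <dbl> <lgl>     <lgl>
#> 1 active-1              0.1       -4.41       4 TRUE      TRUE
#> 2 active-1              1         -4.14       4 TRUE      TRUE
#> 3 inert-1               0.1       41.6        4 TRUE      FALSE
#> 4 inert-1               1         38.9        4 TRUE      FALSE
#> 5 toxic-1               0.1      -19.2        4 TRUE      TRUE
#> 6 toxic-1               1        -18.9        4 TRUE      TRUE
```

The demo screen is a 4 × 8 mini-plate: three archetype compounds
(a potent active, an inert compound, a cytotoxic compound) in
quadruplicate at 0.1 and 1 µM beside unstimulated and
forskolin-stimulated controls. The Z′ of 0.42 is the replicate-adjusted
separation between those control groups; the hit table shows the active
and the toxic compound pulling cyst size at or below the unstimulated
median (z ≤ 0) at both doses, while the inert compound tracks the
swollen stimulated state (z ≫ 0). The profiling stage then separates
them: `labels.csv` marks the active `restored` and the toxic compound
`novel` (it shrinks cysts, but fragments walls and depletes nuclei).

```r
readr::read_csv(file.path(out, "labels.csv"), show_col_types = FALSE) |>
  dplyr::select(compound, concentration_um, label)
#> # A tibble: 6 × 3
#>   compound concentration_um label
#>   <chr>               <dbl> <chr>
#> 1 active-1              0.1 restored
#> 2 active-1              1   restored
#> 3 inert-1               0.1 unchanged
#> 4 inert-1               1   unchanged
#> 5 toxic-1               0.1 novel
#> 6 toxic-1               1   novel
```

See `vignettes/cystscreen-methods.Rmd` for the model, parameter and
design documentation.

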