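# shellont

Ontogenetic shell-shape analysis for turtles: from 3D landmark
configurations and carapace lengths to the minimum size at which a species'
shell reaches its adult shape.

Turtle shells change shape as they grow — mostly elongating and narrowing —
and comparative studies that want "adult" morphologies need a defensible
size cut-off. `shellont` implements the full analysis chain:

1. **Generalized Procrustes Analysis** of K×3 landmark configurations
   (translation, rotation and size removed; reflections never allowed),
   with tangent-space PCA.
2. **Allometric regression** of shape on log10 centroid size per species,
   with residual-randomization permutation inference (RRPP): multivariate
   F, permutation p, and effect size Z = (ln F − mean ln F*)/sd ln F*.
   Two trajectory scores are extracted: the **common allometric component**
   (CAC), the unit direction of size-associated shape change, and
   **PredLine** ("multivariate shape"), PC1 of the fitted values.
3. **Gompertz shape-growth curves** f(x) = c + (d−c)·exp(−exp(−k(x−x₀)))
   of score versus straight carapace length (SCL), and two adult-size
   thresholds: the size where the curve crosses the Wald lower 90%
   confidence bound of the asymptote d (closed-form inversion), and the
   size where 85% of the Procrustes distance between the smallest-specimen
   shape and the shape at the largest recorded SCL is covered. Thresholds
   are reported as % of the species' maximum recorded SCL.
4. **Ontogenetic staging** (Ward clustering of score + SCL into
   small/intermediate/large) and **stage-wise disparity** — sum of ranges
   on PC scores (bootstrapped and rarefied) and Procrustes variance —
   compared with Zou's overlapping confidence-interval test, Bonferroni
   corrected.
5. A **synthetic growth-series generator** with closed-form ground truth,
   so the entire pipeline is testable without any external data.

## Worked example

Simulate a ten-species panel with planted adult-shape thresholds spanning
55–75% of maximum SCL, run the whole pipeline, and compare:

```r
library(shellont)

panel <- generate_panel(default_panel_profiles(10), seed = 2026)
cfg <- pipeline_config(dataset = panel$dataset, max_table = panel$max_table,
                       n_perm = 999, n_boot = 1000, seed = 2026)
res <- run_pipeline(cfg)

subset(res$summary, proxy == "cac")
#>   proxy n_species median_pct  min_pct  max_pct asym_mean_pct ...
#> 1   cac        10   64.64186 54.82273 75.97356      91.86674 ...

head(res$allometry, 3)
#>                        species  n        r2        f        z     p
#> Simulatus sp01  Simulatus sp01 14 0.7666063 39.41526 4.143205 0.001
#> Simulatus sp02  Simulatus sp02 22 0.7230554 52.21662 4.834951 0.001
#> Simulatus sp03  Simulatus sp03 29 0.7618548 86.37620 5.370775 0.001
```

The CAC-based 85%-distance thresholds land at a median of 64.6% of maximum
recorded carapace length (range 54.8–76.0%), recovering the planted truths
(median 65%) to well under one percentage point; every species shows
significant allometry at p = 0.001, the smallest value 999 permutations can
resolve. `res$thresholds` holds the per-species thresholds in mm and %,
`res$stages` the ontogenetic stage of every specimen, and `res$disparity` /
`res$zou` the stage-wise disparity with its pairwise tests — on this panel
shell-shape disparity rises from juveniles to adults and the small stage
separates significantly from the large one.

The same analysis, stage by stage with tables written under `results/`, is
scripted in `analysis/01_simulate.R` … `analysis/05_disparity.R`.

Reading real data instead of simulating it:

```r
cfg <- pipeline_config(landmarks = "landmarks.tps",    # LM3= blocks, ID= keys
                       metadata = "metadata.tsv",      # specimen_id, species, sex, scl_mm
                       max_sizes = "max_sizes.tsv",    # species, max female/male SCL
                       exclude_species = c(...),       # dimorphism artefacts etc.
                       dimorphic = c("Some species" = "female"))
res <- run_pipeline(cfg)
```

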