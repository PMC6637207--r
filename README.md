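# smatkit

Quantification of actin cytoskeleton turnover from fluorogenic-probe
time-lapse imaging.

SiR-actin (SA) is a cell-permeable probe that fluoresces only while bound
to filamentous actin; when filament turnover strips it off, its
fluorescence drops more than 100-fold. The field-level decay of SA
intensity after washout is therefore a live, label-efficient readout of
actin turnover — fast enough to separate mesenchymal stem cell (MSC)
populations under adipogenic (AD), chondrogenic (CH), osteogenic (OS) and
basal (BA) media within minutes to hours, and to flag the slower turnover
of in-vitro aged cells. `smatkit` implements the complete computational
side of that workflow:

* **Binding-kinetics model** — the reversible ligand–receptor scheme
  `L + R <-> C` with excess binding sites gives

  * dissociation: `dC/dt = kf_d (C0 − C) − kr C`, `kf_d = kf · R_T`
  * association:  `dC/dt = kf_d L_T − kr C`

  solved in closed form, and fitted sequentially by deterministic
  multi-start least squares: `(kf_d, kr)` from the decay curve, then
  `L_T` from the association curve with the rates held fixed. Because
  `kf` and `R_T` enter only as a product, the lineage-discriminating
  summary is the ratio `kr / kf_d` (smaller = slower turnover).
* **SMAT quantification** — per-frame mean gray value of each imaged
  field, normalization of every trace to its first (post-wash) timepoint,
  ratiometric mean ± SEM per condition, and per-timepoint
  condition-vs-reference contrasts from a two-way ANOVA with Bonferroni
  correction across timepoints (with a media-switch mode that
  re-references curves to the switch frame).
* **Dual-stain high-content analysis (HCIA)** — nuclei-seeded Otsu
  segmentation of SA + phalloidin images, a versioned 41-descriptor set
  (9 shape, 6 intensity, 2 × 13 gray-level co-occurrence texture
  statistics), canonical linear discriminant analysis with percent
  correctly classified, Wilks' lambda with the approximate `p_F`, 50%
  canonical contour ellipses, and bootstrap-forest predictor ranking.
* **Synthetic data with ground truth** — deterministic generators for
  noisy kinetic traces, rendered multi-page TIFF time-lapse stacks
  (textured elliptical cells over a ≤1% detached-probe background), and
  dual-channel single-cell populations whose between-condition divergence
  grows along a schedule of effect sizes. Every generated dataset ships
  with its generating parameters, so the whole pipeline is testable
  closed-loop.

## Worked example

Simulate the tri-lineage induction design (3 replicate wells × 2 fields,
16 frames over 14 h), quantify the stacks, and fit the binding model:

```r
library(smatkit)

scn <- scenario_preset("lineage", seed = 42, frame_size = 256,
                       cells_per_field = 9, cell_size_range = c(9, 14),
                       n_replicates = 3, n_fields = 2)
run_simulate(scn, "demo/sim")
res  <- run_smat("demo/sim/manifest.csv", "demo/smat", reference = "BA",
                 background = "manifest", seed = 42)
fits <- run_fit("demo/smat/curves.csv", "demo/fit", seed = 42)
print(fits, digits = 3)
#>   condition    kf_d      kr L_T kr_over_kf_d      sse converged
#> 1        AD 0.00397 0.00379  NA        0.953 0.001039      TRUE
#> 2        BA 0.00200 0.01999  NA        9.997 0.000735      TRUE
#> 3        CH 0.00295 0.00882  NA        2.985 0.000523      TRUE
#> 4        OS 0.00187 0.01749  NA        9.377 0.000557      TRUE
```

The generating rates were AD (0.004, 0.004), CH (0.003, 0.009),
OS (0.002, 0.018), BA (0.002, 0.020): the pipeline recovers them from the
rendered pixels to within a few percent, and the fitted `kr/kf_d` ratios
(≈1, 3, 9, 10) rank the conditions by turnover — adipogenic slowest. The
per-timepoint contrasts at the final frame show the same picture: AD and
CH retain significantly more probe than basal medium, OS does not:

```r
subset(res$comparison$table, time_min == 840)
#>    condition time_min   diff         p     p_adj stars
#> 15        AD      840 0.4213 1.49e-115 2.24e-114   ***
#> 30        CH      840 0.1544  8.60e-34  1.29e-32   ***
#> 45        OS      840 0.0121  2.83e-01  1.00e+00
```

For the single-cell arm, `run_hcia(scn, "demo/hcia")` generates dual-stain
populations at each schedule timepoint and writes the feature tables,
confusion matrices, contour ellipses and predictor rankings; 4-way
percent-correct rises along the divergence schedule while the binary
condition-vs-basal classifiers stay ahead of it.

A command-line wrapper over the same runners is available at
`inst/scripts/smat.R` (subcommands `simulate`, `smat`, `fit`, `hcia`,
`report`).

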