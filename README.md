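# qpaintr

Quantitative DNA-PAINT (qPAINT) molecular counting and nanocluster
analysis in R.

## The problem

DNA-PAINT super-resolution microscopy localizes single molecules through
the repeated, transient binding of dye-labelled "imager" DNA strands to
antibody-coupled "docking" strands. Each target protein therefore appears
as a cloud of localizations, and the blinking statistics carry
quantitative information: the waiting time between binding events (the
dark time, τ_OFF) shortens in proportion to the number of docking strands
present,

```
N = (k_ON · [I] · τ_OFF)^-1 = τ_OFF,1 / τ_OFF ,
```

where k_ON is the imager association rate, [I] the imager concentration
and τ_OFF,1 the single-site dark time. qPAINT exploits this to count how
many proteins reside in each localization cluster. `qpaintr` implements
the complete analysis chain for membrane-receptor nanocluster studies —
from a drift-corrected localization table to calibrated protein-copy-number
maps and per-ROI cluster statistics — together with a synthetic DNA-PAINT
generator with known ground truth, so that every stage can be validated by
parameter recovery without microscope data.

The pipeline stages (in fixed order):

1. **Quality filter** — remove localizations with uncertainty > 13 nm.
2. **ROI selection** — 3.5 × 3.5 µm regions (seeded random sampling).
3. **DBSCAN** — eps from the NeNA localization precision (~10 nm),
   minPts from Poisson statistics of the expected localizations per
   docking strand (`N_frames · τ_bright · k_ON · [I]`, 40 at the default
   acquisition settings, giving minPts = 15).
4. **Mean-frame filter** — clusters whose temporal centre of mass falls
   outside mean ± SD of the per-cluster mean-frame distribution are
   discarded as nonspecific (a persistent site averages ~half the
   acquisition, 7,500 of 15,000 frames).
5. **Dark times & qPAINT index** — per cluster, empty-frame gaps are
   fitted with the exponential CDF `1 − exp(−t/τ_d)`; the qPAINT index is
   `q_i = 1/τ_d`.
6. **Calibration** — the q_i histogram of spatially small clusters
   (< 100 nm extent) is fitted with a multi-peak Gaussian whose centres
   are integer multiples of the single-protein index `q_i1`.
7. **Counting & partitioning** — `N = round(q_i/q_i1)` proteins per
   cluster; k-means (k = N) converts each cluster into protein positions.
8. **Summaries** — protein and cluster densities, % clustered proteins
   (clusters = groups of ≥ 3), small/<6 / medium/6–12 / large/>12 class
   counts, equivalent diameters and first-neighbour distances per ROI.

## Worked example

```r
library(qpaintr)

acq <- acquisition_params()   # 15,000 frames x 100 ms, 130 nm px, 9 nm
kin <- kinetics_model()       # k_on 1e7 /M/s, 1 nM imager, 0.27 s bright
expected_localizations_per_site(acq, kin, floor = TRUE)
#> [1] 40
min_points_from_poisson(40)
#> [1] 15

cfg <- qpaint_config()        # 23 proteins/um^2, 44% clustered, 3.5 um ROI
sim <- simulate_dna_paint(cfg$generator, acq, kin, seed = 42)
sim$truth
#> Ground-truth map: 282 proteins in 12.2 um^2 (23.0 /um^2), 22 clusters, 44.0% clustered

res <- analyze_roi(sim$locs, cfg)
res$calibration
#> qPAINT calibration: q_i1 = 0.01156 Hz (multi_gauss, counting precision +/- 0.36 proteins)
round(res$summary, 2)
#>   n_proteins protein_density n_clusters cluster_density pct_clustered n_small
#> 1        203           16.57         14            1.14         42.36       8
#>   n_medium n_large median_eq_diameter median_first_neighbour
#> 1        5       1               65.6                  22.08
```

Reading the output: 40 localizations are expected per docking strand at
these acquisition settings, which fixes DBSCAN's minPts at 15. The
simulated resting-state ROI holds 282 proteins (23.0/µm², 44% in
clusters). The pipeline's own calibration finds a single-protein qPAINT
index of 0.0116 Hz and a counting precision of ±0.36 proteins; the
recovered clustered fraction (42.4%) closely tracks the planted 44%. The
recovered density (16.6/µm²) is systematically below truth because the
mean ± SD mean-frame band — by construction — also removes a fraction of
genuine clusters; see the methods vignette for the quantitative analysis
of this attrition.

File-based runs with manifests and per-stage logs:

```r
run_simulate(cfg, "run1")                          # CSV + ground truth + manifest
run_analyze("run1/localizations.csv", cfg, "out1") # per-cluster + per-ROI CSVs
```

or from a shell via the thin wrapper `inst/scripts/qpaint-cli.R`
(`simulate`, `analyze`, `config` verbs).

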