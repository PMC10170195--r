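---
title: "qPAINT counting and nanocluster analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qPAINT counting and nanocluster analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpaintr)
```

## The counting model

DNA-PAINT blinking is binding-kinetic, not photophysical: a docking
strand is dark until a diffusing imager strand binds (rate
`k_ON · [I]`, units s⁻¹) and bright for an exponential dwell with mean
`τ_bright`. For a localization cluster containing `N` docking strands the
observed dark times are exponential with mean

τ_OFF = (N · k_ON · [I])⁻¹,

so `N = τ_OFF,1 / τ_OFF = q_i / q_i1` where `q_i = 1/τ_d` is the
cluster's qPAINT index and `q_i1` the index of a single protein. The
entire pipeline reduces to estimating `τ_d` well per cluster and `q_i1`
well once.

Two properties follow directly and are covered by tests: indexes are
additive over merged independent sites, and longer acquisitions shrink
the spread of `τ_d` estimates, so counting precision is acquisition-time
limited, not photobleaching limited.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `n_frames`, `frame_time` | 15,000 × 0.1 | frames, s | standard TIRF DNA-PAINT acquisition; 25 min total |
| `pixel_size` | 130 | nm | camera pixel in the focal plane |
| `k_on` | 1e7 | M⁻¹s⁻¹ | typical for optimized imager sequences |
| `imager_conc` | 1e-9 | M | standard working concentration |
| `tau_bright` | 0.27 | s | measured dwell of the imager-docking duplex |
| `loc_precision_sigma` | 9 | nm | per-axis precision achievable at this SNR |
| `max_uncertainty` | 13 | nm | conventional quality cut for DNA-PAINT tables |
| `eps` | 10 | nm | NeNA precision rounded to nm |
| `min_pts` | 15 | — | Poisson tail at the 40 locs/site planning mean |
| `calibration_max_extent` | 100 | nm | single-protein clusters are spatially compact |
| `linking_radius` | 60 | nm | see "Grouping proteins" below |
| `min_cluster_size` | 3 | proteins | minimum size that counts as a cluster |

`min_points_from_poisson()` formalizes the minPts choice: localization
counts per docking strand are treated as Poisson around the planning mean
`N_frames · τ_bright · k_ON · [I]` (40.5 at the defaults, floored to 40),
and minPts is the largest `m` whose lower tail `P(X ≤ m − 1)` stays below
`tail_epsilon`. The frozen default `tail_epsilon = 5e-6` makes the
planning mean of 40 yield the conventional minPts of 15; the exact-CDF
scan is tested against a brute-force oracle. The threshold grows with the
mean and shrinks as `tail_epsilon → 0`.

## The synthetic generator

`simulate_protein_map()` plants `Poisson(density × area)` proteins:
a target fraction in clusters whose sizes are drawn from a
small (3–5) / medium (6–12) / large (13–20) mixture — default weights
0.70/0.25/0.05, a small-dominated composition typical of resting
membranes — and the rest as uniform monomers. Cluster members scatter as
an isotropic Gaussian (SD `cluster_radius_scale`, default 40 nm, which
places intra-cluster first-neighbour distances in the few-tens-of-nm
regime observed for membrane glycoprotein nanoclusters); a uniform-disc
option exists because the true in-cell scatter model is unknown — we make
no claim of biological fidelity beyond these two standard choices.

`simulate_binding_timeseries()` draws the alternating dark/bright renewal
process per site in continuous time and discretizes bright events to
frames. Three discretization models are provided:

* **`round`** (default): an event of duration `d` occupies
  `max(1, round(d / frame_time))` consecutive frames. Every binding event
  is detected, so the observed event sequence mirrors the underlying
  kinetics exactly — the right default for validating dark-time
  estimation, and consistent with practice, where even sub-frame events
  deposit enough photons to be localized.
* **`fractional`**: partially covered edge frames are detected with
  probability equal to their covered fraction. This is the
  photon-budget-limited model: the expected localization count per site
  equals the planning formula exactly (the package tests verify the
  match within Monte-Carlo error), at the price of missing ~19% of
  events (mostly sub-frame ones), which inflates observed dark times by
  ~20%.
* **`overlap`**: every overlapped frame counts; an upper bound (~55
  locs/site at the defaults).

The three models bracket reality; `round` preserves kinetics, so it is
the study default, while `fractional` is the one that reproduces the
planning arithmetic. No model can do both: matching the planning product
in expectation forces sub-frame events to be droppable.

Background is a uniform spatio-temporal Poisson field of single-frame
localizations (default 0.01 µm⁻²frame⁻¹, a few percent of signal). Note
what this does **not** emulate: transient nonspecific *sites* that
accumulate many localizations. Consequently DBSCAN almost never forms
background clusters, which matters for the mean-frame filter (below).
Localization error is isotropic Gaussian (`loc_precision_sigma` per
axis); reported per-row uncertainties are drawn from a truncated Gaussian
so the 13 nm filter has realistic input. A k-frame event yields k rows —
no temporal merging, matching the convention of the upstream localization
software. Drift is not simulated (tables are assumed drift-corrected
upstream).

All randomness flows from one master seed through labelled child seeds
(`derive_seed`), so stages are independently reproducible and outputs are
byte-identical across runs.

## Dark-time estimation

Dark times are the runs of empty frames between a cluster's event frames,
times `frame_time`. Two boundary conventions matter:

* **Censored edges.** The intervals before the first and after the last
  event are censored draws; including them would bias `τ_d` upward, so
  they are excluded.
* **CDF fit.** `fit_dark_time()` least-squares fits the empirical CDF
  (plotting positions `(i − ½)/n`, every gap its own abscissa — no
  binning parameter) to `1 − exp(−t/τ_d)`. The exponent is negative, as
  it must be for a CDF; with fewer than 5 gaps the sample mean is used
  and flagged. A degenerate all-identical gap list returns that value
  exactly.

Three small biases are inherent to this estimator chain and are worth
knowing when interpreting absolute indexes (they cancel in the
calibrated *ratio* to first order): complete gaps inside a finite
acquisition are on average ~`τ_OFF/T_total` too short (~6% for monomers
at the defaults); inverting a noisy `τ̂_d` adds ~`+1/n_gaps` to the
index; and the least-squares CDF fit emphasizes the window-clipped bulk.
The package's own calibration on default-kinetics synthetic data
accordingly lands near 0.012–0.013 Hz although `k_ON·[I]` is 0.01 Hz —
the same ~20% inflation that measured single-protein indexes show over
their kinetic prediction in real experiments. This is why qPAINT
calibrates empirically instead of using `(k_ON · [I])⁻¹` directly.

At high copy numbers two further effects appear: simultaneously bright
sites hide each other's events, and frame quantization merges sub-frame
gaps. Both shorten the *apparent* event sequence, so counts saturate
gently: recovery is within ±1 for ≥ 80% of clusters up to about 6 sites
(100% at ≤ 4) and the mean still tracks the planted number within ~15%
at 12 sites. Plan calibration populations accordingly: they should be
dominated by monomers and small oligomers.

## Calibration

`calibrate_qpaint()` histograms the indexes of spatially small clusters
(max pairwise extent < 100 nm) and fits `K ≤ 4` Gaussians with centres
constrained to integer multiples of a shared fundamental. Design choices
that proved necessary:

* The fundamental is seeded from the **first substantial local mode** of
  a kernel density estimate, and refined by multi-start over fundamentals
  at and below that mode (× 1, 0.85, 0.7, 0.55). Starting only at the
  global mode fails when monomer and dimer peaks blend; and a *halved*
  fundamental must never be offered as a free alternative, because with
  free amplitudes it nests the true model and always wins on residuals.
  Within each start the fundamental is bounded to ±30%, and candidate
  solutions whose first peak carries < 15% of the fitted mass are
  rejected as implausible fundamentals before residual-based selection.
* The histogram covers only `[0, (K + 2.5) · mode]` with a bin count that
  grows as `2√n`: a handful of very large clusters would otherwise
  stretch the bins and blur the fundamental peak.
* Peak SDs are per-peak free; amplitudes are non-negative.

The counting precision is reported as `σ₁/q_i1` in protein units
(typically ±0.3–0.4 proteins at the default acquisition length). A
percentage-style precision figure is deliberately not emitted — its
definition is ambiguous — and `count_proteins()` rounds the index ratio
to the nearest integer (halves away from zero, floor at 1).

## Localization precision (NeNA)

Because events span several frames, the same emitter is localized
repeatedly; the distance between a localization and its nearest
neighbour in the *next* frame is distributed as the 2D displacement
p(d) = (d/2σ²)·exp(−d²/4σ²) for per-axis precision σ. `nena_precision()`
fits this density plus a linear background term to the histogram of
adjacent-frame nearest-neighbour distances (cap 200 nm to exclude
cross-cluster pairs). One background term suffices up to ~20% uniform
contamination (tested); the estimator is unbiased within 10% across
σ ∈ {5, 9, 15} nm. The estimate, rounded to the nearest nm, is the
recommended DBSCAN `eps`. The degenerate all-coincident case falls back
to the method-of-moments limit `σ = √(E[d²]/4)`.

## The mean-frame filter and its cost

Specific, persistent docking sites are revisited throughout the
acquisition, so their localization mean frame concentrates near
mid-acquisition; nonspecific signal clusters early or late. The filter
fits a Gaussian to the per-cluster mean-frame distribution — via the
sample mean and SD, which is the large-n limit of a histogram fit without
a binning choice — and keeps clusters within ±1 SD.

This band has a structural cost that users of the pipeline should know.
When the detected clusters are *all* genuine (as in our synthetic fields,
whose single-frame background cannot form clusters), the mean-frame
distribution is approximately Gaussian, and a mean ± 1 SD band retains
~68% of it by construction. The per-cluster summaries therefore
undercount absolute densities by roughly a third at the default
acquisition settings, while *composition* statistics (clustered fraction,
size-class proportions) are far less affected because the attrition hits
single-site and clustered parents alike. In real data the band is wider
relative to the genuine peak — the nonspecific subpopulation inflates the
fitted SD — so the attrition is milder, but absolute densities from this
pipeline remain conservative. We keep the ±1 SD convention because it is
the established protocol; the filter's `mu`/`sigma` and rejection counts
are logged per run so the attrition is always visible.

## Partitioning and grouping

`kmeans_partition()` splits each counted cluster into `N` protein
positions (k-means++ seeding, 5 restarts, best inertia, deterministic
given the seed; degenerate clusters pad with the centroid and are
flagged). Proteins from one localization cluster are never split across
protein clusters. Across localization clusters, `group_proteins()`
single-links protein positions within `linking_radius`; groups of ≥ 3
are protein clusters. The default radius of 60 nm sits between the two
natural scales of the problem: intra-cluster first-neighbour distances
(~25–40 nm at the generator's 40 nm scatter) and the monomer background
spacing (~140 nm at ~13 monomers/µm²), near their geometric mean. The
"equivalent diameter" of a protein cluster is the diameter of the circle
matching the convex-hull area of its member *localizations* (not the
k-means centroids, which would underestimate the physical footprint);
the hull of protein positions is available as an alternative.

Cluster size classes — small < 6, medium 6–12 (inclusive), large > 12 —
partition the sizes exhaustively; groups below 3 count as unclustered.
Size-class counts are reported per ROI as absolute counts over the fixed
12.25 µm² area; densities are also available. First-neighbour distances
are computed among protein positions within the ROI, without edge
correction (ROIs are large relative to the distances involved). The cell
`morphology_index()` (perimeter²/4π·area, 1 for a circle) is included for
the accompanying cell-shape workflow.

## Validation scale and what it shows

The test-suite and the acceptance script run on one CPU in about a
minute: recovery runs use 10–20 ROIs of 3.5 × 3.5 µm at 23 proteins/µm²
(~280 proteins, ~12,000 localizations each), calibration populations of
300–2,500 clusters, and ≥10⁴-event kinetics checks. Passing these
synthetic-recovery tests demonstrates that the estimator chain is
self-consistent under the generative model — two-state kinetics, Gaussian
localization error, single-frame background. It does not certify
performance under real-data pathologies the generator omits: residual
drift, sticky nonspecific sites, variable epitope labelling efficiency,
or partially bound antibody stoichiometry. Absolute densities are
conservative (see the mean-frame section); ratios and composition
statistics are the robust outputs.

## Known limitations

* Copy-number recovery saturates above ~6 sites per cluster (±1 accuracy)
  though means track to ~12; reported large-cluster sizes are mild
  underestimates.
* The density cost of the ±1 SD mean-frame band is not compensated; users
  comparing absolute densities across conditions should verify the
  rejection counts are comparable.
* Calibration assumes a monomer-dominated small-cluster population; if
  monomers are rare, the fundamental may lock onto a higher multiple.
* 2D only; no Picasso-HDF5 reader (CSV interchange, including a
  camera-pixel dialect); drift is assumed corrected upstream.
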