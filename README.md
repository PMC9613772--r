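# ktrfate

Linking single-cell ERK/Akt kinase-translocation-reporter (KTR) dynamics
to cell-division fate.

## What this package is for

In a quiescent epithelial population stimulated with growth factors,
only some cells go on to divide within 48 h. Live-cell KTR imaging reads
each cell's ERK and Akt activity over time as the cytoplasm-to-nucleus
fluorescence ratio (**C/N ratio**): active kinase phosphorylates the
reporter and pushes it into the cytoplasm, so higher C/N means higher
activity. `ktrfate` implements the full computational chain that turns
such movies into statements about division fate, for analysts who want a
tested, scriptable version of this workflow:

* **quantification** — illumination correction, nuclear segmentation, a
  10-px perinuclear "cytoring" as the cytoplasmic sampling region, and
  per-cell C/N = mean ring / mean nuclear intensity;
* **tracking** — optimal centroid assignment per frame pair with a
  displacement gate, plus the conservative full-duration track filter;
* **division detection** — a division appears as a steep transient C/N
  drop (relative drop > 35% within ≤ 2 frames, prominent dip); traces
  are truncated 5 frames before the detected peak and cells classified
  dividing / non-dividing / excluded;
* **statistics** — per-cell median activity in the 8.5–40 h (S–G2)
  window; right-tailed Wilcoxon rank-sum between fates; logistic
  regression `P(divide) = logit⁻¹(β₀ + β_E·medERK + β_A·medAkt)`;
  pooled ERK–Akt Pearson correlation per fate class with a
  multivariate-normal resampling band (1000 reps, 5th–95th percentiles,
  ends rounded up to 0.01); and a perturbation-based two-node crosstalk
  test (effect of inhibiting one kinase on the other's trajectory, with
  cell-level bootstrap CI and a practical-significance floor);
* **synthetic data** — a seeded generator of ground-truth activity
  dynamics and rendered movies (division drop included), so the whole
  chain is testable end to end without external data.

No external dataset is required anywhere: the generator defines the
study conditions, and every stage is validated against its ground truth
or an independent oracle.

## Worked example

Simulate the default study (300 cells, 48 h at 15-min sampling, growth
factor at 1 h, half the cells dividing between 16 and 36 h), run the
trace-level pipeline and the statistics:

```r
library(ktrfate)

cfg <- sim_config(n_cells = 300, seed = 1)
pop <- simulate_cell_population(cfg)
res <- run_trace_pipeline(pop$traces)
feat <- res$features

ranksum_right(feat$median_erk[feat$divided],
              feat$median_erk[!feat$divided])$p_value
#> [1] 2.008863e-41

fit_division_logit(feat)$coefficients
#>         term   estimate std_error         z            p
#> 1  intercept -33.756387  4.247297 -7.947735 1.899528e-15
#> 2 median_erk  17.046679  2.117519  8.050306 8.258753e-16
#> 3 median_akt   8.384754  1.891169  4.433636 9.265689e-06

pts <- pooled_points(res)
pooled_pearson(pts$dividing$erk, pts$dividing$akt, "dividing")$r
#> [1] 0.1264321
pooled_pearson(pts$nondividing$erk, pts$nondividing$akt, "non-dividing")$r
#> [1] 0.3504813
```

Reading the output: dividing cells have clearly higher windowed median
ERK activity (right-tailed rank-sum p ≈ 1e-41); in the joint logistic
model the ERK coefficient is about twice the Akt one with a far smaller
p-value, i.e. ERK dynamics are the stronger correlate of division; and
the pooled ERK–Akt correlation is markedly lower in dividing cells
(0.13 vs 0.35) — the generator's built-in class difference in kinase
coupling, recovered through detection, truncation and pooling.

The numbered scripts under `analysis/` run the same study as a
narrative workflow — `01_simulate.R` (population + demo movie),
`02_quantify.R` (C/N accuracy under noise and shading; median error
~0.2%), `03_track_detect.R` (tracking accuracy 1.0, detection
sensitivity 1.0 / false-positive rate 0.0 at default conditions),
`04_statistics.R` (the numbers above, plus figures),
`05_crosstalk.R` (both cross-edges absent, both positive controls
present) — and write their tables under `results/`.

## Package layout

```
R/                  implementation (simulation, rendering, imaging,
                    tracking, division detection, statistics, IO)
src/                one Rcpp kernel (column medians for the bootstrap)
analysis/           numbered workflow scripts (01..05)
scripts/acceptance.R  from-scratch recomputation of the study numbers
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette (model, parameters, design choices)
```
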