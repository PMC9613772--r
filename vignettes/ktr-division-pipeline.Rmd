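---
title: "Linking single-cell ERK/Akt KTR dynamics to division fate: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking single-cell ERK/Akt KTR dynamics to division fate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ktrfate)
```

# The measurement and the question

Kinase translocation reporters (KTRs) convert kinase activity into a
spatial readout: phosphorylation of the reporter shifts it from the
nucleus to the cytoplasm, so the ratio of cytoplasmic to nuclear
fluorescence (the **C/N ratio**) tracks the activity of the upstream
kinase in each cell at each frame. Following growth-factor stimulation
of a quiescent epithelial population, some cells divide within 48 h and
some do not. The question the pipeline addresses is whether features of
single-cell ERK and Akt activity dynamics — summarized as the per-cell
median C/N within the 8.5–40 h post-stimulus window, the S–G2 interval —
are associated with that binary division fate, and whether the two
kinases interact as a signaling network.

The pipeline has five stages, each a module of this package:

1. **Synthetic data** (`sim_config()`, `simulate_cell_population()`,
   `render_timelapse()`, `write_fixture()`): ground-truth activity
   dynamics and rendered movies, so every downstream stage can be
   validated against known truth.
2. **Imaging** (`correct_illumination()`, `segment_nuclei()`,
   `build_cytoring()`, `measure_cells()`): per-frame C/N quantification.
3. **Tracking** (`link_tracks()`, `filter_full_duration()`): persistent
   single-cell identities across frames.
4. **Division detection** (`detect_division()`, `truncate_trace()`,
   `classify_fates()`): automatic calling of division events from the
   C/N drop signature, trace truncation, and fate labels.
5. **Statistics** (`window_median()`, `ranksum_right()`,
   `fit_division_logit()`, `pooled_pearson()`,
   `correlation_null_band()`, `crosstalk_effect()`): the analysis
   proper.

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

# The synthetic-data generator

## Activity model

Each cell's latent activity per channel is

$$a(t) = b + (P - b)\,\sigma\!\left(\frac{t - t_{gf} - 5\tau}{\tau}\right) + \varepsilon_t,$$

a baseline $b$ (default 0.4 C/N units) rising logistically after
growth-factor addition at $t_{gf}$ (default 1 h; rise time constant
$\tau$ = 0.15 h, so the plateau is reached within ~1.5 h of stimulus) to
a plateau $P$, plus stationary AR(1) noise $\varepsilon_t$ with marginal
standard deviation `noise_sd` (default 0.1) and autocorrelation
`ar_coeff` (default 0.8; C/N fluctuations are strongly autocorrelated at
15-min sampling). The plateau is

$$P = P_0 + \delta_{\text{class}} + u,$$

where $P_0$ = 1.2 (`plateau_median_nondiv`), $\delta$ is the class
effect (`effect_size`, default ERK +0.3 and Akt +0.15 for dividing
cells — the ERK association with division is the stronger one), and $u$
is a per-cell offset with sd `cell_sd` = 0.12, independent across
channels.

Three features of this design deserve justification:

* **Per-cell heterogeneity** (`cell_sd`) is what makes the two fate
  classes overlap in their windowed medians, as real single-cell data
  do. Without it the time-averaged noise shrinks as
  $1/\sqrt{n_\text{frames}}$ and the classes separate almost perfectly,
  which quasi-separates any logistic fit.
* **Independence of the offsets across channels** means one channel's
  median carries no division information beyond the other's true
  effect. A correlated alternative was considered and rejected: it
  turns the weaker channel into a significant negative suppressor in
  the bivariate logistic regression, an artifact of the generator
  rather than a property of the modeled biology.
* **Correlation targets act on the innovations.** The per-frame ERK/Akt
  innovations are bivariate normal with correlation `rho_div` (default
  0.3) in dividing and `rho_nondiv` (0.7) in non-dividing cells. The
  *pooled* cell-by-time correlation equals these targets only when the
  plateau is noise-dominated (`cell_sd = 0`); with the default
  heterogeneity the uncorrelated cell variance dilutes the pooled
  coefficients (to roughly 0.1 and 0.35), but the class *ordering* —
  lower coupling in dividing cells — is preserved, and that ordering is
  the scientific claim being reproduced.

Dividing cells (exactly `round(frac_dividing * n_cells)` of them) carry
one division time drawn uniformly from `division_window_h` (default
16–36 h, inside the S–G2 analysis window). At division the *observed*
C/N is multiplied by `1 - drop_frac` (default 0.5) for
`drop_span_frames` (default 2) frames — the steep transient drop the
mitotic morphology change produces — after which the trace continues as
the tracked daughter. Pulsatile activity is available
(`pulsing = TRUE`) but off by default: the emulated system shows
sustained, non-pulsatile activation, and no pulse parameters are
reported for it.

## Renderer

Movies are rendered as a nuclear-marker channel (filled disks, radius 8
px) plus KTR channels in which a fixed per-pixel intensity budget $T$ is
split between the nuclear disk, $T(1-\varphi)$, and a cytoplasmic
annulus (outer radius 20 px), $T\varphi$, with
$\varphi = \mathrm{cn}/(1+\mathrm{cn})$ clipped to $[0.05, 0.95]$ so
both compartments always carry signal. Mean annulus over mean nuclear
intensity then equals the ground-truth C/N exactly. At division the
nucleus splits into two daughters displaced by $\ge 2 r_{\text{nuc}}$.
Frames are optionally blurred (`psf_sigma_px`), shaded by a smooth
unit-mean flatfield ($1 + A f(x,y)$, a cosine dome), offset by a camera
background and corrupted by Gaussian noise.

`psf_sigma_px` defaults to 0. The renderer's purpose is ground-truth
anchored validation of the quantification chain, and optical blur mixes
compartment intensities at the nucleus/cytoplasm and annulus/background
boundaries, confounding that anchor; blur is exercised separately in the
unit tests. What the renderer deliberately does **not** emulate: cell
crowding and confluency, photobleaching, shot-noise statistics,
three-dimensional structure, and segmentation-hostile morphologies.
Passing tests on these movies therefore validate the *computational
chain* — segmentation geometry, ring construction, ratio arithmetic,
correction algebra, tracking and detection logic — not robustness to
every real-microscopy pathology.

# Imaging

Correction order matters: the camera offset is additive *after* the
multiplicative shading, so background subtraction precedes flatfield
division. The background estimator is the median of the pixel
intensities after excluding the brightest 10% (a mode-like estimate of
the cell-free background). A low-percentile estimator was rejected: with
symmetric noise of sd $\sigma$ a 5th-percentile estimate sits
$1.64\sigma$ below the true offset, and that residual offset biases the
C/N ratio by several percent.

Nuclear segmentation is a classical stand-in (Otsu threshold, hole
filling, optional distance-transform watershed, area filter) for the
original study's trained pixel classifier; every downstream function
accepts external label masks, so a learned segmenter can be dropped in.

The **cytoring** — the cytoplasmic sampling region — is the set of
pixels within 10 px (Euclidean) of a nucleus, excluding all nuclear
pixels, each pixel assigned to its nearest nucleus with ties going to
the lower label. The implementation compares exact integer squared
distances within dilated bounding boxes, so it is bit-identical to a
brute-force per-pixel oracle (property-tested on random masks, and part
of the acceptance suite at 200 masks). C/N is the mean ring intensity
over the mean nuclear intensity; cells with empty rings (possible at
image borders) are flagged, not dropped.

# Tracking

Frame-to-frame linking is an optimal one-to-one assignment on centroid
distance (a compact Hungarian solver, property-tested against
permutation enumeration) with a hard gate `max_disp_px` (default 25 px);
links beyond the gate are never made. Unmatched current labels start
tracks; unmatched previous tracks terminate; there is no gap closing —
the full-duration filter then removes transient tracks, which is the
conservative choice the emulated pipeline made. After a division the
track continues as the nearer daughter and the other daughter starts a
new track; since traces are truncated before the division anyway, this
choice does not affect the statistics.

# Division detection

A division appears as a relative C/N drop
$(\mathrm{cn}_{p-s} - \mathrm{cn}_p)/\mathrm{cn}_{p-s} > f_{\min}$
(default $f_{\min}$ = 0.35) over a span $s \le 2$ frames, with dip
prominence above 0.2 C/N units. The earliest qualifying candidate wins
(one division per cell is analyzed). Secondary checks flag rather than
drop: a drop that recovers immediately (`SPURIOUS_CANDIDATE`) and a peak
within 5 frames of trace start (`NEAR_START`); flagged calls go to a QC
report — the programmatic analogue of the original study's manual
review — and the cell is excluded.

Detection is gated to frames after 2 h post-start (`earliest_frame` =
8): a *relative* drop criterion is ill-defined while C/N is near
baseline, where noise excursions of ~0.25 on a 0.4 level exceed 35%,
and no cell completes S and G2 within 2 h of stimulation, so the gate
costs no sensitivity. The thresholds were fixed once by calibration on
the synthetic ensemble (the original pipeline used a generic peak finder
plus manual curation and reports no thresholds) and are fully exposed in
`detect_params()`.

Accepted calls truncate the trace 5 frames before the peak — the
terminal frames reflect mitotic morphology, not kinase activity. Cells
with no call are non-dividing only if present 48 h (15-min sampling) or
at least 41.67 h (5-min sampling); the comparison carries a half-frame
tolerance because 41.67 h is the rounded value of 500 five-minute
frames. Everything else is excluded with a reason code.

# Statistics

* **Windowed medians.** Per-cell median C/N over frames with
  $8.5 \le t \le 40$ h (inclusive), restricted to the truncated trace;
  at least 10 in-window frames are required, otherwise the median is
  absent (the spec of the original analysis is silent on truncated-trace
  minimums; 10 frames = 2.5 h of data is the package's choice).
* **Rank-sum.** Right-tailed Wilcoxon rank-sum of dividing vs
  non-dividing medians: exact enumeration for $n_x + n_y \le 12$ without
  ties, otherwise the normal approximation with tie correction and
  continuity correction. No multiple-testing correction is applied;
  p-values are reported raw, one per comparison, as in the emulated
  analysis.
* **Logistic regression.** `divided ~ median_erk + median_akt`, binomial
  family, logit link, IRLS to a tight tolerance with a post-fit score
  check ($\lVert X^\top(y-\hat p)\rVert < 10^{-8}$); quasi-separation is
  reported via a flag, never an exception, with the diverging
  coefficients visible to the caller.
* **Pooled correlation.** Pearson correlation over all (cell, in-window
  frame) pairs of one fate class, with the pooled count $n$ reported.
  Treating pooled points as exchangeable matches the emulated analysis;
  a per-cell-mean alternative is easy to compute from the same pooled
  tables but is not the default.
* **Resampling band.** Uncertainty for a pooled $r$: draw $n$ paired
  points from the bivariate normal with the class's estimated mean and
  covariance (per class by default; a global option exists), compute
  $r$, repeat 1000 times, report the 5th–95th percentile range, each end
  rounded *up* to the next 0.01 (taken literally as a ceiling; a
  round-half-up mode exists for sensitivity checks). Calibration: over
  outer replicates with a known generating $\rho$ (0.5, $n$ = 300
  points), the band covers $\rho$ at close to the nominal 90%.
* **Crosstalk.** For a 2-node network, three time-course experiments —
  no inhibitor, ERK-pathway inhibitor, Akt-pathway inhibitor — decide
  the two cross-edges. The implemented decision statistic (the emulated
  study judged "negligible effect" visually): effect = time-averaged
  difference of population median trajectories (perturbed − control)
  over the window, CI by cell-level bootstrap (1000 resamples,
  percentile 2.5/97.5), and `edge_present` only if the CI excludes zero
  *and* the effect magnitude clears a practical floor, default 10% of
  the control trajectory's dynamic range. The floor prevents a large-n
  bootstrap from declaring biologically negligible shifts to be edges.

# Numerical choices and degenerate inputs

* Ring geometry and the rank-sum exact path use integer arithmetic; no
  floating-point distance transform enters the ring construction.
* Blank frames segment to zero labels (not an error); empty masks yield
  empty rings; empty scenes render pure background.
* A singular correlation matrix ($\rho = \pm 1$) yields a degenerate
  band at $\pm 1$ rather than a Cholesky failure.
* Constant-zero or aliased regressors yield `NA` coefficient rows, with
  the remaining terms intact.
* All stochastic components are seeded; identical configuration and
  seed give bit-identical output everywhere, including the renderer and
  the bootstrap.

# Problem sizes

The shipped tests and the acceptance script run the study at desk
scale, chosen to make every stochastic criterion stable under its
stated threshold: 200–300 cells for the trace-level studies, 2000 cells
where an effect-size recovery to ±0.02 is asserted, movies of 4–30
cells at 400×400 px and 9–29 frames, 200 random masks for the ring
oracle, 100 seeded runs for the association-pattern and crosstalk
rates, and 500 outer replicates for band-coverage calibration. The
acceptance script reports the same quantities at mildly reduced
replicate counts (50 crosstalk runs, 200 coverage replicates) so a
full from-scratch rerun stays around a minute.

# Known limitations

* The classical segmentation stand-in assumes bright, convex,
  well-separated nuclei; crowded or dim fields need an external
  segmenter (the mask interface accepts one).
* The tracker does not bridge detection gaps and keeps no lineage
  beyond the first division; multi-generation analyses are out of
  scope.
* Fusion events are surfaced only as QC flags; the movie-level review
  that the original workflow performed manually has no automated
  counterpart here.
* The crosstalk design assumes the inhibitor fully silences its target
  node; partial inhibition would shrink the positive-control effect but
  leaves the cross-edge logic unchanged.
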