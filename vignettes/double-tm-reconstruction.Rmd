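---
title: "Non-invasive double transmission-matrix reconstruction from fluorescence speckle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive double transmission-matrix reconstruction from fluorescence speckle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(specklemix)
```

## The problem

A fluorescent object made of `N` point-like emitters sits behind a strongly
scattering medium. Coherent light shaped by a phase-only SLM with `N_SLM`
segments excites it through the medium; the fluorescence comes back through
the same medium and is recorded in epi-detection — the only measurement
available is a stack of low-contrast speckle images on the camera, one per
input wavefront. Two linear operators describe the system:

* the ingoing **field-TM** `T` (`N x N_SLM`, complex): SLM segments to the
  excitation field at each emitter, so the excitation intensities are
  `|T E_in|^2`;
* the outgoing **intensity-TM** `W` (`D x N`, non-negative): each emitter's
  fluorescence casts a fixed speckle *eigen-pattern* (a column of `W`) on
  the `D` camera pixels, because fluorescence is incoherent.

For input pattern `p` the camera records

```
I_out(p) = W (|T E_in(p)|^2)^e,        e = 1 (linear) or 2 (two-photon),
```

so the `D x P` stack is a product of two non-negative matrices of rank `N`
(with `N << D, P`). Everything the package does follows from this
factorized structure: `W` and the excitation matrix `H = |T E_in|^2` are
recovered by non-negative matrix factorization (NMF), each row of `T` by
intensity-only phase retrieval on the corresponding row of `H`, foci are
formed by displaying the conjugate phase of a retrieved row, and the
object's geometry is recovered from cross-correlations between
eigen-patterns that the memory effect turns into translated copies.

## The simulator

`simulation_config()` + `make_field_tm()` / `make_intensity_tm()` /
`simulate_acquisition()` implement the forward model. Design choices that
matter:

* **Speckle statistics.** Fields are circular complex Gaussians with a
  Gaussian power spectrum (`speckle_field()`); intensities are
  exponentially distributed with unit contrast, and the speckle grain
  (default 2 px) is Nyquist-sampled by construction. Frames of an
  `N`-emitter object have ensemble contrast `sqrt(2/N)` under linear
  excitation, rising for two-photon excitation.
* **Memory effect, field side.** Row `n` of `T` is
  `c(d_n) (a * tilt(x_n)) + sqrt(1 - c(d_n)^2) g_n` with one shared pupil
  field `a`, a linear phase ramp `tilt` that maps object-plane shifts to
  pupil tilts (one fringe per speckle grain), independent `g_n`, `d_n` the
  distance to the first emitter, and `c(d) = exp(-d^2 / (2 me_range^2))` —
  a Gaussian decorrelation chosen as the simplest monotone, differentiable
  one-parameter model. The operational consequence, which the tests
  exercise, is that the conjugate pattern of emitter 1 plus the
  compensating tilt refocuses on a neighbour at efficiency `c(d)^2`.
* **Memory effect, intensity side.** Eigen-patterns of nearby emitters
  must be *translated copies* for every close pair, not only pairs
  involving a reference emitter — stitching beyond one patch depends on
  it. Columns of `W` are therefore built as `|sum_k w_k(x_n) G_k(r - x_n)|^2`:
  `n_mix = 64` shared complex mother speckles `G_k`, windowed at each
  emitter's offset (so the correlated part is shifted *exactly*, making
  the cross-correlation ground truth pixel-exact), mixed with
  Gaussian-process weights over emitter positions whose field kernel is
  `sqrt(c(d))`, giving intensity correlation `c(d_ij)` for every pair.
  The realized correlation fluctuates by ~`1/sqrt(n_mix)` around `c`.
  This is a modeling simplification: the package synthesizes the
  eigen-patterns directly rather than propagating a second physical TM.
* **Noise.** Poisson noise at `photon_budget` mean photons/pixel plus
  Gaussian read noise, clipped at zero; `photon_budget = Inf` (default)
  is noiseless and bit-reproducible. One master seed is split into named
  substreams (`patterns`, `field_tm`, `intensity_tm`, `noise`) so each
  ingredient is independently reproducible.

What the simulator does **not** emulate: physical diffraction propagation,
polarization Jones calculus, spectral width of the fluorescence,
photobleaching, background fluorescence from out-of-focus tissue, and
sub-pixel emitter positions. Tests passing on this generator show the
*algorithms* are correct under fully developed speckle statistics and a
Gaussian memory effect; they do not certify performance on real tissue.

### Contrast estimation

`stack_contrast()` reports the ensemble contrast
`sqrt(mean frame variance) / mean frame mean`. The naive alternative —
averaging per-frame `sd/mean` ratios — is biased low by Jensen's
inequality (about 11% at `N = 4`), which would mask the `sqrt(2/N)` law
the estimator is meant to verify; the per-frame variant remains available
via `method = "per-frame"`.

## Demixing (NMF)

`high_pass_filter()` removes the smooth background (Gaussian blur of width
`highpass_sigma`, default 6 px — comfortably above the 2 px grain —
subtracted and clipped at zero; clipping is required because NMF needs
non-negative input). `nmf_factorize()` minimizes `||I - WH||_F` with
Lee-Seung multiplicative updates, chosen for the monotonicity guarantee
that gives a clean test surface (the objective trace is asserted
non-increasing on every run); 3 random seeded restarts by default, best
final residual wins, `W` columns normalized to unit maximum with the scale
absorbed into `H`.

`estimate_rank()` runs the factorization for `r = 1..r_max` and places the
elbow at the maximum second difference of the residual curve (ties toward
the smaller rank). Beyond roughly ten targets the elbow washes out; the
function then flags `low_confidence` (curvature peak less than twice the
runner-up) and the recommended practice — which the pipeline follows — is
to overestimate the rank and prune afterwards.

`select_eigenpatterns()` prunes the overestimated factorization:

* **spurious** components have eigen-pattern contrast (`sd/mean` of the
  `W` column — scale-invariant, which matters because NMF columns carry
  arbitrary scale) more than `theta_var = 2` robust z-scores below the
  median, with the z-scale floored at 10% of the median so tightly
  clustered contrasts do not explode the score; a component that fails the
  non-invasive focusing validation (below) is also spurious;
* **duplicates** are pairs whose patterns correlate above
  `theta_dup = 0.8`; the lower-contrast member is dropped. When the
  validation-time epi frames are available they are correlated instead of
  the raw `W` columns: NMF tends to *split* one emitter across components
  whose raw columns correlate only moderately (0.6-0.75 in our runs),
  while their focused frames are near-identical (> 0.99) and frames of
  distinct emitters — even within one memory-effect patch — decorrelate at
  zero lag within a speckle grain (< 0.15).

Both thresholds are declared defaults, exposed in the configuration.

## Phase retrieval

Each selected row `h` of `H` is the intensity `|<t, E_in(p)>|^2` of one
unknown complex row `t`, recoverable up to a global phase once `P` is a
few times `N_SLM`. `retrieve_row()` uses:

* **Refined spectral initialization**: leading eigenvector of
  `(1/P) sum_p f(h_p) E_p E_p^H` with `f(h) = max(1 - 1/h, -1)` on
  unit-mean `h` (the truncation is configurable). With the package's
  measurement convention `a_p = sum_s E[s,p] t_s` and phase-only sensing
  vectors, the eigenvector estimates `conj(t)`, so the conjugate is
  returned — a consequence of the non-Gaussian pattern statistics worth
  noting for anyone modifying the code.
* **Amplitude-flow descent** on `(1/P) sum_p (sqrt(h_p) - |a_p|)^2`,
  backtracking line search by default (monotone loss trace, asserted in
  tests), fixed step `0.2/L` available with `L` the spectral norm of
  `(1/P) E E^H` estimated by (deterministic) power iteration. The
  amplitude loss is better conditioned than the intensity (Wirtinger)
  loss at moderate `P/N_SLM`, which is why it was chosen.
* NMF rows carry arbitrary scale: `h` is normalized to unit mean and the
  scale re-attached as `sqrt(mean h)` afterwards.

Quality is reported phase-invariantly (`tm_cosine()`), plus a
ground-truth-free self-consistency (Pearson correlation between `h` and
the predicted intensities).

## Focusing and non-invasive validation

`conjugate_focus_pattern()` displays `-arg(t)`; with a perfect row the
focus intensity is the phase-only maximum `(sum |t_k|)^2` and the expected
enhancement over random illumination is `1 + (pi/4)(N_SLM - 1)`.
`evaluate_focus()` is the control-camera analogue: intensities at all
emitters plus 50 independent background grains, with

* `snr` = target intensity / mean off-target intensity (off-target
  emitters and background grains pooled), and
* `snr_std` = (target - background mean) / background sd,

both reported because either convention is common and they differ by
roughly the background's relative spread. `epi_variance_validation()` is
the purely epi-side verdict: when a pattern truly focuses, the epi frame
collapses to one eigen-pattern and its spatial variance jumps by a factor
approaching the `N/2` contrast-squared ratio; the score is the
high-passed frame variance normalized by the median variance under random
patterns, with verdict threshold `theta_focus = 2` (the gap between
focused and random scores is one to two orders of magnitude in practice,
so the verdict is insensitive to the exact threshold; at small `N` the
random-pattern scores are heavy-tailed and occasional false positives at
`theta_focus = 2` are expected). Control-side and epi-side quantities are
kept in separate columns of `focus_report()`; `validated` means the
epi verdict *and* control-side selectivity both hold.

## Imaging beyond the memory-effect range

Within one patch, eigen-patterns are translated copies and
`cross_correlate()` recovers the displacement `u_ij = x_j - x_i`
pixel-exactly (integer pixels; sub-pixel refinement is out of scope). Two
thresholds gate an edge of the displacement graph:

* `theta_edge = 5` robust-std units above the correlation-plane
  background, and
* `theta_peak = 0.2` on the normalized peak itself. The z-criterion alone
  over-connects: the argmax over a correlation plane of two *independent*
  4096-pixel speckles already reaches ~0.1 (extreme-value statistics over
  thousands of plane samples) with a large z-score, and focused epi frames
  share a leak background that correlates at zero shift. Genuine
  within-patch pairs at spacings up to `1.5 me_range` have peaks at
  `c(d) >= 0.3`.

`stitch_positions()` solves all edge constraints `x_j - x_i = u_ij` by
least squares per connected component (reference node at the origin),
rather than accumulating shifts along paths — a deliberate strengthening
that avoids drift along chains. Outliers are rejected robustly: while the
worst edge residual exceeds `resid_tol = 2` px, that edge is removed and
the system re-solved. Only edges lying on cycles can carry residual, so
removal never disconnects a component; the flip side is that a spurious
*bridge* edge is undetectable from residuals, which is exactly the
paper-level statement that isolated targets cannot be located — they can
at best be attached wrongly, and the peak threshold is what keeps that
rare. Positions are defined up to one translation per component
(`align_positions()` removes it against ground truth); singleton nodes are
reported unlocated, never silently placed.

`mds_localize()` is the alternative localizer: classical MDS
(`stats::cmdscale`) on `||u_ij||`, with missing pairs completed by graph
shortest paths and `procrustes_align()` (vegan) for comparisons. In our
head-to-head Monte-Carlo it does **not** beat the least-squares stitcher —
under Gaussian distance noise (sigma 0.5 px, 15 emitters) stitching
reaches ~0.18 px rmse vs ~0.4 px for MDS, and under 10% wrong-peak
outliers robust stitching wins by an order of magnitude. The advantage
MDS is sometimes credited with holds against sequential shift
accumulation, which this package deliberately does not use; MDS is kept
as an independent cross-check and for cases where only scalar distances
are trusted. Shortest-path completion overestimates distances along
curved chains (the isomap effect), so MDS is most useful on compact,
well-connected components.

For continuous objects factorized at heavily overestimated rank, only the
high-variance (non-spurious) components should be cross-correlated and
rendered (`assemble_image()`).

## The pipeline and reproducibility

`run_pipeline()` chains simulate, high-pass, (optional) rank estimation,
NMF, selection, phase retrieval, focusing with both validations, final
component selection, and memory-effect imaging. For the imaging stage the
default input is the epi frames recorded under the validated focusing
patterns, with the mean random-illumination frame subtracted to cancel
the focus-leak background common to all frames; the raw `W` columns are
available via `imaging_source = "W"` and both sources are legitimate —
raw columns avoid the leak but inherit NMF splitting artifacts. Artifacts
and a manifest (config echo, substream seeds, stage timings, md5 hashes)
are written as stages complete, so a failure leaves earlier results on
disk; noiseless reruns with the same master seed are bit-identical, which
the tests assert.

Interchange formats are deliberately plain: multi-page 16-bit TIFF with a
YAML sidecar (values quantized by rounding, so the round-trip error is at
most half a quantization step) for stacks, CSV for emitter maps, edge
lists and reports, YAML for configurations.

## Problem sizes used in the shipped tests

The test suite validates the quantitative laws at deliberately compact
sizes: the polarizer factor on ~10^5-pixel speckles; the `sqrt(2/N)` law
at `N` in {4, 8, 16} with 60-80 frames; the noisy end-to-end focusing run
at `N = 20`, `N_SLM = 256`, `P = 5120`, `D = 64 x 64`, ~100
photons/pixel; the capability run at `N = 50`, `N_SLM = 128`, `P = 4096`,
rank 60; and beyond-range stitching on a 20-emitter chain spanning more
than three patch diameters on a 96 x 96 grid. These sizes keep a full run
in minutes on one core while leaving each effect comfortably above its
estimation noise; `scripts/acceptance.R` re-runs the two end-to-end
configurations from scratch at an arbitrary seed.

## Known limitations

* The eigen-pattern generator synthesizes correlated shifted envelopes
  directly; it does not model a second physical scattering propagation,
  axial structure, or sub-pixel shifts.
* The memory-effect decorrelation is Gaussian by assumption; real
  diffuser stacks need not follow it (only monotonicity is relied upon).
* Rank estimation is unreliable beyond ~10 targets (flagged, not fixed);
  the supported workflow is overestimate-then-prune.
* Selection thresholds (`theta_dup`, `theta_var`, `theta_focus`,
  `theta_edge`, `theta_peak`) are declared defaults tuned on the
  simulator's statistics, not reproductions of any experimental setting.
* Isolated emitters (no correlation partner) are reported unlocated;
  nothing can place them, and a spurious bridge edge can still misplace
  one in adversarial regimes.
* 2D only: the object is reconstructed as a projection; volumetric
  reconstruction is out of scope.
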