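---
title: "Methods: translocation quantification and line-scan FRAP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translocation quantification and line-scan FRAP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucytoloc)
```

# The measurement model

## Concentration index

The translocation readout is the per-cell concentration index

$$CI = \frac{F_{nuc} - BG}{F_{cyto} - BG},$$

where $F_{nuc}$ and $F_{cyto}$ are mean reporter intensities over the
nucleus and cytoplasm masks and $BG$ is the background level. Because both
numerator and denominator are background-corrected means, CI is exactly
invariant under affine transformations of the camera response
($I \mapsto gI + o$ applied consistently to pixels and background), which
the test suite verifies to $10^{-12}$ relative. The cytoplasmic mean is
computed by subtracting the summed nuclear intensity from the summed
whole-cell intensity and dividing by the area difference; this is
algebraically identical to the mean over the cytoplasm mask (cell minus
nucleus as an exact set difference) and is fuzz-tested as such.

Measurements whose denominator falls at or below a small guard
$\varepsilon$ (default $10^{-6}$ of the intensity range) are marked
*invalid* and excluded from group statistics while remaining visible in
the output — a cell with cytoplasmic signal at background level carries no
ratio information, but silently dropping it would bias condition means.

## Normalization and condition summaries

Raw CI values are only comparable within one acquisition setting, so
condition-level statistics use min–max normalized values
$\overline{CI} = (CI - \min)/(\max - \min)$, with the extremes taken over
**all cells of all conditions and reporter groups in one experiment
batch**. The pool definition matters: normalized values from different
pools are on different scales, so the pool's $(\min, \max)$ pair is stored
with every output. The package deliberately treats raw CI (time-lapse
kinetics) and $\overline{CI}$ (condition tables) as distinct, labelled
quantities; their absolute scales cannot be reconciled after the fact
because the original pooling is not recoverable from published means.

Summaries per reporter group and treatment report mean ± SEM and $n$,
fold-change (mean over the group's own baseline mean),
$\Delta\overline{CI}$ (mean minus baseline mean), and — between reporter
groups — the ratio of matching $\Delta\overline{CI}$ values. The
$\Delta$-over-$\Delta$ rule is applied uniformly; for near-baseline rows
its denominator is small and the ratio numerically unstable, which is a
property of the statistic, not of the implementation. A baseline mean of
zero makes fold-change undefined; this is flagged, not patched.

## Response metrics

For a stimulus time course the package reports baseline (pre-stimulus
mean), peak (post-stimulus maximum), plateau (mean over a final window,
default the last quarter of the recording), and the split of the
stimulation-induced rise into

$$\%\,decline = 100\,\frac{peak - plateau}{peak - baseline}, \qquad
  \%\,above = 100\,\frac{plateau - baseline}{peak - baseline}.$$

Both are fractions of the rise ($peak - baseline$); this is the only
denominator under which a "54 % decline yet 46 % above baseline" pair of
statements is simultaneously consistent, and the two always sum to 100.
A non-response ($peak \le baseline$) flags the metrics undefined.

## Group statistics

Two groups are compared with Welch's two-tailed unpaired t-test. Three or
more use one-way ANOVA plus Dunnett's many-to-one contrasts against a
designated control. No multiple-comparison package is assumed: the
adjusted p-value $P(\max_j |T_j| \ge |t_i|)$ is obtained by direct 2-D
quadrature, conditioning on the control z-score and the pooled scale
(exact for unbalanced designs); agreement with an independent
implementation (scipy's) is pinned in the test suite to $10^{-3}$.
Significance stars follow the conventional thresholds
(ns > 0.05 ≥ * > 0.01 ≥ ** > 0.001 ≥ *** > 0.0001 ≥ ****).

# Line-scan FRAP

## Record model and traces

A fast-FRAP record is a kymogram — rows are pixels along one repeatedly
scanned line, columns are successive scans — with contiguous pre-bleach,
bleach and post-bleach column ranges (defaults 1 s / 150 ms / 3 s) and two
pixel ranges along the line: the bleach ROI and a background region
outside the cell. The reference region is *derived*: all line pixels
except the bleach ROI widened by a 5-px guard band and except the
background region. The guard band avoids bleach spill-over contaminating
the reference; using the whole remainder of the line maximizes reference
signal. Per scan line, the FRAP and reference traces are ROI means minus
that same line's background mean.

The nominal line rate of such acquisitions is instrument-specific and not
derivable from published image dimensions, so the line interval is a
configuration input (simulator default 700 lines/s).

## Double normalization and fitting

$$y(t) = \frac{I_{Ref,Pre}}{I_{Ref}(t)} \cdot
         \frac{I_{FRAP}(t)}{I_{FRAP,Pre}}$$

with pre-bleach means taken over the full pre-bleach phase. The reference
ratio cancels whole-field acquisition bleaching *exactly* when bleaching
acts multiplicatively on both regions — the tests impose a global
$e^{-\beta t}$ decay and verify cancellation to $10^{-9}$ — and the
pre-bleach scaling puts the resting level at 1. No additional detrending
is applied: the reference term is the bleaching correction. Bleach-phase
lines are excluded from both the pre-bleach means and the fit; $t = 0$ at
the first post-bleach line.

Recovery is fitted by nonlinear least squares to the one-phase exponential
association $I(t) = I_0 + A(1 - e^{-kt})$ (reaction-limited exchange; no
diffusion-model fitting). Initialization: $I_0$ from the first 5 samples,
plateau from the last 10 %, $k$ from a log-linear regression of the
residual amplitude; bounds $I_0 \in [0, 1.2]$, $A \in [0, 1.5]$,
$k \in (10^{-4}, 10^{4})\,s^{-1}$; all post-bleach samples enter
unweighted (line-scan data are dense; binning would only discard
information). Non-convergence is flagged, never silently defaulted; fits
with residual SD > 0.1 or plateau > 1.2 are marked unreliable. Reported
identities are exact by construction: $t_{1/2} k = \ln 2$ and
$IF = 100(1 - I_0 - A)$. A plateau above 1 yields a negative immobile
fraction that is retained and flagged as over-recovery.

# The synthetic-data generators

## What they emulate

*Translocation*: circular cells with concentric circular nuclei on a
non-overlapping layout; reporter intensity $gain \cdot c + background$
per compartment, a constant nuclear-marker channel mimicking a DNA stain,
optional Gaussian optical blur, and Poisson-plus-Gaussian noise (scaled
shot noise $p\,\mathrm{Pois}(I/p)$ plus additive read noise; the source
experiments specify no noise model, so this standard camera model was
chosen once). Compartment concentrations follow a closed two-compartment
exchange $dN/dt = k_{in}(t) C - k_{out} N$ with the cytoplasmic balance
scaled by the nuclear/cytoplasmic volume ratio, the minimal kinetics that
produces stimulus-switched nuclear accumulation. The import rate steps at
the stimulus time; an optional exponential relaxation of $k_{in}$ toward a
late value reproduces the rise-then-partial-decline shape seen in
stimulated recordings (off by default, so the documented contract — a pure
step — holds exactly). Defaults mirror the experiments' stated world:
0.5 µm pixels, 2-min frame interval, a 10-min baseline before stimulus.

*FRAP*: kymograms at the stated phase timing with a configurable mobile
fraction, recovery rate, bleach depth, optional whole-field acquisition
bleaching (magnitude unpublished, hence a free parameter defaulting to
off) and additive noise (default SD 1 % of the pre-bleach level). Default
bleach depth is 1 (complete bleaching): the immobile fraction defined
against the pre-bleach level equals
$100 \cdot d \cdot (1 - m)$ for bleach depth $d$ and mobile fraction $m$,
so only at $d = 1$ does the simulator's "mobile fraction 0.82" correspond
to the intuitive 18 % immobile target. Incomplete bleaching is supported
and the coupling documented here.

## What they do not emulate

No cell motion, division, focus drift or 3-D structure; no photophysics
beyond first-order bleaching; no diffusion PDE for FRAP (recovery is
reaction-limited by construction, matching the fitted model). A green test
therefore establishes correctness of the measurement and fitting
machinery under the stated model — not robustness to segmentation-breaking
morphologies or diffusion-dominated recovery.

# Numerical choices

- **Integration** of the exchange ODE: fixed-step RK4 with step
  $\le \min(\Delta t_{frame}/20,\ 0.05/\max k)$. Because total mass is a
  linear invariant annihilated by the vector field, every Runge–Kutta step
  conserves it to machine precision; trajectories are additionally checked
  against an independent fine-step Euler oracle. The instant $t = t_{stim}$
  itself is convention-dependent (the step is applied to stage times
  $\ge t_{stim}$); sampling exactly at the discontinuity is avoided in
  oracles.
- **Segmentation**: Otsu threshold on a 256-bin histogram of the
  normalized intensity range (hence scale-invariant masks, and a first-max
  tie-break), hole filling by border-connected background flood,
  area-filtered 4-connected components, and cells grown from nucleus seeds
  by multi-source geodesic distance (the distance-transform flavour of
  seeded watershed; equidistant ties go to the lowest label). All label
  renumbering is raster-ordered, so results are deterministic.
- **Coordinates**: masks are sets of integer pixel centres, `[row, col]`
  = `(y, x)`; label images use 0 for background.
- **Background**: mean outside a 3-px dilation of all cells (the margin
  clears the diffraction halo), or an explicit user ROI.
- **Tracking**: per-frame re-segmentation with nearest-centroid linking,
  max displacement 10 px/frame; ties by smallest distance then lowest
  track id; lost cells yield explicit missing rows, never interpolation.
- **TIFF**: the bundled codec writes uncompressed little-endian baseline
  TIFF with 64-bit float samples — round trips are bit-exact — and JSON
  metadata (channel roles, pixel size, frame times) in the
  ImageDescription tag; interoperability with an independent reader is
  part of the test suite. Configs are JSON.
- **Printed-precision comparisons**: published derived columns were
  computed from unrounded means; recomputing them from printed 3-decimal
  means can differ by half a unit in the last printed digit. Acceptance
  tests therefore assert the headline values exactly and the remaining
  columns within the uncertainty propagated from input rounding
  ($|\Delta fold| \le fold \cdot (5{\cdot}10^{-4}/\bar x +
  5{\cdot}10^{-4}/\bar x_{base})$) — a bound derived from the inputs, not
  tuned to observations.

# Known limitations

- Segmentation is classical (threshold + geodesic growth); heavily
  overlapping or non-convex cells need external masks, which can be
  supplied directly to `build_compartments()`.
- The Δ-over-Δ cross-ratio is unstable when the reference group's response
  is near zero; values are reported with that caveat rather than censored.
- Monte-Carlo acceptance studies run at reduced image and record sizes
  (e.g. 64–150 px scenes, 128-px lines at 700 Hz) relative to full-size
  acquisitions (1024² frames, 1024-px lines), chosen to keep the complete
  suite within minutes on one CPU; all tolerances are met with margin at
  these sizes, and the statistics being means over masks, size enters only
  through sampling variance.
- Two-way ANOVA designs are out of scope; use the exported per-group
  summaries with standard R modelling functions.
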