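---
title: "Quantifying protein aggregation by spatial image correlation and FRAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein aggregation by spatial image correlation and FRAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsfrap)
```

## The measurement problem

Disease mutants of non-muscle myosin II-A (and many other filament-forming
proteins) change how the molecule distributes between dispersed monomers,
small filamentous assemblies and large aggregates. Super-resolution (STED)
images of tagged protein show a speckle field in which this clustering state
is encoded not in any single structure but in the *statistics* of the
intensity fluctuations. Spatial image correlation spectroscopy (ICS) turns
those statistics into three per-ROI numbers:

* the mean intensity $\langle I \rangle$, proportional to the total number
  of fluorescent monomers in an average focal spot;
* the cluster density $CD$, the number of *independent* fluorescent
  assemblies per unit area;
* the degree of aggregation $DA = \langle I \rangle / CD$, a relative
  measure of monomers per assembly.

The companion FRAP analysis measures how fast those molecules exchange:
the dissociation rate $K_\mathrm{off}$, the mobile fraction (plateau $P$),
the immobile fraction $1 - P$, and a relative association-rate estimate
$K^*_\mathrm{on} = P \, K_\mathrm{off} / F_\mathrm{eq}$.

## The ICS model

For an ROI of a single detection channel, the fluctuation field is
$\delta I(x, y) = I(x, y) - \langle I \rangle_r$, and the discrete spatial
autocorrelation over pixel lags $(\xi, \eta)$ is

$$ g(\xi, \eta) \;=\;
   \frac{\langle \delta I(x, y)\, \delta I(x + \xi, y + \eta) \rangle_r}
        {\langle I \rangle_r^2}. $$

Because the focal spot acts as the spatial correlator, $g$ is Gaussian with
the correlation radius $\omega$ of the effective point-spread function. Its
zero-lag amplitude is the squared relative fluctuation, which for
non-interacting assemblies equals $1/\langle N_a \rangle$, the reciprocal of
the mean number of independent assemblies per beam area. White detection
noise (Poisson shot noise, Gaussian read noise) is delta-correlated and so
inflates *only* the $(0,0)$ value. The amplitude is therefore obtained by
fitting

$$ g(\xi, \eta) = g_0 \, e^{-(\xi^2 + \eta^2)/\omega^2} + g_\infty $$

over all lags *except* $(0,0)$ and extrapolating back to zero lag; the
offset $g_\infty$ absorbs incomplete decay from long-range correlations
(including the small uniform depression caused by estimating the mean from
the same ROI). From the fit,

$$ \langle N_a \rangle = 1/g_0, \qquad
   CD = \frac{1}{g_0\, \pi \omega^2}, \qquad
   DA = \frac{\langle I \rangle}{CD}. $$

The optical brightness constant linking intensity to monomer counts is not
estimable from a single acquisition; it is absorbed into arbitrary
intensity units, so $DA$ is meaningful *comparatively*, across conditions
imaged with matched settings.

```{r ics-example}
p <- sim_params(cluster_rate = 30, seed = 1)
img <- render_image(simulate_emitter_field(p), p)
ics_analyze(img, background = p$background_mean, roi_id = "demo",
            condition = "WT")
```

### Background correction

A uniform background offset does not fluctuate, so it leaves
$\delta I$ untouched while inflating $\langle I \rangle$; uncorrected, it
deflates $g_0$ by $(S/(S+B))^2$ and correspondingly inflates the apparent
assembly count. `fluctuation_field()` and `ics_analyze()` therefore accept a
`background` level that is subtracted from the mean (only). Estimating that
level (from a cell-free region, say) is the caller's responsibility.

### Numerical choices

* **Boundary convention.** The spatial average in $g$ uses the periodic
  (circular) convention computed with FFTs. Fitting is restricted to lags
  $|\xi|, |\eta| \le$ `max_lag_px` (default `min(dim)/4`, capped at 32 for
  128 px ROIs), where wrap-around bias is negligible for speckle-scale
  $\omega$. The test-suite oracle — a direct double-loop sum under the same
  convention — agrees with the transform to $10^{-10}$.
* **Symmetrization.** $g(\xi,\eta) = g(-\xi,-\eta)$ is enforced exactly by
  averaging the surface with its reflection, removing FFT round-off
  asymmetry.
* **Fit initialization.** $g_0$ starts at the mean of the four unit-lag
  values, $\omega$ at the nominal PSF radius in pixels (default 4),
  $g_\infty$ at the mean of the outermost fitted ring; a deterministic
  ladder of up to three re-scaled starts runs before a fit is declared
  non-converged. Convergence tolerance is $10^{-10}$ on parameters and
  residuals with at most 500 iterations (Levenberg–Marquardt).
* **Degenerate inputs.** An all-zero or constant ROI has no defined
  relative fluctuation and errors out early; a flat ACF surface or a
  non-positive fitted amplitude is flagged non-converged, and
  `ics_analyze()` returns the row with `converged = FALSE` so condition
  summaries can count exclusions instead of silently dropping them.

### ROI conventions

Analysis ROIs are 128 × 128 px by default (120 × 120 is equally valid; the
size is a parameter). Coordinates are (row, col), 0-based, half-open. ROI
*selection* is deliberately caller-supplied: regions are picked away from
large amorphous aggregates, whose single dominant structure violates the
non-interacting speckle assumption; `flag_aggregate_rois()` provides a
percentile-based screen to support that judgment, not to replace it.

## The synthetic-data generator

Every stage of the pipeline is verified by parameter recovery on simulated
data whose ground truth is known exactly. `sim_params()` defines the
generative model:

* cluster centers follow a homogeneous spatial Poisson process
  (`cluster_rate`, clusters per µm²; default 30, giving on the order of one
  assembly per beam area at the default PSF — a dense but analyzable
  speckle field);
* each cluster holds a fixed number of monomers (`fixed_monomers(k)`) or
  `1 + Poisson(lambda)` monomers (`poisson_monomers(lambda)`), scattered
  with isotropic Gaussian SD `cluster_spread_nm` (default 0: point-like
  assemblies);
* each monomer contributes `brightness_photons` (default 500) through a
  Gaussian PSF of e⁻² radius `psf_e2_radius_nm` (default 100 nm — a
  plausible effective STED spot; the instrument value is not critical since
  $\omega$ is fitted), integrated exactly over 25 nm pixels;
* a uniform `background_mean` (default 10 photons) is added, then Poisson
  shot noise, then Gaussian read noise (`read_noise_sd`, default 2), the
  result clamped at 0;
* emitters are also placed within `margin_nm` (default 3 × PSF radius)
  outside the field so edge pixels see realistically truncated spots;
* for two channels, a channel-2 cluster is placed at a channel-1 center
  with probability `co_aggregation` (sequestration) and independently
  otherwise (exclusion);
* one master seed expands into fixed per-stage substreams (placement, shot
  noise, read noise, per channel), so the same field can be re-rendered
  bit-identically under different noise settings.

What the generator does *not* emulate: aggregate morphology (real mutant
aggregates are large and amorphous or stubby and filament-like; the
simulator's clusters are a statistical stand-in), STED depletion physics,
acquisition photobleaching, detector pixel cross-talk, and cell-shaped
illumination structure. Passing recovery tests therefore demonstrate that
the *estimators* are correct under the model's assumptions, not that any
particular biological image satisfies those assumptions.

Two recovery properties anchor the suite: simulated monomeric fields
recover the true cluster density to within 10% on average, and 5-mer
fields at one-fifth the cluster rate (equal total monomer count) give a
$DA$ ratio of 5 ± 15% against monomeric fields — the
$\langle N_m \rangle / \langle N_a \rangle$ reading of $DA$.

## The FRAP model

In the reaction-dominant regime — diffusion fast relative to binding, as
verified when a one-phase model interpolates recovery data accurately — the
normalized post-bleach intensity follows

$$ I(t) = P\,(1 - e^{-K t}), $$

with the model constrained through $I(0) = 0$ to exclude non-physical fits,
and bounds $K \ge 0$, $0 \le P \le 1.2$ (mild over-recovery from noise is
tolerated; the immobile fraction is $1 - P$). The recovery rate $K$ equals
the dissociation rate $K_\mathrm{off}$ and is independent of
$K_\mathrm{on}$, which enters only through the plateau via
$S\,K_\mathrm{on} = P\,K_\mathrm{off}/F_\mathrm{eq}$. With the free-site
concentration $S$ assumed condition-independent and $F_\mathrm{eq} = 1$,
$K^*_\mathrm{on} = P\,K_\mathrm{off}$ is reported as a relative
association-rate estimate. The printed form of this relation is ambiguous
in its source; the implemented reading is the only one consistent with
reaction-dominant FRAP theory, in which $K_\mathrm{on}$ affects the plateau
but not the rate.

Normalization is background-subtracted and prebleach-scaled:
$(I_\mathrm{raw} - B)/(\bar I_\mathrm{pre} - B)$, with the time axis
re-zeroed to the bleach frame. This is the simplest normalization
consistent with the $I(0)=0$ constraint. Double normalization against a
whole-cell reference (acquisition-bleaching correction) is available but
off by default, appropriate when fixed-cell controls show acquisition
bleaching is negligible or already corrected.

```{r frap-example}
trace <- simulate_frap_trace(koff = 0.05, plateau = 0.8,
                             schedule = frap_schedule(), noise_sd = 0.05,
                             seed = 2)
fit_frap(trace)
```

The default sampling schedule — 5 frames at 0.526 s, 15 at 1 s, 30 at 4 s,
after the bleach frame at $t = 0$ — spans ~138 s, about 10 recovery
half-times at $K = 0.05\,\mathrm{s^{-1}}$. Noiseless traces on this
schedule are recovered to $10^{-6}$ relative for
$K \in [0.005, 1]\,\mathrm{s^{-1}}$; condition-level estimates aggregate
at least ~40 traces as mean ± SEM.

## Group statistics

Per-ROI and per-trace metrics are compared across conditions with the
two-sided Mann–Whitney U test (`mann_whitney()`): exact tail-doubled
p-values from the null distribution of U whenever $n_1 + n_2 \le 20$ with
no ties, otherwise the normal approximation with tie and continuity
corrections (the method is always labeled in the output, since exact and
asymptotic p-values can differ at small n). Star levels follow the usual
mapping (* < 0.05, ** < 0.01, *** < 0.001, **** < 10⁻⁴). No
multiple-testing correction is applied by default, matching
per-comparison reporting conventions; a Holm option exists.

Gliding-assay tracks are filtered before averaging: a track is excluded
iff its velocity SD / mean velocity exceeds 0.33 (strictly greater — a
ratio of exactly 0.33 is retained); non-positive mean velocities are
flagged invalid and fall in neither bin, so record counts are conserved.

## Known limitations

* $DA$ and $\langle I \rangle$ are in arbitrary units; only within-study
  comparisons are meaningful.
* ICS assumes spatially stationary, non-interacting assemblies within the
  ROI; fields dominated by one large aggregate violate this and must be
  screened out.
* The FRAP module fits only the one-phase reaction-dominant model; systems
  with diffusion-coupled or two-phase recovery need different machinery.
* Pixel-size calibration is taken from configuration, not image metadata;
  a wrong pixel size rescales $CD$ (by the square) and $DA$ accordingly.
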