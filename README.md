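# icsfrap

Quantitative analysis of protein clustering and turnover from fluorescence
microscopy, built around two classical fluctuation methods:

* **Spatial image correlation spectroscopy (ICS)** — for super-resolution
  (STED) images of tagged filament-forming proteins such as non-muscle
  myosin II-A, whose disease mutants shift the balance between dispersed
  monomers, small assemblies and large aggregates. From each region of
  interest, the spatial autocorrelation of intensity fluctuations

  g(ξ, η) = ⟨δI(x, y) δI(x+ξ, y+η)⟩ / ⟨I⟩²

  is fitted with a Gaussian plus offset, g₀·exp(−(ξ²+η²)/ω²) + g∞,
  *excluding the zero-lag point* (which white detection noise inflates).
  The extrapolated amplitude gives the mean number of independent
  fluorescent assemblies per beam area ⟨Na⟩ = 1/g₀, the cluster density
  CD = 1/(g₀·π·ω²), and the degree of aggregation DA = ⟨I⟩/CD — a relative
  measure of monomers per assembly.

* **Reaction-dominant FRAP** — normalized recovery traces are fitted with
  the one-phase model I(t) = P·(1 − e^(−Kt)) constrained through I(0) = 0.
  In the reaction-dominant regime K equals the dissociation rate K_off;
  the plateau P is the mobile fraction (immobile fraction 1 − P); and
  K*_on = P·K_off/F_eq is a relative association-rate estimate.

The package also ships the nonparametric group statistics used with such
data (exact/approximate two-sided Mann–Whitney U, significance stars,
condition summaries with exclusion accounting, the gliding-assay velocity
dispersion filter), TIFF/ROI/CSV I/O, and a **synthetic-data generator**
(Poisson-placed emitter clusters, Gaussian PSF rendering, Poisson + read
noise, co-aggregating second channels, FRAP traces) so that every estimator
is verifiable by parameter recovery against known ground truth.

## Worked example

Simulate a 128 × 128 px field (25 nm pixels) of 3-mer clusters, analyze it
by ICS, and fit a noisy FRAP trace:

```r
library(icsfrap)

p   <- sim_params(cluster_rate = 30, monomers_per_cluster = fixed_monomers(3),
                  seed = 7)
img <- render_image(simulate_emitter_field(p), p)
ics_analyze(img, background = p$background_mean, roi_id = "roi1",
            condition = "N93K")
#>   roi_id channel condition mean_intensity     g0 omega_nm     g_inf
#> 1   roi1     ch0      N93K           29.9 0.9757    92.27 -0.007626
#>   n_assemblies cluster_density_per_um2 degree_of_aggregation converged
#> 1        1.025                   38.32                0.7805      TRUE

fit_frap(simulate_frap_trace(0.05, 0.8, noise_sd = 0.05, seed = 7))
#> <frap_fit> K_off = 0.05699 /s, plateau = 0.792 (immobile 0.208),
#>            K*_on = 0.04515 /s, converged

mann_whitney(c(1.2, 1.9, 2.4, 3.1), c(4.0, 4.4, 5.1, 6.2))
#> <mw_test> U = 0 (n1 = 4, n2 = 4), p = 0.02857 [exact] *
```

Reading the ICS row: the fitted correlation radius (92 nm) tracks the PSF,
not the pixel grid; ~1.0 independent assemblies sit in each beam area
(g₀ ≈ 0.98); the 3-mer field at rate 30 clusters/µm² yields a cluster
density near 38 /µm² and a DA three times that of the equivalent monomeric
field at equal total intensity. The FRAP fit recovers the generating
K = 0.05 s⁻¹ and P = 0.8 to within the noise. The Mann–Whitney example is a
fully separated 4-vs-4 comparison, whose exact two-sided p is 2/70 = 0.0286.

Real images enter through `read_image()` (8/16-bit grayscale TIFF, one
`pixel_grid` per page) and `extract_rois()`; per-ROI metric tables are
written with `write_metrics()` and compared across conditions with
`summarize_condition()` / `compare_conditions()`.

See `vignettes/ics-frap-methods.Rmd` for the model assumptions, parameter
defaults, numerical choices and limitations.

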