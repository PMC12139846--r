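# Spatial image correlation spectroscopy.
#
# The intensity fluctuation field of an ROI is autocorrelated over discrete
# pixel lags, normalized by the squared mean intensity, and fitted with a 2D
# Gaussian plus offset while EXCLUDING the zero-lag point, whose value is
# inflated by white detection noise (shot + read noise are delta-correlated,
# so they contribute only at lag (0,0)). The extrapolated zero-lag amplitude
# g0 gives the mean number of independent fluorescent assemblies per beam
# area, <Na> = 1/g0; the cluster density CD = 1/(g0 * pi * omega^2); and the
# degree of aggregation DA = <I>/CD, a relative measure of monomers per
# assembly.

#' Intensity fluctuation field of an ROI
#'
#' delta(x, y) = I(x, y) - <I>, with <I> the spatial mean over the ROI.
#' A known uniform background offset can be subtracted from the mean: a
#' constant background does not fluctuate, so it leaves delta untouched but
#' deflates the relative fluctuation g = <delta^2>/<I>^2 by
#' (signal/(signal+background))^2 if uncorrected, which inflates the
#' apparent assembly count. `mean_intensity` is therefore the
#' background-corrected mean.
#'
#' @param roi A [pixel_grid()].
#' @param background Uniform background level (same units as the image) to
#'   subtract from the mean intensity; default 0.
#' @return Object of class `fluctuation_field`: `delta` matrix,
#'   `mean_intensity`, and the inherited `pixel_size_nm`.
#' @export
fluctuation_field <- function(roi, background = 0) {
  stopifnot(inherits(roi, "pixel_grid"))
  mu <- mean(roi$values) - background
  if (mu <= 0)
    stop("degenerate ROI: background-corrected mean intensity is not ",
         "positive, relative fluctuations are undefined", call. = FALSE)
  structure(
    list(delta = roi$values - mean(roi$values), mean_intensity = mu,
         pixel_size_nm = roi$pixel_size_nm,
         channel_label = roi$channel_label),
    class = "fluctuation_field"
  )
}

#' Discrete spatial autocorrelation of intensity fluctuations
#'
#' Computes g(xi, eta) = <delta(x, y) delta(x + xi, y + eta)> / <I>^2 under
#' the periodic (circular) boundary convention via FFTs; the spatial average
#' uses all N pixels. Fitting is later restricted to small lags where
#' wrap-around bias is negligible for speckle-scale correlation lengths. The
#' zero-lag value equals the population variance over squared mean. The
#' surface is explicitly symmetrized so g(xi, eta) = g(-xi, -eta) holds
#' exactly.
#'
#' @param fluct A [fluctuation_field()].
#' @param max_lag_px Largest lag retained for fitting; defaults to
#'   min(dim)/4 (capped at 32), the window where periodic wrap-around is
#'   negligible.
#' @return Object of class `acf_surface`: matrix `g` over centered lags with
#'   integer lag vectors `xi` (columns) and `eta` (rows), `max_lag_px`, and
#'   the pixel size.
#' @export
spatial_acf <- function(fluct, max_lag_px = NULL) {
  stopifnot(inherits(fluct, "fluctuation_field"))
  d <- fluct$delta
  nr <- nrow(d); nc <- ncol(d)
  if (is.null(max_lag_px)) max_lag_px <- min(32L, floor(min(nr, nc) / 4))
  max_lag_px <- as.integer(max_lag_px)
  if (max_lag_px < 1L || max_lag_px > floor((min(nr, nc) - 1) / 2))
    stop("`max_lag_px` must be in [1, floor((min(dim)-1)/2)]", call. = FALSE)

  FT <- stats::fft(d)
  corr <- Re(stats::fft(FT * Conj(FT), inverse = TRUE)) / length(d)^2
  g <- corr / fluct$mean_intensity^2
  # enforce exact lag-inversion symmetry (FFT round-off can break it at eps)
  refl <- g[c(1L, nr:2L), c(1L, nc:2L), drop = FALSE]
  g <- (g + refl) / 2

  # wrapped -> centered layout
  eta <- c(seq.int(-floor(nr / 2), -1L), 0L, seq_len(ceiling(nr / 2) - 1L))
  xi  <- c(seq.int(-floor(nc / 2), -1L), 0L, seq_len(ceiling(nc / 2) - 1L))
  g <- g[c((nr - floor(nr / 2) + 1L):nr, 1L:(nr - floor(nr / 2))),
         c((nc - floor(nc / 2) + 1L):nc, 1L:(nc - floor(nc / 2)))]
  structure(
    list(g = g, xi = sort(xi), eta = sort(eta), max_lag_px = max_lag_px,
         pixel_size_nm = fluct$pixel_size_nm),
    class = "acf_surface"
  )
}

#' Look up the ACF value at a given lag
#' @param acf An [spatial_acf()] surface.
#' @param xi,eta Integer pixel lags.
#' @return The ACF value g(xi, eta).
#' @export
acf_at <- function(acf, xi, eta) {
  acf$g[match(eta, acf$eta), match(xi, acf$xi)]
}

.fit_points <- function(acf) {
  keep_xi <- abs(acf$xi) <= acf$max_lag_px
  keep_eta <- abs(acf$eta) <= acf$max_lag_px
  sub <- acf$g[keep_eta, keep_xi, drop = FALSE]
  xi <- acf$xi[keep_xi]; eta <- acf$eta[keep_eta]
  df <- data.frame(xi = rep(xi, each = length(eta)),
                   eta = rep(eta, times = length(xi)),
                   g = as.vector(sub))
  df[!(df$xi == 0L & df$eta == 0L), ]
}

#' Fit the ACF with a 2D Gaussian plus offset, excluding zero lag
#'
#' Nonlinear least squares of
#' g(xi, eta) = g0 * exp(-(xi^2 + eta^2) / omega^2) + g_inf over all lags
#' with |xi|, |eta| <= max_lag_px, excluding (0, 0) so that white detection
#' noise (which inflates only the zero-lag value) does not bias the
#' amplitude. g0 is the extrapolated zero-lag amplitude; omega is the
#' correlation radius (proportional to the e^-2 radius of the effective
#' focal spot); g_inf absorbs incomplete decay from long-range correlations.
#'
#' Initialization: g0 from the mean of the four unit-lag values, omega from
#' `omega_init_px`, g_inf from the outermost fitted lag ring; up to
#' `restarts` jittered restarts before declaring non-convergence.
#'
#' @param acf An [spatial_acf()] surface.
#' @param pixel_size_nm Pixel size used to express omega in nm; defaults to
#'   the size carried by the surface.
#' @param init Optional named list overriding initial values
#'   (`g0`, `omega_px`, `g_inf`).
#' @param omega_init_px Default initial correlation radius (nominal PSF
#'   radius in pixels).
#' @param restarts Jittered restarts after a failed fit.
#' @param max_iter,ptol Optimizer controls.
#' @return Object of class `acf_fit` with `g0`, `omega_px`, `omega_nm`,
#'   `g_inf`, `rss`, `converged`, `n_points_fit`.
#' @export
fit_acf <- function(acf, pixel_size_nm = acf$pixel_size_nm, init = NULL,
                    omega_init_px = 4, restarts = 3L, max_iter = 500L,
                    ptol = 1e-10) {
  stopifnot(inherits(acf, "acf_surface"))
  pts <- .fit_points(acf)
  if (nrow(pts) < 10L)
    stop("need at least 10 non-zero-lag points within max_lag", call. = FALSE)
  if (stats::var(pts$g) == 0) {
    # flat surface (e.g. zero fluctuations): no amplitude to fit
    return(structure(list(g0 = NA_real_, omega_px = NA_real_,
                          omega_nm = NA_real_, g_inf = pts$g[1],
                          rss = 0, converged = FALSE, degenerate = TRUE,
                          n_points_fit = nrow(pts)),
                     class = "acf_fit"))
  }

  ring <- pmax(abs(pts$xi), abs(pts$eta))
  g0_0 <- mean(pts$g[ring == 1L & (abs(pts$xi) + abs(pts$eta)) == 1L])
  ginf_0 <- mean(pts$g[ring == max(ring)])
  start <- list(g0 = if (is.finite(g0_0) && g0_0 > 0) g0_0 else
                  max(pts$g) - min(pts$g) + 1e-6,
                omega_px = omega_init_px, g_inf = ginf_0)
  if (!is.null(init)) start[names(init)] <- init

  fit <- NULL
  for (att in 0:restarts) {
    st <- start
    if (att > 0) {   # deterministic jitter ladder, no RNG consumed
      fac <- c(0.5, 2, 4)[min(att, 3)]
      st$omega_px <- start$omega_px * fac
      st$g0 <- start$g0 * c(2, 0.5, 1)[min(att, 3)]
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ g0 * exp(-(xi^2 + eta^2) / omega_px^2) + g_inf,
        data = pts, start = st,
        lower = c(g0 = -Inf, omega_px = 1e-3, g_inf = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                             ptol = ptol, ftol = ptol)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }

  if (is.null(fit)) {
    return(structure(list(g0 = NA_real_, omega_px = NA_real_,
                          omega_nm = NA_real_, g_inf = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          degenerate = TRUE, n_points_fit = nrow(pts)),
                     class = "acf_fit"))
  }
  cf <- stats::coef(fit)
  degenerate <- !is.finite(cf[["g0"]]) || cf[["g0"]] <= 0
  structure(
    list(g0 = cf[["g0"]], omega_px = cf[["omega_px"]],
         omega_nm = cf[["omega_px"]] * pixel_size_nm,
         g_inf = cf[["g_inf"]],
         rss = sum(stats::residuals(fit)^2),
         converged = !degenerate, degenerate = degenerate,
         n_points_fit = nrow(pts)),
    class = "acf_fit"
  )
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf(
    "<acf_fit> g0 = %.4g, omega = %.3g px (%.3g nm), g_inf = %.3g, %s\n",
    x$g0, x$omega_px, x$omega_nm, x$g_inf,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Derive ICS metrics from a fitted ACF
#'
#' Number of independent assemblies per beam area <Na> = 1/g0; cluster
#' density CD = 1/(g0 * pi * omega^2) per square micron (omega in microns);
#' degree of aggregation DA = <I>/CD in intensity x um^2. DA is relative:
#' the optical brightness constant is absorbed into arbitrary intensity
#' units, so DA is comparable only across matched acquisition settings.
#'
#' @param fit A converged [fit_acf()] result.
#' @param fluct The [fluctuation_field()] of the same ROI.
#' @param roi_id,channel,condition Identifiers copied into the output row.
#' @return One-row `data.frame` with mean_intensity, g0, omega_nm, g_inf,
#'   n_assemblies, cluster_density_per_um2, degree_of_aggregation,
#'   converged and the identifiers.
#' @export
ics_metrics <- function(fit, fluct, roi_id = "", channel = "",
                        condition = "") {
  stopifnot(inherits(fit, "acf_fit"), inherits(fluct, "fluctuation_field"))
  if (!isTRUE(fit$converged))
    stop("ACF fit did not converge (or fitted amplitude is non-positive); ",
         "refusing to derive metrics", call. = FALSE)
  omega_um <- fit$omega_nm / 1000
  cd <- 1 / (fit$g0 * pi * omega_um^2)
  data.frame(
    roi_id = as.character(roi_id), channel = as.character(channel),
    condition = as.character(condition),
    mean_intensity = fluct$mean_intensity,
    g0 = fit$g0, omega_nm = fit$omega_nm, g_inf = fit$g_inf,
    n_assemblies = 1 / fit$g0,
    cluster_density_per_um2 = cd,
    degree_of_aggregation = fluct$mean_intensity / cd,
    converged = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Run the full ICS chain on one ROI
#'
#' Convenience wrapper: [fluctuation_field()] -> [spatial_acf()] ->
#' [fit_acf()] -> [ics_metrics()]. A non-converged or degenerate fit yields
#' a row with NA metrics and `converged = FALSE` rather than an error, so
#' batch runs can log exclusions.
#'
#' @inheritParams fluctuation_field
#' @inheritParams spatial_acf
#' @param ... Passed to [fit_acf()].
#' @param roi_id,channel,condition Identifiers for the output row.
#' @return One-row `data.frame` as in [ics_metrics()].
#' @export
ics_analyze <- function(roi, max_lag_px = NULL, background = 0, roi_id = "",
                        channel = roi$channel_label, condition = "", ...) {
  fl <- fluctuation_field(roi, background = background)
  fit <- fit_acf(spatial_acf(fl, max_lag_px), ...)
  if (isTRUE(fit$converged))
    return(ics_metrics(fit, fl, roi_id, channel, condition))
  data.frame(
    roi_id = as.character(roi_id), channel = as.character(channel),
    condition = as.character(condition),
    mean_intensity = fl$mean_intensity,
    g0 = fit$g0, omega_nm = fit$omega_nm, g_inf = fit$g_inf,
    n_assemblies = NA_real_, cluster_density_per_um2 = NA_real_,
    degree_of_aggregation = NA_real_, converged = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Pearson colocalization coefficient of two equally sized ROIs
#'
#' Standard Pearson correlation over paired pixels of the two channels,
#' typically computed on hand-picked 64 x 64 px regions.
#'
#' @param roiA,roiB [pixel_grid()] objects of identical shape.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(roiA, roiB) {
  stopifnot(inherits(roiA, "pixel_grid"), inherits(roiB, "pixel_grid"))
  if (!identical(dim(roiA$values), dim(roiB$values)))
    stop("ROIs must have identical shapes", call. = FALSE)
  a <- as.vector(roiA$values); b <- as.vector(roiB$values)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a channel is constant over the ROI",
         call. = FALSE)
  stats::cor(a, b)
}
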