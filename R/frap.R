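# Reaction-dominant FRAP analysis.
#
# In the reaction-dominant regime (diffusion equilibrates fast relative to
# binding) the normalized post-bleach recovery follows a one-phase
# exponential I(t) = P (1 - exp(-K t)), where the recovery rate K equals the
# dissociation rate K_off and the plateau P is the mobile fraction. K_on
# enters only through the plateau: S*K_on = P * K_off / F_eq, so with the
# free-binding-molecule concentration F_eq fixed and the free-site
# concentration S assumed condition-independent, P * K_off is a relative
# association-rate estimate (K*_on) comparable across conditions.

#' Normalized FRAP trace
#'
#' @param times_s Strictly increasing times in seconds, starting at 0 (the
#'   bleach frame).
#' @param values Normalized intensities (unitless).
#' @param prebleach_mean,background Raw-unit normalization metadata.
#' @param roi_area_um2 Bleach ROI area (metadata; typically 6-7 um^2).
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, values, prebleach_mean = NA_real_,
                       background = NA_real_, roi_area_um2 = NA_real_) {
  if (length(times_s) != length(values))
    stop("times and values differ in length", call. = FALSE)
  if (times_s[1] != 0 || any(diff(times_s) <= 0))
    stop("times must start at 0 and increase strictly", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 prebleach_mean = prebleach_mean, background = background,
                 roi_area_um2 = roi_area_um2),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames over %.1f s, final value %.3f\n",
              length(x$times_s), max(x$times_s),
              x$values[length(x$values)]))
  invisible(x)
}

#' Background-subtract and prebleach-normalize a raw FRAP recording
#'
#' The first `prebleach_frames` samples define the prebleach level; the next
#' frame is the bleach frame. Normalized intensity is
#' (raw - background) / (prebleach_mean - background), and the time axis is
#' re-zeroed to the bleach frame. An optional whole-cell reference trace
#' enables double normalization (correction for acquisition bleaching); off
#' by default since acquisition bleaching is typically corrected upstream or
#' absent, as verified with fixed-cell controls.
#'
#' @param raw_values Raw ROI intensities, prebleach frames first.
#' @param raw_times Acquisition times (seconds), same length.
#' @param prebleach_frames Number of leading prebleach frames (>= 2).
#' @param background Raw-unit background level to subtract.
#' @param reference_values Optional whole-cell raw trace (same length) for
#'   double normalization.
#' @param roi_area_um2 Optional bleach ROI area, carried as metadata.
#' @return A [frap_trace()] whose first frame is the bleach frame at t = 0.
#' @export
normalize_trace <- function(raw_values, raw_times, prebleach_frames = 2L,
                            background = 0, reference_values = NULL,
                            roi_area_um2 = NA_real_) {
  n_pre <- as.integer(prebleach_frames)
  if (n_pre < 2L)
    stop("need at least 2 prebleach frames", call. = FALSE)
  if (length(raw_values) != length(raw_times))
    stop("values and times differ in length", call. = FALSE)
  if (length(raw_values) < n_pre + 5L)
    stop("need at least 5 post-bleach frames", call. = FALSE)
  pre_mean <- mean(raw_values[seq_len(n_pre)])
  if (pre_mean <= background)
    stop("invalid normalization: prebleach mean does not exceed background",
         call. = FALSE)
  post <- (n_pre + 1L):length(raw_values)
  vals <- (raw_values[post] - background) / (pre_mean - background)
  if (!is.null(reference_values)) {
    ref_pre <- mean(reference_values[seq_len(n_pre)])
    ref <- (reference_values[post] - background) / (ref_pre - background)
    if (any(ref <= 0))
      stop("invalid reference trace for double normalization", call. = FALSE)
    vals <- vals / ref
  }
  frap_trace(raw_times[post] - raw_times[post[1]], vals,
             prebleach_mean = pre_mean, background = background,
             roi_area_um2 = roi_area_um2)
}

#' Fit the one-phase exponential recovery model
#'
#' Least squares of I(t) = P (1 - exp(-K t)) over all frames including the
#' bleach frame, with the model constrained through I(0) = 0 (no intercept
#' term, removing non-physical fits with negative initial fluorescence) and
#' bounds K >= 0, 0 <= P <= 1.2 (mild over-recovery from noise allowed). In
#' the reaction-dominant regime K is reported as the dissociation rate
#' K_off; the immobile fraction is 1 - P.
#'
#' @param trace A [frap_trace()].
#' @param feq Assumed free-binding-molecule concentration F_eq used for the
#'   relative K*_on = P * K_off / F_eq; default 1 (relative units).
#' @param max_iter Optimizer iteration cap.
#' @return Object of class `frap_fit`: `koff_per_s`, `plateau`,
#'   `immobile_fraction`, `kon_star_per_s`, `feq_assumed`, `rss`,
#'   `converged`, `nonphysical` (monotone-decreasing trace flag).
#' @export
fit_frap <- function(trace, feq = 1, max_iter = 500L) {
  stopifnot(inherits(trace, "frap_trace"))
  if (length(trace$times_s) < 6L)
    stop("need at least 5 post-bleach points", call. = FALSE)
  t <- trace$times_s; y <- trace$values
  nonphysical <- all(diff(y) <= 0) && y[length(y)] < y[1]

  p0 <- stats::median(utils::tail(y, 5L))
  p0 <- min(max(p0, 0.05), 1.2)
  half_idx <- which(y >= p0 / 2 & t > 0)[1]
  k0 <- if (!is.na(half_idx)) log(2) / t[half_idx] else 1 / max(t)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ P * (1 - exp(-K * t)),
      data = data.frame(t = t, y = y),
      start = list(K = max(k0, 1e-4), P = p0),
      lower = c(K = 0, P = 0), upper = c(K = Inf, P = 1.2),
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ptol = 1e-12, ftol = 1e-12)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(koff_per_s = NA_real_, plateau = NA_real_,
                          immobile_fraction = NA_real_,
                          kon_star_per_s = NA_real_, feq_assumed = feq,
                          rss = NA_real_, converged = FALSE,
                          nonphysical = nonphysical),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  K <- cf[["K"]]; P <- cf[["P"]]
  structure(
    list(koff_per_s = K, plateau = P, immobile_fraction = 1 - P,
         kon_star_per_s = kon_star_value(P, K, feq), feq_assumed = feq,
         rss = sum(stats::residuals(fit)^2),
         converged = is.finite(K) && is.finite(P) && K > 0,
         nonphysical = nonphysical),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> K_off = %.4g /s, plateau = %.3f (immobile %.3f), K*_on = %.4g /s, %s\n",
    x$koff_per_s, x$plateau, x$immobile_fraction, x$kon_star_per_s,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

kon_star_value <- function(plateau, koff, feq) {
  if (feq <= 0) stop("`feq` must be positive", call. = FALSE)
  plateau * koff / feq
}

#' Relative association-rate estimate from a FRAP fit
#'
#' K*_on = P * K_off / F_eq. With F_eq = 1 and the free-site concentration S
#' assumed condition-independent, this is a relative quantity comparable
#' across conditions.
#'
#' @param fit A converged [fit_frap()] result.
#' @param feq Assumed F_eq (positive).
#' @return Rate in 1/s (relative units when `feq = 1`).
#' @export
kon_star <- function(fit, feq = 1) {
  stopifnot(inherits(fit, "frap_fit"))
  if (!isTRUE(fit$converged))
    stop("FRAP fit did not converge; refusing to derive K*_on",
         call. = FALSE)
  kon_star_value(fit$plateau, fit$koff_per_s, feq)
}

#' Fit a batch of FRAP traces into a tidy table
#'
#' @param traces List of [frap_trace()] objects (typically >= 40 per
#'   condition).
#' @param ids Optional identifiers, recycled into the `trace_id` column.
#' @param condition Condition label for all rows.
#' @param feq Passed to [fit_frap()].
#' @return `data.frame` with one row per trace: koff_per_s, plateau,
#'   immobile_fraction, kon_star_per_s, rss, converged.
#' @export
fit_frap_batch <- function(traces, ids = seq_along(traces), condition = "",
                           feq = 1) {
  rows <- lapply(seq_along(traces), function(i) {
    f <- fit_frap(traces[[i]], feq = feq)
    data.frame(trace_id = as.character(ids[[i]]),
               condition = as.character(condition),
               koff_per_s = f$koff_per_s, plateau = f$plateau,
               immobile_fraction = f$immobile_fraction,
               kon_star_per_s = f$kon_star_per_s, rss = f$rss,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
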