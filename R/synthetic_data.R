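# Ground-truth simulator: point-emitter fields, image rendering with a
# Gaussian PSF and Poisson + Gaussian noise, and FRAP recovery traces.
#
# One master seed expands deterministically into per-stage substreams
# (placement, channel-2 placement, shot noise, read noise) so that, e.g.,
# the same emitter field can be re-rendered under different noise settings.

.SEED_STAGE <- c(placement = 1L, placement_ch2 = 2L, shot = 3L, read = 4L,
                 shot_ch2 = 5L, read_ch2 = 6L)

.substream_seed <- function(seed, stage) {
  off <- .SEED_STAGE[[stage]]
  as.integer((abs(as.numeric(seed)) * 31 + off * 7919) %% 2147483647)
}

#' Simulation parameters for synthetic STED-like fields
#'
#' Defines the statistical structure the analysis assumes: clusters placed as
#' a spatial Poisson process, a per-cluster monomer multiplicity
#' distribution, within-cluster Gaussian scatter, a Gaussian PSF, Poisson
#' shot noise and Gaussian read noise. Defaults emulate the acquisition the
#' pipeline targets: 25 nm pixels, 128 x 128 px ROIs, a 100 nm e^-2 PSF
#' radius.
#'
#' @param cluster_rate Expected independent clusters per square micron
#'   (Poisson intensity of the cluster process).
#' @param monomers_per_cluster Multiplicity model: `fixed_monomers(k)` for
#'   exactly k monomers per cluster, or `poisson_monomers(lambda)` for
#'   1 + Poisson(lambda). Default: monomeric speckles, `fixed_monomers(1)`.
#' @param cluster_spread_nm Isotropic Gaussian SD of monomer positions about
#'   their cluster center (0 = point-like assemblies).
#' @param co_aggregation Fraction of channel-2 clusters placed at channel-1
#'   cluster centers (co-sequestration); only meaningful for two channels.
#' @param psf_e2_radius_nm e^-2 radius of the effective PSF. The effective
#'   STED spot size is instrument-dependent; 100 nm (4 px at 25 nm/px) is a
#'   plausible default, and the correlation radius is fitted anyway.
#' @param pixel_size_nm Physical pixel size, default 25.
#' @param roi_px Rendered field extent in pixels, default 128.
#' @param brightness_photons Expected photons contributed by one monomer per
#'   exposure.
#' @param background_mean Uniform background level (photons/pixel) added
#'   before shot noise.
#' @param read_noise_sd SD of additive Gaussian read noise (0 disables).
#' @param shot_noise Apply Poisson shot noise to the expected photon image.
#' @param margin_nm Emitters are also placed within this margin outside the
#'   rendered field so edge pixels see realistically truncated spots;
#'   default 3 x PSF radius. Set 0 to confine emitters to the field.
#' @param seed Master integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(cluster_rate = 30,
                       monomers_per_cluster = fixed_monomers(1L),
                       cluster_spread_nm = 0,
                       co_aggregation = 0,
                       psf_e2_radius_nm = 100,
                       pixel_size_nm = 25,
                       roi_px = 128L,
                       brightness_photons = 500,
                       background_mean = 10,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       margin_nm = 3 * psf_e2_radius_nm,
                       seed = 1L) {
  stopifnot(cluster_rate >= 0, cluster_spread_nm >= 0,
            co_aggregation >= 0, co_aggregation <= 1,
            psf_e2_radius_nm > 0, pixel_size_nm > 0,
            brightness_photons > 0, background_mean >= 0,
            margin_nm >= 0)
  if (read_noise_sd < 0)
    stop("`read_noise_sd` must be non-negative", call. = FALSE)
  roi_px <- as.integer(roi_px)
  if (roi_px <= 0)
    stop("non-positive field area: `roi_px` must be positive", call. = FALSE)
  if (psf_e2_radius_nm < pixel_size_nm / 4)
    warning("PSF e^-2 radius below pixel_size/4: the PSF is undersampled",
            call. = FALSE)
  structure(
    list(cluster_rate = cluster_rate,
         monomers_per_cluster = monomers_per_cluster,
         cluster_spread_nm = cluster_spread_nm,
         co_aggregation = co_aggregation,
         psf_e2_radius_nm = psf_e2_radius_nm,
         pixel_size_nm = pixel_size_nm,
         roi_px = roi_px,
         brightness_photons = brightness_photons,
         background_mean = background_mean,
         read_noise_sd = read_noise_sd,
         shot_noise = shot_noise,
         margin_nm = margin_nm,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Fixed cluster multiplicity
#' @param k Monomers per cluster (positive integer).
#' @return Multiplicity spec for [sim_params()].
#' @export
fixed_monomers <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(type = "fixed", k = k, mean = as.numeric(k)),
            class = "monomer_dist")
}

#' Shifted-Poisson cluster multiplicity: 1 + Poisson(lambda)
#' @param lambda Mean excess monomers per cluster (non-negative).
#' @return Multiplicity spec for [sim_params()].
#' @export
poisson_monomers <- function(lambda) {
  stopifnot(lambda >= 0)
  structure(list(type = "poisson", lambda = lambda, mean = 1 + lambda),
            class = "monomer_dist")
}

.draw_multiplicities <- function(dist, n) {
  if (n == 0L) return(integer(0))
  switch(dist$type,
         fixed = rep(dist$k, n),
         poisson = 1L + stats::rpois(n, dist$lambda),
         stop("unknown multiplicity model", call. = FALSE))
}

#' Construct an emitter field from explicit positions
#'
#' Builds the ground-truth record [render_image()] consumes, for
#' hand-crafted configurations. Positions are in nm in the rendered-field
#' frame and must lie within `[-margin_nm, field_extent_nm + margin_nm)`.
#'
#' @param x_nm,y_nm Emitter coordinates in nm.
#' @param cluster_id Integer cluster assignment per emitter; every cluster
#'   must be non-empty (ids are the set of values present).
#' @param brightness Photons per emitter per exposure (positive), recycled.
#' @param field_extent_nm Rendered field extent in nm.
#' @param margin_nm Placement margin outside the field.
#' @param channel_label Channel label.
#' @return An `emitter_field` object.
#' @export
emitter_field <- function(x_nm, y_nm, cluster_id = seq_along(x_nm),
                          brightness = 1, field_extent_nm,
                          margin_nm = 0, channel_label = "ch0") {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n, length(cluster_id) == n)
  brightness <- rep_len(brightness, n)
  if (any(brightness <= 0))
    stop("brightness must be positive for every emitter", call. = FALSE)
  lo <- -margin_nm; hi <- field_extent_nm + margin_nm
  if (n > 0 && (any(x_nm < lo | x_nm >= hi) || any(y_nm < lo | y_nm >= hi)))
    stop("emitter positions outside the placement region", call. = FALSE)
  cid <- as.integer(cluster_id)
  centers <- if (n > 0)
    cbind(x_nm = tapply(x_nm, cid, mean)[as.character(sort(unique(cid)))],
          y_nm = tapply(y_nm, cid, mean)[as.character(sort(unique(cid)))])
  else cbind(x_nm = numeric(0), y_nm = numeric(0))
  structure(
    list(emitters = data.frame(x_nm = as.numeric(x_nm),
                               y_nm = as.numeric(y_nm),
                               cluster_id = cid, brightness = brightness),
         cluster_centers = centers,
         field_extent_nm = field_extent_nm, margin_nm = margin_nm,
         channel_label = as.character(channel_label)),
    class = "emitter_field"
  )
}

#' Simulate a ground-truth emitter field
#'
#' Cluster centers follow a homogeneous spatial Poisson process of intensity
#' `cluster_rate` over the placement region (the rendered field plus
#' `margin_nm` on every side); each cluster receives a number of monomers
#' drawn from the multiplicity model, scattered isotropically with SD
#' `cluster_spread_nm` about the center. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param channel Channel label recorded in the field.
#' @param centers Optional matrix of cluster centers (x_nm, y_nm) to reuse
#'   (e.g. forced co-aggregation); overrides Poisson placement.
#' @return An object of class `emitter_field`: `emitters` data frame
#'   (x_nm, y_nm, cluster_id, brightness), field extent, margin and channel.
#'   Coordinates are in the rendered-field frame, so x and y lie in
#'   `[-margin_nm, field_extent + margin_nm)`.
#' @export
simulate_emitter_field <- function(params, channel = "ch0", centers = NULL) {
  stopifnot(inherits(params, "sim_params"))
  extent_nm <- params$roi_px * params$pixel_size_nm
  m <- params$margin_nm
  place_w <- extent_nm + 2 * m
  area_um2 <- (place_w / 1000)^2
  if (area_um2 <= 0)
    stop("non-positive field area", call. = FALSE)

  stage <- if (identical(channel, "ch1")) "placement_ch2" else "placement"
  set.seed(.substream_seed(params$seed, stage))

  if (is.null(centers)) {
    n_clusters <- stats::rpois(1, params$cluster_rate * area_um2)
    cx <- stats::runif(n_clusters, -m, extent_nm + m)
    cy <- stats::runif(n_clusters, -m, extent_nm + m)
  } else {
    n_clusters <- nrow(centers)
    cx <- centers[, 1]; cy <- centers[, 2]
  }

  mult <- .draw_multiplicities(params$monomers_per_cluster, n_clusters)
  idx <- rep.int(seq_len(n_clusters), mult)
  n_em <- length(idx)
  sd <- params$cluster_spread_nm
  ex <- cx[idx] + if (sd > 0) stats::rnorm(n_em, 0, sd) else 0
  ey <- cy[idx] + if (sd > 0) stats::rnorm(n_em, 0, sd) else 0

  structure(
    list(emitters = data.frame(x_nm = ex, y_nm = ey, cluster_id = idx,
                               brightness = rep(params$brightness_photons,
                                                n_em)),
         cluster_centers = cbind(x_nm = cx, y_nm = cy),
         field_extent_nm = extent_nm,
         margin_nm = m,
         channel_label = as.character(channel)),
    class = "emitter_field"
  )
}

#' @export
print.emitter_field <- function(x, ...) {
  cat(sprintf(
    "<emitter_field> %d emitters in %d clusters, %.2f um field (+%g nm margin), channel '%s'\n",
    nrow(x$emitters), nrow(x$cluster_centers), x$field_extent_nm / 1000,
    x$margin_nm, x$channel_label))
  invisible(x)
}

#' Render an emitter field into a noisy image
#'
#' Each emitter contributes a 2D Gaussian spot whose intensity profile has
#' the e^-2 radius `psf_e2_radius_nm` (i.e. Gaussian SD = radius/2),
#' integrated exactly over pixel areas so each interior spot sums to the
#' emitter brightness. A uniform background is added, then Poisson shot
#' noise, then Gaussian read noise (clamped at 0). Noise substreams derive
#' from the master seed, so the same field re-renders bit-identically.
#'
#' @param field An [simulate_emitter_field()] result.
#' @param params The [sim_params()] used (geometry, PSF and noise settings).
#' @return A [pixel_grid()] of `roi_px` x `roi_px` photon counts. Rows index
#'   y, columns x.
#' @export
render_image <- function(field, params) {
  stopifnot(inherits(field, "emitter_field"), inherits(params, "sim_params"))
  if (field$field_extent_nm != params$roi_px * params$pixel_size_nm)
    stop("field extent does not match params geometry", call. = FALSE)
  n <- params$roi_px
  px <- params$pixel_size_nm
  sigma <- params$psf_e2_radius_nm / 2   # e^-2 intensity radius -> Gaussian SD
  img <- matrix(0, n, n)

  em <- field$emitters
  if (nrow(em) > 0) {
    win <- ceiling(5 * sigma / px)       # +/- 5 SD covers > 1 - 1e-6 of mass
    edges <- (0:n) * px                  # pixel boundaries, nm
    for (i in seq_len(nrow(em))) {
      # columns index x, rows index y
      jc <- floor(em$x_nm[i] / px); ic <- floor(em$y_nm[i] / px)
      cols <- max(1L, jc + 1L - win):min(n, jc + 1L + win)
      rows <- max(1L, ic + 1L - win):min(n, ic + 1L + win)
      if (length(cols) == 0L || length(rows) == 0L ||
          cols[1] > cols[length(cols)] || rows[1] > rows[length(rows)]) next
      fx <- diff(stats::pnorm(edges[c(cols, cols[length(cols)] + 1L)],
                              em$x_nm[i], sigma))
      fy <- diff(stats::pnorm(edges[c(rows, rows[length(rows)] + 1L)],
                              em$y_nm[i], sigma))
      img[rows, cols] <- img[rows, cols] + em$brightness[i] * (fy %o% fx)
    }
  }
  img <- img + params$background_mean

  ch2 <- identical(field$channel_label, "ch1")
  if (params$shot_noise) {
    set.seed(.substream_seed(params$seed, if (ch2) "shot_ch2" else "shot"))
    img[] <- stats::rpois(length(img), lambda = img)
  }
  if (params$read_noise_sd > 0) {
    set.seed(.substream_seed(params$seed, if (ch2) "read_ch2" else "read"))
    img[] <- pmax(0, img + stats::rnorm(length(img), 0,
                                        params$read_noise_sd))
  }
  pixel_grid(img, params$pixel_size_nm,
             channel_label = field$channel_label)
}

#' Simulate a two-channel co-expression field
#'
#' Channel-1 clusters are placed as usual; each channel-2 cluster is placed
#' at a randomly chosen channel-1 cluster center with probability
#' `co_aggregation` (co-sequestration, as when an aggregating mutant recruits
#' the wild-type protein) and independently otherwise (exclusion). Both
#' channels are rendered with independent noise substreams.
#'
#' @param params A [sim_params()]; `co_aggregation` controls the overlap.
#' @return List with `image_ch0`, `image_ch1` ([pixel_grid()]) and
#'   `field_ch0`, `field_ch1` (ground truth).
#' @export
simulate_two_channel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  f1 <- simulate_emitter_field(params, channel = "ch0")

  extent_nm <- params$roi_px * params$pixel_size_nm
  m <- params$margin_nm
  area_um2 <- ((extent_nm + 2 * m) / 1000)^2
  set.seed(.substream_seed(params$seed, "placement_ch2"))
  n2 <- stats::rpois(1, params$cluster_rate * area_um2)
  shared <- stats::runif(n2) < params$co_aggregation
  cx <- stats::runif(n2, -m, extent_nm + m)
  cy <- stats::runif(n2, -m, extent_nm + m)
  n1 <- nrow(f1$cluster_centers)
  if (any(shared) && n1 > 0) {
    pick <- sample.int(n1, sum(shared), replace = TRUE)
    cx[shared] <- f1$cluster_centers[pick, 1]
    cy[shared] <- f1$cluster_centers[pick, 2]
  }
  f2 <- simulate_emitter_field(params, channel = "ch1",
                               centers = cbind(cx, cy))
  list(image_ch0 = render_image(f1, params),
       image_ch1 = render_image(f2, params),
       field_ch0 = f1, field_ch1 = f2)
}

#' FRAP acquisition schedule
#'
#' Sampling times of the post-bleach recovery: the bleach frame at t = 0
#' followed by the cumulative times of each (n_frames, interval_s) segment.
#' The default is the three-segment schedule 5 frames at 0.526 s, 15 at 1 s
#' and 30 at 4 s.
#'
#' @param segments List of `c(n_frames, interval_s)` pairs.
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
frap_schedule <- function(segments = list(c(5, 0.526), c(15, 1), c(30, 4))) {
  ints <- unlist(lapply(segments, function(s) {
    stopifnot(length(s) == 2, s[1] >= 1, s[2] > 0)
    rep(s[2], s[1])
  }))
  c(0, cumsum(ints))
}

#' Simulate a normalized FRAP recovery trace
#'
#' Samples the reaction-dominant one-phase model
#' \eqn{I(t) = P (1 - e^{-K t})} on the given schedule and adds i.i.d.
#' Gaussian noise. The bleach frame t = 0 is included (value 0 plus noise);
#' prebleach frames are not part of the normalized trace.
#'
#' @param koff Recovery rate K in 1/s (equals the dissociation rate in the
#'   reaction-dominant regime); must be positive.
#' @param plateau Mobile fraction P in `[0, 1]`.
#' @param schedule Sampling times from [frap_schedule()].
#' @param noise_sd SD of additive Gaussian noise (0 = noiseless).
#' @param seed Integer seed.
#' @return An object of class `frap_trace` with `times_s` and `values`.
#' @export
simulate_frap_trace <- function(koff, plateau, schedule = frap_schedule(),
                                noise_sd = 0, seed = 1L) {
  if (!is.numeric(koff) || koff <= 0)
    stop("`koff` must be positive", call. = FALSE)
  if (plateau < 0 || plateau > 1)
    stop("`plateau` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("`noise_sd` must be non-negative", call. = FALSE)
  vals <- plateau * (1 - exp(-koff * schedule))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  }
  frap_trace(schedule, vals)
}

#' Write a two-channel simulation to disk
#'
#' One 16-bit TIFF per channel, a ground-truth CSV
#' (x_nm, y_nm, cluster_id, brightness, channel) and a JSON sidecar with the
#' simulation parameters.
#'
#' @param sim Result of [simulate_two_channel()].
#' @param params The [sim_params()] used.
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, params, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_ch0 <- file.path(dir, "ch0.tif")
  p_ch1 <- file.path(dir, "ch1.tif")
  write_image(sim$image_ch0, p_ch0)
  write_image(sim$image_ch1, p_ch1)
  truth <- rbind(
    cbind(sim$field_ch0$emitters, channel = "ch0"),
    cbind(sim$field_ch1$emitters, channel = "ch1"))
  p_truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(truth, p_truth, row.names = FALSE)
  p_json <- file.path(dir, "params.json")
  pj <- params
  pj$monomers_per_cluster <- unclass(pj$monomers_per_cluster)
  jsonlite::write_json(unclass(pj), p_json, auto_unbox = TRUE, digits = NA)
  invisible(list(ch0 = p_ch0, ch1 = p_ch1, truth = p_truth,
                 params = p_json))
}
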