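# Independent oracles used across the suite.

# Direct double-loop spatial ACF under the periodic convention:
# g(xi, eta) = (1/N) sum_xy delta(x, y) delta(x+xi, y+eta) / mean^2
acf_direct_oracle <- function(delta, mean_intensity, xi, eta) {
  nr <- nrow(delta); nc <- ncol(delta)
  s <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- ((i - 1 + eta) %% nr) + 1
    jj <- ((j - 1 + xi) %% nc) + 1
    s <- s + delta[i, j] * delta[ii, jj]
  }
  s / (nr * nc * mean_intensity^2)
}

# Mann-Whitney U by pair counting, and the exact two-sided p by full
# enumeration of all C(n1+n2, n1) group labelings of the pooled sample.
mw_u_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- mw_u_pairs(x, y)
  center <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(k) mw_u_pairs(pooled[k], pooled[-k]))
  p <- mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
  list(u = u_obs, p = p)
}

# Exact model ACF surface on a centered lag grid, with the zero-lag value
# optionally corrupted (as white noise would).
model_acf_surface <- function(g0, omega_px, g_inf, half = 32L,
                              corrupt_zero_lag = NA, pixel_size_nm = 25,
                              max_lag_px = half %/% 2) {
  xi <- seq.int(-half, half - 1L)
  eta <- xi
  g <- outer(eta, xi, function(e, x) g0 * exp(-(x^2 + e^2) / omega_px^2) +
               g_inf)
  if (!is.na(corrupt_zero_lag))
    g[eta == 0L, xi == 0L] <- corrupt_zero_lag
  structure(list(g = g, xi = xi, eta = eta,
                 max_lag_px = as.integer(max_lag_px),
                 pixel_size_nm = pixel_size_nm),
            class = "acf_surface")
}

# One ICS run on a fresh simulation; returns the metrics row.
sim_and_analyze <- function(seed, ...) {
  p <- sim_params(seed = seed, ...)
  img <- render_image(simulate_emitter_field(p), p)
  ics_analyze(img, background = p$background_mean, roi_id = seed)
}
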