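# Independent oracles used to freeze expected values.

# invert the Forster relation numerically (root finding on the forward map)
# instead of using the closed-form inverse under test
oracle_distance_for_efficiency <- function(E, r0 = 5.3) {
  stats::uniroot(function(R) r0^6 / (r0^6 + R^6) - E,
                 lower = r0 / 100, upper = r0 * 100, tol = 1e-12)$root
}

# brute-force O(n^2) circular convolution of a wrapped multi-exponential
# with a unit-normalized kernel (direct summation; no FFT)
oracle_reconvolution <- function(components, irf_counts, time_ns, period_ns) {
  n <- length(time_ns)
  kern <- irf_counts / sum(irf_counts)
  t0 <- time_ns - time_ns[1] + (time_ns[2] - time_ns[1]) / 2
  d <- rep(0, n)
  for (i in seq_len(nrow(components))) {
    tau <- components$lifetime_ns[i]
    d <- d + components$amplitude[i] * exp(-t0 / tau) / (1 - exp(-period_ns / tau))
  }
  out <- numeric(n)
  for (k in seq_len(n)) {
    idx <- ((k - seq_len(n)) %% n) + 1
    out[k] <- sum(kern * d[idx])
  }
  out
}

# small dual-view movie fixture: a handful of vesicles, short stack
tiny_movie <- function(efret = 0.45, n_frames = 30, seed = 11,
                       field_um = c(9, 9), shift = c(dx = 2, dy = -1), ...) {
  fld <- simulate_vesicle_field(field_um = field_um, seed = seed)
  simulate_movie(fld, efret = efret, n_frames = n_frames,
                 channel_shift_px = shift, seed = seed, ...)
}
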