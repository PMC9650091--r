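#' TCSPC decay histogram and instrument response function
#'
#' Containers for time-correlated single-photon-counting data: a histogram
#' of photon arrival times (uniform bins over one excitation period) and the
#' matching instrument response function (IRF) on the same grid convention.
#'
#' @param time_ns Uniform bin centers (ns), strictly increasing.
#' @param counts Nonnegative counts per bin (integers for measured decays).
#' @param rep_period_ns Excitation repetition period: 12.5 ns for 80 MHz
#'   (DiI--DiD), 50 ns for 20 MHz (FliptR).
#' @return `decay_histogram` / `tcspc_irf` objects.
#' @export
decay_histogram <- function(time_ns, counts, rep_period_ns = 12.5) {
  check_tcspc_grid(time_ns)
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be nonnegative")
  if (max(counts) <= 0) stop("decay histogram has no counts")
  structure(list(time_ns = as.numeric(time_ns), counts = as.numeric(counts),
                 rep_period_ns = rep_period_ns),
            class = "decay_histogram")
}

#' @rdname decay_histogram
#' @export
tcspc_irf <- function(time_ns, counts) {
  check_tcspc_grid(time_ns)
  if (any(!is.finite(counts)) || any(counts < 0)) stop("IRF counts must be nonnegative")
  if (sum(counts) <= 0) stop("IRF is not normalizable (sums to 0)")
  structure(list(time_ns = as.numeric(time_ns), counts = as.numeric(counts)),
            class = "tcspc_irf")
}

check_tcspc_grid <- function(time_ns) {
  if (length(time_ns) < 8L) stop("time grid too short")
  dt <- diff(time_ns)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("time grid must be uniform and increasing")
  }
  invisible(TRUE)
}

# circular shift of x by s bins (s may be fractional; linear interpolation)
roll_frac <- function(x, s) {
  n <- length(x)
  s0 <- floor(s)
  f <- s - s0
  idx <- function(k) ((seq_len(n) - 1 - k) %% n) + 1
  if (f == 0) return(x[idx(s0)])
  (1 - f) * x[idx(s0)] + f * x[idx(s0 + 1)]
}

#' Periodic reconvolution model for a multi-exponential decay
#'
#' Computes model counts per bin for \eqn{\sum_i a_i e^{-t/\tau_i}} under
#' periodic excitation: each component is wrapped over the repetition
#' period (geometric pile-up of incomplete decay from earlier pulses), the
#' sum is circularly convolved with the unit-normalized IRF, shifted by a
#' sub-bin timing offset, and a constant background is added.
#'
#' @param components Data.frame (or list coercible to one) with columns
#'   `amplitude` (>= 0) and `lifetime_ns` (> 0).
#' @param irf A [tcspc_irf()].
#' @param rep_period_ns Repetition period (ns); defaults to the full grid span.
#' @param offset Constant background counts per bin.
#' @param shift_ns IRF-to-decay timing offset (ns), applied by circular
#'   sub-bin linear interpolation.
#' @return Model counts on the IRF grid (all >= `offset`).
#' @export
convolve_irf <- function(components, irf, rep_period_ns = NULL,
                         offset = 0, shift_ns = 0) {
  stopifnot(inherits(irf, "tcspc_irf"))
  comp <- as.data.frame(components)
  if (!all(c("amplitude", "lifetime_ns") %in% names(comp))) {
    stop("'components' needs columns amplitude and lifetime_ns")
  }
  if (any(comp$lifetime_ns <= 0)) stop("lifetimes must be positive")
  if (any(comp$amplitude < 0)) stop("amplitudes must be nonnegative")
  t <- irf$time_ns
  n <- length(t)
  dt <- t[2] - t[1]
  if (is.null(rep_period_ns)) rep_period_ns <- n * dt
  irf_sum <- sum(irf$counts)
  if (irf_sum <= 0) stop("IRF sums to 0: cannot normalize")
  kernel <- irf$counts / irf_sum

  t0 <- t - t[1] + dt / 2            # bin-center sampling of the decay clock
  d <- numeric(n)
  for (i in seq_len(nrow(comp))) {
    tau <- comp$lifetime_ns[i]
    wrap <- 1 - exp(-rep_period_ns / tau)
    d <- d + comp$amplitude[i] * exp(-t0 / tau) / wrap
  }
  m <- Re(stats::fft(stats::fft(d) * stats::fft(kernel), inverse = TRUE)) / n
  m <- roll_frac(m, shift_ns / dt)
  pmax(m, 0) + offset
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' \deqn{\tau_{av} = \sum_i a_i \tau_i / \sum_i a_i}
#'
#' @inheritParams convolve_irf
#' @return Lifetime in ns.
#' @examples
#' amplitude_weighted_lifetime(data.frame(amplitude = c(0.7, 0.3),
#'                                        lifetime_ns = c(1, 3)))  # 1.6
#' @export
amplitude_weighted_lifetime <- function(components) {
  comp <- as.data.frame(components)
  a <- comp$amplitude
  if (sum(a) <= 0) stop("sum of amplitudes is zero: tau_av undefined")
  sum(a * comp$lifetime_ns) / sum(a)
}

#' Fit a TCSPC decay by iterative reconvolution
#'
#' Weighted least-squares fit of [convolve_irf()]'s periodic reconvolution
#' model to a measured decay. Free parameters are the component amplitudes
#' and lifetimes, a constant background, and the IRF timing shift.
#' Residuals carry Poisson weights \eqn{1/\sqrt{\max(m_k, 1)}} with the
#' variance taken from the model counts \eqn{m_k} (Pearson weighting,
#' re-evaluated at every iteration). Estimating the variance from the
#' observed counts instead (Neyman weighting) overweights downward
#' fluctuations and biases the lifetimes upward by a fraction of a percent
#' at 1e4 peak counts -- enough to spoil bootstrap interval coverage -- so
#' the model-based form is used. The fit window runs from the first bin
#' reaching `rise_fraction` of the peak (rising edge) to the end of the
#' record.
#'
#' Lifetimes closer than 5\% relative after convergence are considered
#' indistinguishable: their amplitudes are summed and the fit is re-run with
#' one component fewer, so a silently degenerate model is never returned.
#'
#' @param decay A [decay_histogram()].
#' @param irf A [tcspc_irf()] on the same grid.
#' @param n_components Number of exponential components (1--4).
#' @param rise_fraction Fraction of the peak defining the fit-window start.
#' @param start Optional named list (`amplitude`, `lifetime_ns`, `offset`,
#'   `shift_ns`) overriding the automatic initialization.
#' @param max_iter Maximum Levenberg--Marquardt iterations.
#' @param max_shift_bins Bound on |shift| in bins.
#' @return A `decay_fit`: `components` (sorted by lifetime), `offset`,
#'   `shift_ns`, `chi2_reduced`, `tau_av_ns`, `fitted`, `fit_range`,
#'   `n_merged`.
#' @export
fit_reconvolution <- function(decay, irf, n_components = 2,
                              rise_fraction = 0.01, start = NULL,
                              max_iter = 200, max_shift_bins = 5) {
  stopifnot(inherits(decay, "decay_histogram"), inherits(irf, "tcspc_irf"))
  if (!(n_components %in% 1:4)) stop("'n_components' must be in 1..4")
  if (length(decay$time_ns) != length(irf$time_ns) ||
      abs(decay$time_ns[1] - irf$time_ns[1]) > 1e-9 ||
      abs(diff(decay$time_ns[1:2]) - diff(irf$time_ns[1:2])) > 1e-9) {
    stop("decay and IRF must share the time grid")
  }
  t <- decay$time_ns
  y <- decay$counts
  n <- length(t)
  dt <- t[2] - t[1]
  period <- decay$rep_period_ns

  peak <- max(y)
  i_rise <- which(y >= rise_fraction * peak)[1]
  fit_idx <- i_rise:n
  n_par <- 2L * n_components + 2L
  if (length(fit_idx) < 5L * n_par) {
    stop("too few bins in fit window for ", n_components,
         " components (need >= ", 5L * n_par, ")")
  }

  # initialization: background from pre-rise bins, lifetimes log-spaced
  # around a tail estimate, amplitudes scaled to the peak
  if (is.null(start)) {
    offset0 <- if (i_rise > 4) stats::median(y[1:(i_rise - 1)]) else min(y)
    tau0 <- estimate_tail_lifetime(t, y, offset0)
    taus <- if (n_components == 1) tau0 else
      exp(seq(log(tau0 / 3), log(tau0 * 1.5), length.out = n_components))
    amps <- rep(peak / n_components, n_components)
    shift0 <- 0
  } else {
    taus <- start$lifetime_ns
    amps <- start$amplitude
    offset0 <- if (is.null(start$offset)) 0 else start$offset
    shift0 <- if (is.null(start$shift_ns)) 0 else start$shift_ns
    stopifnot(length(taus) == n_components, length(amps) == n_components)
  }

  # parameter vector: amplitudes, log-lifetimes, offset, shift
  pack <- function(a, tau, off, sh) c(a, log(tau), off, sh)
  unpack <- function(p) {
    list(a = p[1:n_components],
         tau = exp(p[(n_components + 1):(2 * n_components)]),
         off = p[2 * n_components + 1],
         sh = p[2 * n_components + 2])
  }
  kernel_fft <- stats::fft(irf$counts / sum(irf$counts))
  model_of <- function(p) {
    q <- unpack(p)
    t0 <- t - t[1] + dt / 2
    d <- numeric(n)
    for (i in seq_len(n_components)) {
      d <- d + q$a[i] * exp(-t0 / q$tau[i]) / (1 - exp(-period / q$tau[i]))
    }
    m <- Re(stats::fft(stats::fft(d) * kernel_fft, inverse = TRUE)) / n
    pmax(roll_frac(m, q$sh / dt), 0) + q$off
  }
  resid_fn <- function(p) {
    m <- model_of(p)[fit_idx]
    (m - y[fit_idx]) / sqrt(pmax(m, 1))
  }

  lower <- c(rep(0, n_components), rep(log(dt / 20), n_components), 0,
             -max_shift_bins * dt)
  upper <- c(rep(Inf, n_components), rep(log(50 * period), n_components), Inf,
             max_shift_bins * dt)
  fit <- minpack.lm::nls.lm(
    par = pack(amps, taus, offset0, shift0),
    lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  q <- unpack(fit$par)
  ord <- order(q$tau)
  comp <- data.frame(amplitude = q$a[ord], lifetime_ns = q$tau[ord])

  # an over-specified model drifts to sub-bin lifetimes or vanishing
  # amplitudes; prune such components and refit the reduced model
  degenerate <- comp$lifetime_ns <= dt / 4 |
    comp$amplitude <= 1e-6 * max(sum(comp$amplitude), 1)
  if (any(degenerate) && nrow(comp) > 1L && !all(degenerate)) {
    keep <- comp[!degenerate, , drop = FALSE]
    sub <- fit_reconvolution(decay, irf, n_components = nrow(keep),
                             rise_fraction = rise_fraction,
                             start = list(amplitude = keep$amplitude,
                                          lifetime_ns = keep$lifetime_ns,
                                          offset = q$off, shift_ns = q$sh),
                             max_iter = max_iter,
                             max_shift_bins = max_shift_bins)
    sub$n_merged <- sub$n_merged + sum(degenerate)
    return(sub)
  }
  if (fit$info == 0 || fit$info == 5) {
    stop(structure(class = c("luvfret_convergence_error", "error", "condition"),
                   list(message = paste0(
                          "reconvolution fit did not converge (info=", fit$info,
                          "); last iterate: ",
                          paste(signif(fit$par, 4), collapse = ", ")),
                        call = sys.call(-1), last_par = fit$par)))
  }

  # merge lifetimes within 5% relative and refit the reduced model
  merged <- merge_close_lifetimes(comp, tol = 0.05)
  if (nrow(merged) < nrow(comp)) {
    sub <- fit_reconvolution(decay, irf, n_components = nrow(merged),
                             rise_fraction = rise_fraction,
                             start = list(amplitude = merged$amplitude,
                                          lifetime_ns = merged$lifetime_ns,
                                          offset = q$off, shift_ns = q$sh),
                             max_iter = max_iter,
                             max_shift_bins = max_shift_bins)
    sub$n_merged <- sub$n_merged + (nrow(comp) - nrow(merged))
    return(sub)
  }

  fitted <- model_of(fit$par)
  chi2 <- sum((fitted[fit_idx] - y[fit_idx])^2 / pmax(fitted[fit_idx], 1)) /
    (length(fit_idx) - n_par)
  structure(list(components = comp,
                 offset = q$off, shift_ns = q$sh,
                 chi2_reduced = chi2,
                 tau_av_ns = amplitude_weighted_lifetime(comp),
                 fitted = fitted, fit_range = range(fit_idx),
                 n_merged = 0L,
                 decay = decay, irf = irf),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Reconvolution fit:", nrow(x$components), "component(s)\n")
  print(transform(x$components,
                  fraction = x$components$amplitude / sum(x$components$amplitude)))
  cat(sprintf("tau_av = %.4g ns, offset = %.3g, shift = %.3g ns, chi2_red = %.3f\n",
              x$tau_av_ns, x$offset, x$shift_ns, x$chi2_reduced))
  invisible(x)
}

# crude tail-slope lifetime estimate used for initialization
estimate_tail_lifetime <- function(t, y, offset) {
  i_peak <- which.max(y)
  yc <- pmax(y - offset, 0.5)
  tail_idx <- seq(min(i_peak + 2, length(t)), length(t))
  tail_idx <- tail_idx[yc[tail_idx] > 1]
  if (length(tail_idx) < 5) return((t[length(t)] - t[i_peak]) / 3)
  cf <- stats::coef(stats::lm(log(yc[tail_idx]) ~ t[tail_idx]))
  slope <- cf[2]
  if (!is.finite(slope) || slope >= -1e-9) return((t[length(t)] - t[i_peak]) / 3)
  min(-1 / slope, t[length(t)] - t[1])
}

merge_close_lifetimes <- function(comp, tol = 0.05) {
  comp <- comp[order(comp$lifetime_ns), , drop = FALSE]
  i <- 1L
  while (i < nrow(comp)) {
    t1 <- comp$lifetime_ns[i]; t2 <- comp$lifetime_ns[i + 1]
    if ((t2 - t1) / ((t1 + t2) / 2) < tol) {
      a <- comp$amplitude[i] + comp$amplitude[i + 1]
      tau <- (comp$amplitude[i] * t1 + comp$amplitude[i + 1] * t2) / max(a, .Machine$double.eps)
      comp$amplitude[i] <- a
      comp$lifetime_ns[i] <- tau
      comp <- comp[-(i + 1), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(comp) <- NULL
  comp
}

#' Parametric bootstrap confidence intervals for decay lifetimes
#'
#' Resamples each bin of the fitted reconvolution model with Poisson noise,
#' refits every replicate, and returns 2.5/97.5 percentile intervals for
#' each lifetime, each amplitude and the amplitude-weighted lifetime.
#' Reproducible for a given seed; the caller's RNG state is untouched.
#'
#' @inheritParams fit_reconvolution
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param ... Passed on to [fit_reconvolution()].
#' @return List with `fit` (the original fit), `replicates` (one row per
#'   successful replicate: lifetimes, amplitudes, tau_av), `intervals`
#'   (2.5/97.5 percentiles), `n_failed`.
#' @export
bootstrap_lifetimes <- function(decay, irf, n_components = 2, n_boot = 100,
                                seed = 1, ...) {
  if (n_boot < 2) stop("'n_boot' must be >= 2")
  fit0 <- fit_reconvolution(decay, irf, n_components, ...)
  k <- nrow(fit0$components)
  mu <- fit0$fitted
  start <- list(amplitude = fit0$components$amplitude,
                lifetime_ns = fit0$components$lifetime_ns,
                offset = fit0$offset, shift_ns = fit0$shift_ns)

  rows <- with_preserved_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      yb <- stats::rpois(length(mu), mu)
      db <- decay_histogram(decay$time_ns, pmax(yb, 0), decay$rep_period_ns)
      fb <- tryCatch(fit_reconvolution(db, irf, n_components = k, start = start, ...),
                     error = function(e) NULL)
      if (is.null(fb) || nrow(fb$components) != k) return(NULL)
      c(fb$components$lifetime_ns, fb$components$amplitude, fb$tau_av_ns)
    })
  })
  ok <- !vapply(rows, is.null, TRUE)
  if (mean(!ok) > 0.2) {
    stop("bootstrap unstable: >20% of replicate fits failed")
  }
  rep_mat <- do.call(rbind, rows[ok])
  colnames(rep_mat) <- c(paste0("tau", seq_len(k)), paste0("a", seq_len(k)), "tau_av")
  ints <- apply(rep_mat, 2, stats::quantile, probs = c(0.025, 0.975))
  list(fit = fit0,
       replicates = as.data.frame(rep_mat),
       intervals = ints,
       n_failed = sum(!ok))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read / write TCSPC decay tables
#'
#' CSV format: columns `time_ns`, `counts`; the repetition period travels in
#' a `# rep_period_ns=` comment header line.
#'
#' @param path CSV path.
#' @return A [decay_histogram()] (reader).
#' @export
read_decay_csv <- function(path) {
  first <- readLines(path, n = 1L)
  period <- 12.5
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("rep_period_ns=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) period <- as.numeric(m[2])
  }
  d <- utils::read.csv(path, comment.char = "#")
  decay_histogram(d$time_ns, d$counts, period)
}

#' @rdname read_decay_csv
#' @param decay Decay to write.
#' @export
write_decay_csv <- function(decay, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rep_period_ns=%g", decay$rep_period_ns), con)
  utils::write.csv(data.frame(time_ns = decay$time_ns, counts = decay$counts),
                   con, row.names = FALSE)
  invisible(path)
}
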