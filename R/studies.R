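#' Lifetime-recovery study on synthetic TCSPC decays
#'
#' Repeatedly generates the reference biexponential decay (0.6 of 0.5 ns +
#' 0.4 of 2.0 ns, Gaussian IRF of 0.2 ns FWHM, 12.5 ns window, 1e4 peak
#' counts), fits it by iterative reconvolution, and bootstraps confidence
#' intervals, recording per-run recovery errors and interval coverage.
#'
#' @param n_seeds Number of independent synthetic decays.
#' @param n_boot Bootstrap replicates per decay (0 skips the bootstrap).
#' @param base_seed Seed offset for the run.
#' @param components True components of the generated decays.
#' @param ... Forwarded to [simulate_decay()].
#' @return List: `runs` (per-seed table), `summary` (median relative errors
#'   in percent and bootstrap coverage in percent).
#' @export
tcspc_recovery_study <- function(n_seeds = 50, n_boot = 100, base_seed = 1,
                                 components = data.frame(
                                   amplitude = c(0.6, 0.4),
                                   lifetime_ns = c(0.5, 2.0)), ...) {
  truth <- components[order(components$lifetime_ns), ]
  tau_av_true <- amplitude_weighted_lifetime(truth)
  runs <- lapply(seq_len(n_seeds), function(i) {
    g <- simulate_decay(components = components, seed = base_seed + i, ...)
    if (n_boot >= 2) {
      bs <- bootstrap_lifetimes(g$decay, g$irf, n_components = nrow(truth),
                                n_boot = n_boot,
                                seed = base_seed + 100000 + i)
      fit <- bs$fit
      covered <- vapply(seq_len(nrow(truth)), function(k) {
        col <- paste0("tau", k)
        truth$lifetime_ns[k] >= bs$intervals["2.5%", col] &&
          truth$lifetime_ns[k] <= bs$intervals["97.5%", col]
      }, logical(1))
      cov_tau_av <- tau_av_true >= bs$intervals["2.5%", "tau_av"] &&
        tau_av_true <= bs$intervals["97.5%", "tau_av"]
    } else {
      fit <- fit_reconvolution(g$decay, g$irf, n_components = nrow(truth))
      covered <- rep(NA, nrow(truth))
      cov_tau_av <- NA
    }
    if (nrow(fit$components) != nrow(truth)) return(NULL)
    data.frame(seed = base_seed + i,
               t(setNames(fit$components$lifetime_ns,
                          paste0("tau", seq_len(nrow(truth))))),
               tau_av = fit$tau_av_ns,
               t(setNames(as.numeric(covered),
                          paste0("covered_tau", seq_len(nrow(truth))))),
               covered_tau_av = as.numeric(cov_tau_av),
               chi2_reduced = fit$chi2_reduced)
  })
  runs <- do.call(rbind, runs[!vapply(runs, is.null, TRUE)])
  k <- nrow(truth)
  err_pct <- vapply(seq_len(k), function(j) {
    100 * stats::median(abs(runs[[paste0("tau", j)]] - truth$lifetime_ns[j]) /
                          truth$lifetime_ns[j])
  }, numeric(1))
  summary <- list(
    tau_true_ns = truth$lifetime_ns,
    tau_av_true_ns = tau_av_true,
    tau_median_error_pct = err_pct,
    tau_av_median_error_pct =
      100 * stats::median(abs(runs$tau_av - tau_av_true) / tau_av_true),
    coverage_pct = if (n_boot >= 2) {
      100 * mean(colMeans(runs[paste0("covered_tau", seq_len(k))]))
    } else NA_real_,
    n_runs = nrow(runs))
  list(runs = runs, summary = summary)
}

#' Diameter-recovery study on synthetic DLS correlograms
#'
#' Generates noisy correlograms across the vesicle size range, inverts each
#' with [fit_correlogram()], and summarizes the median absolute diameter
#' error per size.
#'
#' @param d_H_nm True hydrodynamic diameters (nm).
#' @param n_seeds Correlograms per diameter.
#' @param noise_sd Additive noise amplitude (A = 1 scale).
#' @param base_seed Seed offset.
#' @return List: `runs`, `summary` (per-size median error, percent).
#' @export
dls_recovery_study <- function(d_H_nm = c(100, 227, 400, 1000), n_seeds = 20,
                               noise_sd = 0.01, base_seed = 1) {
  runs <- do.call(rbind, lapply(d_H_nm, function(d_true) {
    fits <- vapply(seq_len(n_seeds), function(i) {
      g <- simulate_correlogram(d_true, noise_sd = noise_sd,
                                seed = base_seed + 1000 * match(d_true, d_H_nm) + i)
      fit_correlogram(g$correlogram)$d_H_nm
    }, numeric(1))
    data.frame(d_true_nm = d_true, seed = seq_len(n_seeds), d_fit_nm = fits)
  }))
  summary <- stats::aggregate(
    cbind(median_error_pct = 100 * abs(runs$d_fit_nm - runs$d_true_nm) /
            runs$d_true_nm),
    by = list(d_true_nm = runs$d_true_nm), FUN = stats::median)
  list(runs = runs, summary = summary)
}

#' Before/after/wash single-vesicle imaging study
#'
#' Simulates one vesicle field imaged through a crowder perturbation:
#' three 500-frame dual-view movies over the same vesicle layout at the
#' given true efficiencies (the experimental situation: one flow cell,
#' three conditions), analyzed end to end and compared for reversibility.
#'
#' @param efret_conditions Named or unnamed length-3 vector of true E for
#'   before / after / wash.
#' @param field_um Field of view (um); the default 36 x 36 um holds ~200
#'   vesicles at the tethering density.
#' @param n_frames Frames per movie.
#' @param base_seed Seed offset.
#' @param shift_threshold Peak-shift threshold for the verdict.
#' @param ... Forwarded to [simulate_movie()].
#' @return List: `peaks` (fitted histogram peaks), `efret_true`,
#'   `peak_errors`, `total_intensity`, `comparison`, `n_vesicles`.
#' @export
imaging_reversibility_study <- function(efret_conditions = c(before = 0.40,
                                                             after = 0.60,
                                                             wash = 0.40),
                                        field_um = c(36, 36), n_frames = 500,
                                        base_seed = 1, shift_threshold = 0.03,
                                        ...) {
  stopifnot(length(efret_conditions) == 3L)
  if (is.null(names(efret_conditions))) {
    names(efret_conditions) <- c("before", "after", "wash")
  }
  field <- simulate_vesicle_field(field_um = field_um, seed = base_seed)
  analyses <- list()
  for (i in seq_along(efret_conditions)) {
    sim <- simulate_movie(field, efret = efret_conditions[[i]],
                          n_frames = n_frames, seed = base_seed + i, ...)
    analyses[[names(efret_conditions)[i]]] <- analyze_movie(sim$movie)
    rm(sim); gc(FALSE)
  }
  peaks <- vapply(analyses, function(a) a$histogram$fit$mean, numeric(1))
  totals <- vapply(analyses, `[[`, 0, "mean_total_intensity")
  cmp <- compare_conditions(analyses$before$histogram,
                            analyses$after$histogram,
                            analyses$wash$histogram,
                            shift_threshold = shift_threshold,
                            total_intensity = unname(totals))
  list(peaks = peaks, efret_true = efret_conditions,
       peak_errors = peaks - efret_conditions,
       total_intensity = totals,
       total_intensity_max_rel_diff = diff(range(totals)) / mean(totals),
       comparison = cmp,
       n_vesicles = vapply(analyses, function(a) a$histogram$n_vesicles,
                           numeric(1)))
}
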