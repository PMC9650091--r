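#' Dual-view TIRF movie container
#'
#' A stack of dual-view camera frames in which donor and acceptor emission
#' are imaged side by side (donor on the low-index half by default).
#' Pixel values are nonnegative camera counts.
#'
#' @param frames 3D numeric array indexed (frame, row, col), or a list of
#'   matrices (one per frame).
#' @param exposure_s Exposure time per frame (s); 0.05 by default.
#' @param pixel_size_um Pixel size in sample space (um); 0.11 for a 100x
#'   objective on an 11 um camera pixel.
#' @param dualview_axis `"col"` (split left/right) or `"row"` (top/bottom).
#' @return An object of class `vesicle_movie`.
#' @export
vesicle_movie <- function(frames, exposure_s = 0.05, pixel_size_um = 0.11,
                          dualview_axis = c("col", "row")) {
  dualview_axis <- match.arg(dualview_axis)
  if (is.list(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  if (length(dim(frames)) != 3L || dim(frames)[1] < 1L) {
    stop("'frames' must be a (frame, row, col) array with >= 1 frame")
  }
  split_dim <- if (dualview_axis == "col") 3L else 2L
  if (dim(frames)[split_dim] %% 2L != 0L) {
    stop("movie does not split evenly along the dual-view axis")
  }
  structure(list(frames = frames, exposure_s = exposure_s,
                 pixel_size_um = pixel_size_um, dualview_axis = dualview_axis),
            class = "vesicle_movie")
}

#' @export
print.vesicle_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dual-view movie: %d frames of %d x %d px (%.0f ms exposure, %.2f um/px, split by %s)\n",
              d[1], d[2], d[3], 1000 * x$exposure_s, x$pixel_size_um,
              x$dualview_axis))
  invisible(x)
}

# time-averaged image of a (frame, row, col) stack
stack_mean <- function(stack) colMeans(stack, dims = 1)

# bilinear sample of img at fractional (row, col) offsets: out[r, c] =
# img[r + dy, c + dx], clamped at the edges
shift_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr) + dy
  c <- seq_len(nc) + dx
  r0 <- pmin(pmax(floor(r), 1L), nr); r1 <- pmin(r0 + 1L, nr)
  c0 <- pmin(pmax(floor(c), 1L), nc); c1 <- pmin(c0 + 1L, nc)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c - c0, 0), 1)
  w_fr <- matrix(fr, nr, nc); w_fc <- matrix(fc, nr, nc, byrow = TRUE)
  img[r0, c0] * (1 - w_fr) * (1 - w_fc) +
    img[r1, c0] * w_fr * (1 - w_fc) +
    img[r0, c1] * (1 - w_fr) * w_fc +
    img[r1, c1] * w_fr * w_fc
}

# translation between two images by FFT cross-correlation with parabolic
# sub-pixel refinement; returns c(dx, dy) such that b[r + dy, c + dx] ~ a[r, c]
estimate_translation <- function(a, b, min_correlation = 0.2) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE)) /
    length(a0)
  norm <- sqrt(sum(a0^2) * sum(b0^2))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  peak_cor <- max(cc) / norm
  nr <- nrow(a); nc <- ncol(a)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  sub <- function(m, i, n) {       # parabolic vertex from circular neighbors
    cm <- m[c((i - 2) %% n + 1, i, i %% n + 1)]
    den <- cm[1] - 2 * cm[2] + cm[3]
    if (abs(den) < .Machine$double.eps) 0 else
      min(max(0.5 * (cm[1] - cm[3]) / den, -0.5), 0.5)
  }
  dy <- wrap(peak[1], nr) + sub(cc[, peak[2]], peak[1], nr)
  dx <- wrap(peak[2], nc) + sub(cc[peak[1], ], peak[2], nc)
  list(dx = dx, dy = dy, peak_correlation = peak_cor,
       ok = is.finite(peak_cor) && peak_cor >= min_correlation)
}

#' Split a dual-view movie and register the acceptor channel
#'
#' Splits the stack into donor and acceptor halves along the dual-view
#' axis, estimates the translation between the two channels by maximizing
#' the cross-correlation of the time-averaged images (sub-pixel, by
#' parabolic interpolation of the correlation peak), and resamples every
#' acceptor frame onto the donor pixel grid by bilinear interpolation.
#'
#' @param movie A [vesicle_movie()].
#' @param min_correlation Normalized correlation-peak height below which
#'   registration is considered to have failed.
#' @return List: `donor`, `acceptor` (registered stack), `transform`
#'   (`dx`, `dy` in px: the displacement of acceptor features relative to
#'   donor features), `peak_correlation`.
#' @export
split_and_register <- function(movie, min_correlation = 0.2) {
  stopifnot(inherits(movie, "vesicle_movie"))
  f <- movie$frames
  if (movie$dualview_axis == "col") {
    h <- dim(f)[3] %/% 2L
    donor <- f[, , 1:h, drop = FALSE]
    acceptor <- f[, , (h + 1):(2 * h), drop = FALSE]
  } else {
    h <- dim(f)[2] %/% 2L
    donor <- f[, 1:h, , drop = FALSE]
    acceptor <- f[, (h + 1):(2 * h), , drop = FALSE]
  }
  est <- estimate_translation(stack_mean(donor), stack_mean(acceptor))
  if (!est$ok) {
    cond <- structure(
      class = c("luvfret_registration_error", "error", "condition"),
      list(message = sprintf(
             "channel registration failed (peak correlation %.3f); identity transform retained",
             est$peak_correlation),
           call = sys.call(-1), transform = c(dx = 0, dy = 0)))
    stop(cond)
  }
  reg <- acceptor
  if (abs(est$dx) > 1e-12 || abs(est$dy) > 1e-12) {
    for (i in seq_len(dim(acceptor)[1])) {
      reg[i, , ] <- shift_image(acceptor[i, , ], est$dx, est$dy)
    }
  }
  list(donor = donor, acceptor = reg,
       transform = c(dx = est$dx, dy = est$dy),
       peak_correlation = est$peak_correlation)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {          # convolve columns of m with k
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Detect diffraction-limited spots in an image stack
#'
#' Band-pass filters the time-averaged image with a difference of Gaussians
#' matched to the PSF, keeps local maxima above `median + k * MAD` of the
#' filtered image, enforces a minimum pairwise separation (brightest spot
#' wins), and refines each detection to a sub-pixel centroid.
#'
#' Coordinates are 0-based with the origin at the center of the first
#' pixel: `x` along columns, `y` along rows.
#'
#' @param stack (frame, row, col) array, or a single image matrix.
#' @param k Detection threshold in robust sigmas above the median.
#' @param min_separation_px Minimum allowed distance between detections.
#' @param psf_sigma_px PSF standard deviation (px) for the band-pass.
#' @return Data.frame `spot_table`: `id`, `x`, `y`, `quality` (filtered
#'   peak height over threshold). Possibly empty.
#' @export
detect_spots <- function(stack, k = 5, min_separation_px = 4,
                         psf_sigma_px = 1.2) {
  img <- if (length(dim(stack)) == 3L) stack_mean(stack) else stack
  bp <- gaussian_blur(img, psf_sigma_px) - gaussian_blur(img, 2 * psf_sigma_px)
  thr <- stats::median(bp) + k * stats::mad(bp)
  nr <- nrow(bp); nc <- ncol(bp)

  # strict local maxima over 8 neighbors, excluding the 1-px border
  is_max <- matrix(FALSE, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- bp[ri, ci]
  is_max[ri, ci] <- ctr > thr &
    ctr >= bp[ri - 1, ci] & ctr >= bp[ri + 1, ci] &
    ctr >= bp[ri, ci - 1] & ctr >= bp[ri, ci + 1] &
    ctr >= bp[ri - 1, ci - 1] & ctr >= bp[ri - 1, ci + 1] &
    ctr >= bp[ri + 1, ci - 1] & ctr >= bp[ri + 1, ci + 1]
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(structure(data.frame(id = integer(), x = numeric(), y = numeric(),
                                quality = numeric()), class = c("spot_table", "data.frame")))
  }
  val <- bp[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; val <- val[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j][d2 < min_separation_px^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; val <- val[keep]

  # sub-pixel centroid on the thresholded band-pass image, 5x5 window
  centroid <- function(r0, c0) {
    rr <- max(1, r0 - 2):min(nr, r0 + 2)
    cc <- max(1, c0 - 2):min(nc, c0 + 2)
    w <- pmax(bp[rr, cc, drop = FALSE] - stats::median(bp), 0)
    if (sum(w) <= 0) return(c(r0, c0))
    c(sum(rr * rowSums(w)) / sum(w), sum(cc * colSums(w)) / sum(w))
  }
  cents <- t(mapply(centroid, cand[, 1], cand[, 2]))
  out <- data.frame(id = seq_len(nrow(cand)),
                    x = cents[, 2] - 1, y = cents[, 1] - 1,
                    quality = val / thr)
  class(out) <- c("spot_table", "data.frame")
  out
}

# integer pixel offsets of a filled disc / annulus around the origin
disc_offsets <- function(r_out, r_in = -1) {
  r <- ceiling(r_out)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(g$dr^2 + g$dc^2)
  g[d <= r_out & d > r_in, , drop = FALSE]
}

#' Extract background-corrected intensity traces
#'
#' For every spot and frame, integrates the counts inside a circular
#' aperture centered on the spot and subtracts the local background
#' (median of an annulus around the aperture, scaled by the aperture area)
#' per channel. Spots whose annulus would leave the image are dropped and
#' reported.
#'
#' @param donor,acceptor Registered (frame, row, col) stacks on a common grid.
#' @param spots A `spot_table` from [detect_spots()] (donor-grid, 0-based).
#' @param aperture_radius_px Aperture radius (px).
#' @param annulus_px Background annulus `c(inner, outer)` radii (px).
#' @param transform Registration transform to record alongside the traces.
#' @return A `trace_set`: matrices `donor`, `acceptor` (spots x frames),
#'   the retained `spots`, `dropped` ids, `transform`.
#' @export
extract_traces <- function(donor, acceptor, spots,
                           aperture_radius_px = 3, annulus_px = c(5, 7),
                           transform = c(dx = 0, dy = 0)) {
  stopifnot(length(dim(donor)) == 3L, all(dim(donor) == dim(acceptor)))
  nr <- dim(donor)[2]; nc <- dim(donor)[3]
  n_frames <- dim(donor)[1]
  ap <- disc_offsets(aperture_radius_px)
  an <- disc_offsets(annulus_px[2], annulus_px[1])
  n_ap <- nrow(ap)
  margin <- ceiling(annulus_px[2])

  rows_center <- round(spots$y) + 1L
  cols_center <- round(spots$x) + 1L
  in_bounds <- rows_center - margin >= 1L & rows_center + margin <= nr &
    cols_center - margin >= 1L & cols_center + margin <= nc
  if (any(!in_bounds)) {
    warning(sum(!in_bounds), " spot(s) too close to the edge were dropped")
  }
  kept <- spots[in_bounds, , drop = FALSE]
  rows_center <- rows_center[in_bounds]; cols_center <- cols_center[in_bounds]

  # reshape once so pixels are rows and frames are columns, then index
  # aperture/annulus pixels linearly
  one_channel <- function(stack) {
    m <- matrix(aperm(stack, c(2, 3, 1)), nr * nc, n_frames)
    out <- matrix(NA_real_, nrow(kept), n_frames)
    for (s in seq_len(nrow(kept))) {
      lin_ap <- (cols_center[s] + ap$dc - 1L) * nr + (rows_center[s] + ap$dr)
      lin_an <- (cols_center[s] + an$dc - 1L) * nr + (rows_center[s] + an$dr)
      bg <- apply(m[lin_an, , drop = FALSE], 2, stats::median)
      out[s, ] <- colSums(m[lin_ap, , drop = FALSE]) - bg * n_ap
    }
    out
  }
  structure(list(donor = one_channel(donor), acceptor = one_channel(acceptor),
                 spots = kept, dropped = spots$id[!in_bounds],
                 transform = transform),
            class = "trace_set")
}

#' Per-vesicle apparent FRET efficiency from traces
#'
#' Averages each vesicle's donor and acceptor trace over a frame range and
#' forms \eqn{E = \bar I_A / (\bar I_A + \bar I_D)}. Vesicles whose mean
#' total intensity is nonpositive are flagged and carry `NA` efficiency.
#'
#' @param traces A `trace_set` from [extract_traces()].
#' @param frame_range `c(first, last)` frames to average; `NULL` = all.
#' @return Data.frame: `id`, `efret`, `total_intensity` (mean I_D + I_A),
#'   `flagged`.
#' @export
trace_efret <- function(traces, frame_range = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  n_frames <- ncol(traces$donor)
  if (is.null(frame_range)) frame_range <- c(1L, n_frames)
  if (frame_range[1] < 1L || frame_range[2] > n_frames ||
      frame_range[1] > frame_range[2]) {
    stop("invalid frame range")
  }
  idx <- frame_range[1]:frame_range[2]
  d_mean <- rowMeans(traces$donor[, idx, drop = FALSE])
  a_mean <- rowMeans(traces$acceptor[, idx, drop = FALSE])
  tot <- d_mean + a_mean
  flagged <- !(tot > 0)
  e <- ifelse(flagged, NA_real_, a_mean / tot)
  data.frame(id = traces$spots$id, efret = e, total_intensity = tot,
             flagged = flagged)
}

#' Per-vesicle FRET efficiency histogram with Gaussian peak fit
#'
#' Bins efficiencies on a fixed 0.01-wide grid over \[0, 1\], fits a single
#' Gaussian to the bin counts by least squares, and converts the fitted
#' mean to a mean dye separation via the Forster relation. The fit is
#' reported only when its relative error (RMS residual over peak count)
#' stays below `max_rel_error`; with fewer than 10 efficiencies the
#' histogram is returned without a fit.
#'
#' @param efficiencies Per-vesicle efficiencies; values outside \[0, 1\] or
#'   non-finite are excluded (and counted in `n_excluded`).
#' @param params A [fret_params()].
#' @param bin_width Histogram bin width (0.01 as standard).
#' @param max_rel_error Fit-rejection threshold.
#' @return An `efret_histogram`: `mids`, `counts`, `n_vesicles`,
#'   `n_excluded`, `fit` (mean, sd, amplitude, rel_error) or `NULL`,
#'   `mean_separation_nm` or `NA`.
#' @export
build_histogram <- function(efficiencies, params = fret_params(),
                            bin_width = 0.01, max_rel_error = 0.5) {
  e <- efficiencies[is.finite(efficiencies)]
  n_excluded <- length(efficiencies) - length(e)
  out_of_range <- e < 0 | e > 1
  n_excluded <- n_excluded + sum(out_of_range)
  e <- e[!out_of_range]
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(e, breaks = breaks, include.lowest = TRUE, plot = FALSE)

  obj <- list(mids = h$mids, counts = h$counts, breaks = breaks,
              n_vesicles = length(e), n_excluded = n_excluded,
              fit = NULL, mean_separation_nm = NA_real_)
  if (length(e) >= 10L) {
    i_max <- which.max(h$counts)
    fit <- minpack.lm::nls.lm(
      par = c(mu = h$mids[i_max], sigma = 0.05, amp = max(h$counts)),
      lower = c(0, bin_width / 10, 0), upper = c(1, 1, Inf),
      fn = function(p) p[3] * exp(-(h$mids - p[1])^2 / (2 * p[2]^2)) - h$counts,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    p <- unname(fit$par)
    resid <- p[3] * exp(-(h$mids - p[1])^2 / (2 * p[2]^2)) - h$counts
    rel_err <- sqrt(mean(resid^2)) / max(h$counts)
    if (rel_err <= max_rel_error) {
      obj$fit <- list(mean = p[1], sd = p[2], amplitude = p[3],
                      rel_error = rel_err)
      if (p[1] > 0 && p[1] < 1) {
        obj$mean_separation_nm <- efficiency_to_distance(p[1], params)
      }
    }
  }
  structure(obj, class = "efret_histogram")
}

#' @export
print.efret_histogram <- function(x, ...) {
  cat(sprintf("E_FRET histogram: %d vesicles in %.2g-wide bins", x$n_vesicles,
              diff(x$mids[1:2])))
  if (!is.null(x$fit)) {
    cat(sprintf("; Gaussian peak %.3f (sd %.3f), <d> = %.2f nm",
                x$fit$mean, x$fit$sd, x$mean_separation_nm))
  }
  cat("\n")
  invisible(x)
}

#' Compare FRET histograms across before / after / wash conditions
#'
#' Classifies a crowder perturbation from the Gaussian peak positions of
#' three efficiency histograms: the peak must move on crowder addition for
#' any effect at all; if it stays displaced after washing the change is
#' irreversible, if it returns it is reversible. Also checks the mean total
#' fluorescence intensity per vesicle across conditions (a shift with
#' conserved total intensity indicates compaction rather than dye loss or
#' vesicle rupture).
#'
#' @param hist_before,hist_after,hist_wash `efret_histogram`s with fits.
#' @param shift_threshold Minimum |peak shift| that counts as an effect.
#' @param total_intensity Optional numeric `c(before, after, wash)` mean
#'   total intensity per vesicle.
#' @param intensity_tolerance Relative change over which intensity is
#'   flagged (0.2 = 20%).
#' @return List: `verdict` ("irreversible" / "reversible" / "no effect"),
#'   `delta_after`, `delta_wash`, `peaks`, `total_intensity`,
#'   `intensity_flag`.
#' @export
compare_conditions <- function(hist_before, hist_after, hist_wash,
                               shift_threshold = 0.03,
                               total_intensity = NULL,
                               intensity_tolerance = 0.2) {
  hs <- list(before = hist_before, after = hist_after, wash = hist_wash)
  for (nm in names(hs)) {
    if (!inherits(hs[[nm]], "efret_histogram") || is.null(hs[[nm]]$fit)) {
      stop("'", nm, "' histogram lacks a Gaussian fit; cannot compare")
    }
  }
  peaks <- vapply(hs, function(h) h$fit$mean, numeric(1))
  delta_after <- unname(peaks["after"] - peaks["before"])
  delta_wash <- unname(peaks["wash"] - peaks["before"])
  moved_after <- abs(delta_after) > shift_threshold
  moved_wash <- abs(delta_wash) > shift_threshold
  verdict <- if (moved_after && moved_wash) "irreversible"
             else if (moved_after) "reversible"
             else "no effect"
  intensity_flag <- NA
  if (!is.null(total_intensity)) {
    stopifnot(length(total_intensity) == 3L)
    rel <- abs(total_intensity - total_intensity[1]) / total_intensity[1]
    intensity_flag <- any(rel[-1] > intensity_tolerance)
  }
  list(verdict = verdict, delta_after = delta_after, delta_wash = delta_wash,
       peaks = peaks, total_intensity = total_intensity,
       intensity_flag = intensity_flag)
}

#' Full movie-to-histogram analysis
#'
#' Convenience wrapper running the whole single-movie pipeline:
#' split + register, detect spots on the summed registered channels (so
#' vesicles shifted toward either channel by FRET are found), extract
#' background-corrected traces, compute per-vesicle efficiencies, and bin
#' them into a fitted histogram.
#'
#' @param movie A [vesicle_movie()].
#' @param params A [fret_params()].
#' @param detect,extract,histogram Named lists of overrides for
#'   [detect_spots()], [extract_traces()], [build_histogram()].
#' @param frame_range Passed to [trace_efret()].
#' @return List: `registration`, `spots`, `traces`, `efret` (per-vesicle
#'   table), `histogram`, `mean_total_intensity`.
#' @export
analyze_movie <- function(movie, params = fret_params(),
                          detect = list(), extract = list(),
                          histogram = list(), frame_range = NULL) {
  reg <- split_and_register(movie)
  spots <- do.call(detect_spots,
                   c(list(stack = reg$donor + reg$acceptor), detect))
  traces <- do.call(extract_traces,
                    c(list(donor = reg$donor, acceptor = reg$acceptor,
                           spots = spots, transform = reg$transform), extract))
  efret <- trace_efret(traces, frame_range)
  ok <- !efret$flagged
  hist <- do.call(build_histogram,
                  c(list(efficiencies = efret$efret[ok], params = params),
                    histogram))
  list(registration = reg$transform, spots = traces$spots, traces = traces,
       efret = efret, histogram = hist,
       mean_total_intensity = mean(efret$total_intensity[ok]))
}

#' Read / write dual-view movies as multi-frame TIFF
#'
#' Movies are stored as 16-bit multi-page TIFF (counts up to 65535);
#' exposure and pixel size travel in a JSON sidecar written next to the
#' TIFF (`<path>.meta.json`).
#'
#' @param path TIFF path.
#' @return A [vesicle_movie()] (reader).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  vesicle_movie(pages,
                exposure_s = meta$exposure_s %||% 0.05,
                pixel_size_um = meta$pixel_size_um %||% 0.11,
                dualview_axis = meta$dualview_axis %||% "col")
}

#' @rdname read_movie_tiff
#' @param movie Movie to write.
#' @export
write_movie_tiff <- function(movie, path) {
  f <- movie$frames
  pages <- lapply(seq_len(dim(f)[1]), function(i) {
    m <- pmin(pmax(f[i, , ], 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(exposure_s = movie$exposure_s,
                            pixel_size_um = movie$pixel_size_um,
                            dualview_axis = movie$dualview_axis),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
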