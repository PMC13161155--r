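# The four sequential preprocessing steps applied to every cell spectrum,
# in fixed order: Savitzky-Golay denoising -> DWT glass-background removal
# -> iterative spline fluorescence-baseline correction -> min-max
# normalization, followed by cropping to the 600-1800 cm^-1 fingerprint
# region.

#' Preprocessing configuration
#'
#' @param sg_window Savitzky-Golay window in channels, odd (default 25).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param wavelet Wavelet used for glass-background scale separation.
#' @param dwt_levels Decomposition depth for the coarse band (default 6: on
#'   the 1761-channel fingerprint grid the approximation then carries only
#'   features broader than roughly 90 cm^-1, well above Raman linewidths).
#' @param spline_interval Initial equal knot interval in channels for
#'   baseline estimation (default 120).
#' @param spline_max_rounds Maximum iterate-and-suppress rounds (default 20).
#' @param region Fingerprint-region crop, cm^-1.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 25L, sg_order = 3L,
                              wavelet = "sym8", dwt_levels = 6L,
                              spline_interval = 120L,
                              spline_max_rounds = 20L,
                              region = c(600, 1800)) {
  if (sg_window %% 2L == 0L || sg_window <= sg_order) {
    stop("parameter error: sg_window must be odd and > sg_order",
         call. = FALSE)
  }
  if (region[1] >= region[2]) {
    stop("parameter error: region lo must be < hi", call. = FALSE)
  }
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 wavelet = wavelet, dwt_levels = as.integer(dwt_levels),
                 spline_interval = as.integer(spline_interval),
                 spline_max_rounds = as.integer(spline_max_rounds),
                 region = region), class = "preprocess_config")
}

#' Savitzky-Golay denoising
#'
#' Local polynomial least-squares smoothing; reproduces polynomials up to
#' the fit order exactly. Edges are handled by the filter's transient
#' matrices (polynomial fits within truncated windows).
#'
#' @param spectrum A [raman_spectrum()].
#' @param window Odd window length in channels, > `order`.
#' @param order Polynomial order.
#' @return Smoothed [raman_spectrum()] on the same grid.
#' @export
sg_denoise <- function(spectrum, window = 25L, order = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  n <- length(spectrum$intensities)
  if (window %% 2L == 0L || window <= order) {
    stop("parameter error: window must be odd and > order", call. = FALSE)
  }
  if (n < window) {
    stop("parameter error: spectrum shorter than window", call. = FALSE)
  }
  y <- signal::sgolayfilt(spectrum$intensities, p = order, n = window)
  raman_spectrum(spectrum$wavenumbers, y)
}

#' Select the Savitzky-Golay window by RMSE against a clean reference
#'
#' Evaluates each candidate window on `noisy`, computes the root mean square
#' error against `clean`, and returns the candidate with the smallest RMSE;
#' ties are broken toward the smallest window.
#'
#' @param noisy,clean [raman_spectrum()]s on the same grid.
#' @param candidates Vector of odd candidate windows.
#' @param order Polynomial order.
#' @return The selected window (integer).
#' @export
select_sg_window <- function(noisy, clean, candidates, order = 3L) {
  if (length(candidates) == 0L) {
    stop("parameter error: no candidate windows", call. = FALSE)
  }
  candidates <- sort(as.integer(candidates))
  rmse <- vapply(candidates, function(w) {
    sm <- sg_denoise(noisy, window = w, order = order)
    sqrt(mean((sm$intensities - clean$intensities)^2))
  }, numeric(1L))
  candidates[which.min(rmse)]
}

#' Remove the glass-substrate background by DWT scale separation
#'
#' Both the cell spectrum and the glass reference are reduced to their
#' coarse wavelet approximation bands (narrow Raman peaks live in the
#' detail bands and would bias a full-spectrum fit). The cell's coarse band
#' is then regressed onto the reference's coarse band with a single
#' non-negative glass coefficient; a low-order polynomial (quadratic in the
#' grid position) is included in the regression to absorb the cell's own
#' broad coarse content — the fluorescence pedestal and the smooth envelope
#' of dense overlapping bands — which would otherwise inflate the glass
#' scale. Finally `scale * glass_ref` is subtracted from the full spectrum.
#'
#' @param spectrum A [raman_spectrum()].
#' @param glass_ref Glass reference spectrum, aligned to the same grid.
#' @param wavelet,dwt_levels See [preprocess_config()].
#' @return List with `spectrum` (corrected) and `scale` (fitted, >= 0).
#' @export
remove_glass_background <- function(spectrum, glass_ref, wavelet = "sym8",
                                    dwt_levels = 6L) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(glass_ref, "raman_spectrum"))
  if (!isTRUE(all.equal(spectrum$wavenumbers, glass_ref$wavenumbers))) {
    stop("alignment error: glass reference not on the spectrum's grid",
         call. = FALSE)
  }
  a_cell <- dwt_approximation(spectrum$intensities, dwt_levels, wavelet)
  a_glass <- dwt_approximation(glass_ref$intensities, dwt_levels, wavelet)
  n <- length(a_cell)
  t <- seq(0, 1, length.out = n)
  detrend <- cbind(1, t, t^2)
  design <- cbind(a_glass, detrend)
  fit <- stats::lm.fit(design, a_cell)
  scale <- unname(fit$coefficients[1L])
  if (!is.finite(scale) || scale < 0) scale <- 0
  corrected <- spectrum$intensities - scale * glass_ref$intensities
  list(spectrum = raman_spectrum(spectrum$wavenumbers, corrected),
       scale = scale)
}

# zero-order Savitzky-Golay smoothing = moving average with truncated
# windows at the edges; O(n) via cumulative sums
moving_average <- function(x, win) {
  n <- length(x)
  half <- (win - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fluorescence-baseline correction by iterative equal-interval splines
#'
#' The spectrum is first smoothed once with a zero-order Savitzky-Golay
#' (moving-average) filter whose window is half the knot interval — wide
#' enough to suppress channel noise at the knot scale while keeping the
#' curvature bias of the averaging small. Then, iteratively: within each
#' equal interval the local minimum of the working curve becomes a knot; a
#' cubic spline through the knots forms the candidate baseline; working
#' points above the baseline are suppressed (clamped down to it) for the
#' next round, so peak bumps are progressively excluded while true
#' baseline regions are retained. The loop stops when the baseline's
#' relative change falls below 0.1% or `max_rounds` is reached. The
#' corrected spectrum is clipped at zero so that no negative intensities
#' enter the non-negativity-constrained decomposition downstream.
#'
#' @param spectrum A [raman_spectrum()].
#' @param interval_init Equal knot interval in channels (>= 4).
#' @param max_rounds Maximum rounds.
#' @return List with `spectrum` (corrected, >= 0), `baseline` (a
#'   [raman_spectrum()]), `rounds` and `converged`.
#' @export
correct_baseline_spline <- function(spectrum, interval_init = 120L,
                                    max_rounds = 20L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  y <- spectrum$intensities
  wn <- spectrum$wavenumbers
  n <- length(y)
  interval <- as.integer(interval_init)
  if (interval < 4L) {
    stop("parameter error: interval_init must be >= 4 channels", call. = FALSE)
  }
  if (interval > n) {
    stop("parameter error: interval wider than spectrum", call. = FALSE)
  }
  win <- max(5L, interval %/% 2L)
  if (win %% 2L == 0L) win <- win - 1L
  segments <- split(seq_len(n), ceiling(seq_len(n) / interval))
  work <- moving_average(y, win)
  baseline_prev <- NULL
  converged <- FALSE
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    knots <- vapply(segments, function(ix) ix[which.min(work[ix])],
                    integer(1L))
    knots <- sort(unique(c(1L, knots, n)))
    baseline <- stats::spline(wn[knots], work[knots], xout = wn,
                              method = "fmm")$y
    if (!is.null(baseline_prev)) {
      ref <- max(abs(baseline_prev))
      delta <- if (ref > 0) max(abs(baseline - baseline_prev)) / ref else 0
      if (delta < 1e-3) {
        converged <- TRUE
        baseline_prev <- baseline
        break
      }
    }
    baseline_prev <- baseline
    work <- pmin(work, baseline)
  }
  corrected <- pmax(y - baseline_prev, 0)
  list(spectrum = raman_spectrum(wn, corrected),
       baseline = raman_spectrum(wn, baseline_prev),
       rounds = rounds, converged = converged)
}

#' Min-max normalization to the unit interval
#'
#' @param spectrum A [raman_spectrum()].
#' @return A [raman_spectrum()] with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  y <- spectrum$intensities
  rng <- range(y)
  if (rng[2] <= rng[1]) {
    stop("degenerate-range error: constant spectrum cannot be min-max normalized",
         call. = FALSE)
  }
  raman_spectrum(spectrum$wavenumbers, (y - rng[1]) / (rng[2] - rng[1]))
}

#' Crop a spectra_set to a wavenumber region
#'
#' Retains channels with `lo <= wavenumber <= hi` (closed interval).
#'
#' @param dataset A [spectra_set()].
#' @param lo,hi Region endpoints in cm^-1.
#' @return A cropped [spectra_set()].
#' @export
crop_region <- function(dataset, lo = 600, hi = 1800) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (lo >= hi) stop("range error: lo must be < hi", call. = FALSE)
  keep <- dataset$wavenumbers >= lo & dataset$wavenumbers <= hi
  if (!any(keep)) {
    stop(sprintf("range error: [%g, %g] does not overlap the grid", lo, hi),
         call. = FALSE)
  }
  spectra_set(dataset$wavenumbers[keep], dataset$matrix[, keep, drop = FALSE],
              dataset$meta)
}

#' The full preprocessing pipeline
#'
#' Applies, per spectrum and in fixed order: [sg_denoise()] ->
#' [remove_glass_background()] -> [correct_baseline_spline()] ->
#' [minmax_normalize()], then crops the set to the fingerprint region.
#'
#' @param dataset A [spectra_set()].
#' @param glass_ref Glass reference [raman_spectrum()] on the dataset grid.
#' @param config A [preprocess_config()].
#' @return List with `dataset` (processed [spectra_set()]) and `report`
#'   (data frame: per-sample glass scale, baseline rounds, convergence
#'   flag).
#' @export
preprocess_pipeline <- function(dataset, glass_ref,
                                config = preprocess_config()) {
  stopifnot(inherits(dataset, "spectra_set"),
            inherits(config, "preprocess_config"))
  n <- n_spectra(dataset)
  out <- dataset$matrix
  scales <- numeric(n)
  rounds <- integer(n)
  conv <- logical(n)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  for (i in seq_len(n)) {
    s <- get_spectrum(dataset, i)
    s <- stage("sg_denoise",
               sg_denoise(s, config$sg_window, config$sg_order))
    gl <- stage("remove_glass_background",
                remove_glass_background(s, glass_ref, config$wavelet,
                                        config$dwt_levels))
    scales[i] <- gl$scale
    bl <- stage("correct_baseline_spline",
                correct_baseline_spline(gl$spectrum, config$spline_interval,
                                        config$spline_max_rounds))
    rounds[i] <- bl$rounds
    conv[i] <- bl$converged
    s <- stage("minmax_normalize", minmax_normalize(bl$spectrum))
    out[i, ] <- s$intensities
  }
  processed <- spectra_set(dataset$wavenumbers, out, dataset$meta)
  processed <- crop_region(processed, config$region[1], config$region[2])
  report <- data.frame(sample_id = dataset$meta$sample_id,
                       glass_scale = scales,
                       baseline_rounds = rounds,
                       baseline_converged = conv,
                       stringsAsFactors = FALSE)
  list(dataset = processed, report = report)
}
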