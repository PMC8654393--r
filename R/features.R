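# Conventional EEG data features: 1/f-adjusted spectra and band power,
# peak-gamma frequency, Morlet time-frequency power, mismatch difference
# waves.

#' Standard frequency bands
#'
#' Theta 3-7, alpha 8-14, beta 15-30 Hz; gamma is open-ended above 31 Hz and
#' runs to `gamma_max` (by default the grid is expected to be clipped by
#' [band_power()] to its own maximum). All bands are closed intervals.
#'
#' @param gamma_max upper gamma edge (Hz)
#' @return data.frame with columns `name`, `low`, `high`
#' @export
default_bands <- function(gamma_max = Inf) {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low = c(3, 8, 15, 31), high = c(7, 14, 30, gamma_max),
             stringsAsFactors = FALSE)
}

#' Subtract the aperiodic 1/f gradient from a power spectrum
#'
#' Fits a least-squares line to log-power over log-frequency on `fit_range`
#' (excluding the line-noise guard band) and returns the residual spectrum on
#' the original grid: `adjusted = power - exp(fit)`. The fitted slope is the
#' (negated) aperiodic exponent the resting-EEG analyses compare between
#' groups.
#'
#' @param grid frequency grid (Hz)
#' @param power power spectrum, strictly positive on the fit range
#' @param fit_range interval (Hz) used for the fit
#' @param exclude optional interval (Hz) dropped from the fit (line noise)
#' @return object of class `adjusted_spectrum`: `grid`, `power`, `fitted`,
#'   `adjusted`, `slope`, `intercept`
#' @export
adjust_onef <- function(grid, power, fit_range = c(2, 48),
                        exclude = c(48.5, 51.5)) {
  stopifnot(length(grid) == length(power))
  sel <- grid >= fit_range[[1]] & grid <= fit_range[[2]] &
    !(grid >= exclude[[1]] & grid <= exclude[[2]])
  if (!any(sel)) stop("empty fit range")
  if (any(power[sel] <= 0))
    stop("power must be strictly positive on the fit range (log undefined)")
  fit <- lm(log(power[sel]) ~ log(grid[sel]))
  b <- unname(coef(fit))
  fitted_full <- exp(b[[1]] + b[[2]] * log(grid))
  structure(list(grid = grid, power = power, fitted = fitted_full,
                 adjusted = power - fitted_full,
                 slope = b[[2]], intercept = b[[1]]),
            class = "adjusted_spectrum")
}

#' Mean adjusted power per frequency band
#'
#' @param adjusted an [adjust_onef()] result
#' @param bands band table as from [default_bands()]; an infinite upper edge
#'   is clipped to the grid maximum
#' @return named numeric of band means
#' @export
band_power <- function(adjusted, bands = default_bands()) {
  g <- adjusted$grid
  out <- numeric(nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    hi <- min(bands$high[[i]], max(g))
    sel <- g >= bands$low[[i]] & g <= hi
    if (!any(sel)) stop("band '", bands$name[[i]], "' is empty on this grid")
    out[[i]] <- mean(adjusted$adjusted[sel])
  }
  out
}

#' Frequency of maximal adjusted power in a search interval
#'
#' Ties are broken toward the lower frequency.
#'
#' @param adjusted an [adjust_onef()] result
#' @param search closed interval (Hz), default the gamma peak window 35-45
#' @return frequency (Hz) of the maximum
#' @export
peak_gamma <- function(adjusted, search = c(35, 45)) {
  sel <- adjusted$grid >= search[[1]] & adjusted$grid <= search[[2]]
  if (!any(sel)) stop("search interval outside the spectrum's grid")
  adjusted$grid[sel][which.max(adjusted$adjusted[sel])]
}

#' Morlet time-frequency power, baseline-normalized
#'
#' Complex Morlet decomposition (fixed number of cycles), magnitude squared,
#' averaged over trials, and expressed relative to the mean over the baseline
#' window per frequency row (so a stationary process has normalized power 1).
#'
#' @param x time x trials matrix (or a vector for one trial)
#' @param time_ms time axis
#' @param freqs analysis frequencies (Hz)
#' @param cycles wavelet cycles (temporal SD = cycles / (2 pi f))
#' @param baseline baseline window (ms), must precede `stim_onset_ms`
#' @param stim_onset_ms stimulus onset
#' @return object of class `tf_map`: `time_ms`, `freqs`, `power`
#'   (freqs x time, normalized), `raw` (same, unnormalized)
#' @export
time_frequency_power <- function(x, time_ms, freqs, cycles = 7,
                                 baseline = NULL, stim_onset_ms = 0) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time_ms))
  if (is.null(baseline)) baseline <- c(min(time_ms), stim_onset_ms)
  if (baseline[[2]] > stim_onset_ms)
    stop("baseline window must precede stimulus onset")
  if (baseline[[1]] < min(time_ms) || baseline[[2]] > max(time_ms))
    stop("baseline window outside the data")
  dt <- diff(time_ms[1:2]) / 1000
  n <- nrow(x)
  pw <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[[k]]
    sd_t <- cycles / (2 * pi * f)
    tw <- seq(-4 * sd_t, 4 * sd_t, by = dt)
    wav <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sd_t^2))
    wav <- wav / sum(Mod(wav))
    for (tr in seq_len(ncol(x))) {
      conv <- convolve_same(x[, tr], wav)
      pw[k, ] <- pw[k, ] + Mod(conv)^2
    }
  }
  pw <- pw / ncol(x)
  bsel <- time_ms >= baseline[[1]] & time_ms <= baseline[[2]]
  bmean <- rowMeans(pw[, bsel, drop = FALSE])
  norm <- sweep(pw, 1, bmean, "/")
  structure(list(time_ms = time_ms, freqs = freqs, power = norm, raw = pw,
                 baseline = baseline), class = "tf_map")
}

# centered complex convolution via FFT
convolve_same <- function(x, w) {
  n <- length(x); m <- length(w)
  nf <- n + m - 1L
  X <- fft(c(x, rep(0, nf - n)))
  W <- fft(c(w, rep(0, nf - m)))
  full <- fft(X * W, inverse = TRUE) / nf
  full[((m - 1L) %/% 2L) + seq_len(n)]
}

#' Mismatch difference wave, amplitude and latency
#'
#' `difference = deviant - standard`; the amplitude is the signed extremum of
#' the difference inside the window and the latency its time.
#'
#' @param standard,deviant traces on a shared time axis (vectors)
#' @param time_ms shared time axis
#' @param window latency window (ms), default 150-250 ms post-stimulus
#' @param stim_onset_ms stimulus onset (window is relative to it)
#' @return list with `difference`, `amplitude`, `latency_ms` (relative to
#'   onset)
#' @export
mismatch_wave <- function(standard, deviant, time_ms,
                          window = c(150, 250), stim_onset_ms = 0) {
  if (length(standard) != length(deviant) ||
      length(standard) != length(time_ms))
    stop("standard, deviant and time axis must share the same length")
  d <- deviant - standard
  rel <- time_ms - stim_onset_ms
  sel <- rel >= window[[1]] & rel <= window[[2]]
  if (!any(sel)) stop("window outside the time axis")
  i <- which.max(abs(d[sel]))
  list(difference = d, amplitude = d[sel][i], latency_ms = rel[sel][i])
}
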