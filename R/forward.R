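# Forward models: linearized frequency responses and cross-spectral
# densities for the induced-response paradigms (resting EEG, 40-Hz ASSR), and
# deterministic time-domain evoked responses for the mismatch-negativity
# paradigm. The fixed-step delay integrator doubles as the package's own
# oracle for the spectral predictions.

#' Frequency grids used by the paradigms
#'
#' Resting EEG: 1-48 Hz; ASSR: 30-50 Hz; both at 0.25 Hz resolution.
#' @param paradigm `"rest"` or `"assr"`
#' @export
default_grid <- function(paradigm = c("rest", "assr")) {
  switch(match.arg(paradigm),
         rest = seq(1, 48, by = 0.25),
         assr = seq(30, 50, by = 0.25))
}

#' Gaussian bump input spectrum
#'
#' Power density of the exogenous drive: a Gaussian bump (the ~40 Hz
#' subcortical drive of the ASSR paradigm) on top of a broadband floor.
#' The bump is `amplitude * exp(-(f - center)^2 / (2 width^2))`, so the value
#' one width away from the center is `exp(-1/2)` of the peak.
#'
#' @param center bump center (Hz)
#' @param width bump width (Hz), > 0
#' @param amplitude peak power density of the bump ((mV/s)^2/Hz)
#' @param grid frequency grid (Hz), strictly increasing and positive
#' @param floor broadband floor power density
#' @return object of class `input_spectrum` with fields `grid`, `density`
#'   and the generating parameters
#' @export
gaussian_bump_input <- function(center, width, amplitude, grid,
                                floor = 0.01 * amplitude) {
  if (width <= 0) stop("bump width must be > 0 (got ", width, ")")
  stopifnot(all(diff(grid) > 0), all(grid > 0))
  dens <- amplitude * exp(-(grid - center)^2 / (2 * width^2)) + floor
  structure(list(grid = grid, density = dens, center = center, width = width,
                 amplitude = amplitude, floor = floor, kind = "bump"),
            class = "input_spectrum")
}

#' Power-law (1/f-like) input spectrum for the resting paradigm
#'
#' @param amplitude density at 1 Hz
#' @param exponent power-law exponent (density ~ f^-exponent)
#' @param grid frequency grid (Hz)
#' @param floor white floor
#' @export
powerlaw_input <- function(amplitude, exponent, grid,
                           floor = 0.01 * amplitude) {
  stopifnot(all(grid > 0))
  dens <- amplitude * grid^(-exponent) + floor
  structure(list(grid = grid, density = dens, amplitude = amplitude,
                 exponent = exponent, floor = floor, kind = "powerlaw"),
            class = "input_spectrum")
}

#' Observation-noise model
#'
#' Channel and source noise, each white + power-law:
#' `g(f) = amp_white + amp_pink * f^-exponent`, added to predicted
#' cross-spectra (source noise is mapped through the lead field).
#'
#' @param channel_white,channel_pink,channel_exp channel-noise parameters
#' @param source_white,source_pink,source_exp source-noise parameters
#' @export
noise_model <- function(channel_white = 0, channel_pink = 0, channel_exp = 1,
                        source_white = 0, source_pink = 0, source_exp = 1) {
  structure(list(channel_white = channel_white, channel_pink = channel_pink,
                 channel_exp = channel_exp, source_white = source_white,
                 source_pink = source_pink, source_exp = source_exp),
            class = "noise_model")
}

noise_density <- function(noise, grid, what = c("channel", "source")) {
  what <- match.arg(what)
  a <- noise[[paste0(what, "_white")]]
  b <- noise[[paste0(what, "_pink")]]
  e <- noise[[paste0(what, "_exp")]]
  a + b * grid^(-e)
}

#' Linearized transfer function of a network
#'
#' Complex gain from the exogenous input channel to the observed channels at
#' each frequency: `C (i w I - A(w))^-1 B`, with transmission delays applied
#' as exact phase factors `exp(-i w tau)` on the intra-column and extrinsic
#' coupling blocks of the Jacobian at the fixed point.
#'
#' @param net a [cmc_network()]
#' @param grid frequency grid (Hz)
#' @param condition optional condition label
#' @param drive0 constant operating-point drive
#' @param stability_tol largest admissible real part of a Jacobian eigenvalue
#' @return complex matrix (frequencies x channels)
#' @export
transfer_function <- function(net, grid, condition = NULL, drive0 = 0,
                              stability_tol = 1e-6) {
  lin <- linearize(net, condition, drive0)
  N <- length(net$areas)
  np <- length(lin$mats$Tpop)
  uncoupled <- N > 1 && !length(net$A_fwd) && !length(net$A_bwd)
  if (!uncoupled) {
    ev <- eigen(lin$A0 + lin$Ai + lin$Ae, only.values = TRUE)$values
    worst <- ev[which.max(Re(ev))]
    if (Re(worst) > stability_tol)
      stop("unstable fixed point: Jacobian eigenvalue ",
           format(worst, digits = 4), " has nonnegative real part")
    H <- cpp_transfer(lin$A0, lin$Ai, lin$Ae, lin$taui, lin$taue, lin$B,
                      lin$C, 2 * pi * grid)
    out <- t(vapply(seq_along(grid), function(k) H[, 1, k],
                    complex(nrow(lin$C))))
    if (nrow(lin$C) == 1) out <- matrix(out, ncol = 1)
  } else {
    # areas without extrinsic coupling evolve independently: solve the
    # per-area 8-state systems instead of the full block-diagonal one
    zero8 <- matrix(0, 8, 8)
    out <- matrix(0 + 0i, length(grid), nrow(lin$C))
    for (a in seq_len(N)) {
      ix <- c((a - 1L) * 4L + 1:4, np + (a - 1L) * 4L + 1:4)
      A0a <- lin$A0[ix, ix]; Aia <- lin$Ai[ix, ix]
      ev <- eigen(A0a + Aia, only.values = TRUE)$values
      worst <- ev[which.max(Re(ev))]
      if (Re(worst) > stability_tol)
        stop("unstable fixed point: Jacobian eigenvalue ",
             format(worst, digits = 4), " has nonnegative real part")
      Ha <- cpp_transfer(A0a, Aia, zero8, lin$taui, lin$taue,
                         lin$B[ix, , drop = FALSE],
                         lin$C[, ix, drop = FALSE], 2 * pi * grid)
      hm <- matrix(vapply(seq_along(grid), function(k) Ha[, 1, k],
                          complex(nrow(lin$C))), nrow = nrow(lin$C))
      out <- out + t(hm)
    }
  }
  colnames(out) <- rownames(net$lead_field)
  out
}

#' Predict a cross-spectral density
#'
#' `S(f) = H(f) g_u(f) H(f)^H + L g_s(f) L^T + g_c(f) I`: the transfer
#' function applied to the input power density, plus source noise mapped
#' through the lead field and channel noise. The result is Hermitian and
#' positive semidefinite at every frequency.
#'
#' @param net a [cmc_network()]
#' @param input an `input_spectrum`
#' @param noise a [noise_model()]
#' @param grid frequency grid (defaults to the input's)
#' @param condition optional condition label
#' @return object of class `cross_spectrum`: list with `grid` and complex
#'   array `csd` (channels x channels x frequencies)
#' @export
predict_csd <- function(net, input, noise = noise_model(), grid = input$grid,
                        condition = NULL) {
  if (!isTRUE(all.equal(grid, input$grid)))
    input <- regrid_input(input, grid)
  H <- transfer_function(net, grid, condition)
  nch <- ncol(H)
  gs <- noise_density(noise, grid, "source")
  gc_ <- noise_density(noise, grid, "channel")
  L <- net$lead_field
  LLt <- L %*% t(L)
  S <- array(complex(real = 0), dim = c(nch, nch, length(grid)))
  for (i in seq_len(nch)) for (j in seq_len(nch))
    S[i, j, ] <- H[, i] * Conj(H[, j]) * input$density + gs * LLt[i, j] +
      (i == j) * gc_
  structure(list(grid = grid, csd = S, condition = condition,
                 channels = colnames(H)), class = "cross_spectrum")
}

regrid_input <- function(input, grid) {
  d <- approx(input$grid, input$density, xout = grid, rule = 2)$y
  out <- input; out$grid <- grid; out$density <- d
  out
}

#' Check the cross-spectrum invariants (Hermitian, PSD, real nonnegative
#' diagonal) at every frequency
#' @param cs a `cross_spectrum`
#' @param tol numerical tolerance
#' @return TRUE or a character description of the first violation
#' @export
check_cross_spectrum <- function(cs, tol = 1e-8) {
  for (k in seq_along(cs$grid)) {
    S <- cs$csd[, , k, drop = FALSE]
    dim(S) <- dim(cs$csd)[1:2]
    scale <- max(abs(S), 1e-300)
    if (max(abs(S - Conj(t(S)))) > tol * scale)
      return(sprintf("not Hermitian at %.2f Hz", cs$grid[[k]]))
    if (any(abs(Im(diag(S))) > tol * scale) || any(Re(diag(S)) < -tol * scale))
      return(sprintf("bad diagonal at %.2f Hz", cs$grid[[k]]))
    ev <- eigen((S + Conj(t(S))) / 2, only.values = TRUE)$values
    if (min(Re(ev)) < -tol * scale)
      return(sprintf("not PSD at %.2f Hz (min eig %.3g)", cs$grid[[k]],
                     min(Re(ev))))
  }
  TRUE
}

#' Integrate the network in the time domain
#'
#' Fixed-step RK4 integration of the delay differential equations; delayed
#' voltages are read from a history ring buffer with linear interpolation.
#' Deterministic given the drive. Observed channels are the lead-field-mapped,
#' J-weighted population voltages.
#'
#' @param net a [cmc_network()]
#' @param drive numeric vector of the exogenous input (mV/s) sampled at `dt`
#' @param dt_ms time step (ms); default 0.1
#' @param condition optional condition label
#' @param init initial state (defaults to the fixed point at drive 0)
#' @param decim record every `decim`-th sample
#' @return list with `time_ms`, `obs` (time x channels), and the final state
#' @export
integrate_time_domain <- function(net, drive, dt_ms = 0.1, condition = NULL,
                                  init = NULL, decim = 1L) {
  m <- build_matrices(net, condition)
  np <- length(m$Tpop)
  if (is.null(init)) init <- fixed_point(net, 0, condition)
  nsteps <- length(drive) - 1L
  r <- cpp_integrate_cmc(m$W0, m$Wi, m$We, m$taui, m$taue, m$Tpop, m$rho,
                         m$Cdrive, m$Jobs, drive, dt_ms * 1e-3,
                         as.integer(nsteps), init[1:np], init[np + 1:np],
                         as.integer(decim))
  if (!isTRUE(r$ok))
    stop("state diverged at t = ", signif(r$t_fail * 1e3, 4), " ms")
  obs <- t(r$obs)
  colnames(obs) <- rownames(net$lead_field)
  list(time_ms = seq(0, by = dt_ms * decim, length.out = nrow(obs)),
       obs = obs, state = c(r$v, r$cur))
}

#' Synthesize a stationary noise series with a prescribed one-sided PSD
#'
#' FFT-shapes unit white noise so its one-sided power spectral density
#' matches `density(f)`; used to drive the time-domain oracle.
#'
#' @param n number of samples
#' @param dt_s sample interval (s)
#' @param density function of frequency (Hz) returning PSD, or an
#'   `input_spectrum` (interpolated, clamped at its ends)
#' @export
colored_noise <- function(n, dt_s, density) {
  if (inherits(density, "input_spectrum")) {
    sp <- density
    density <- function(f) approx(sp$grid, sp$density, xout = f, rule = 2)$y
  }
  fs <- 1 / dt_s
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)
  g <- sqrt(pmax(density(pmax(f_fold, f[2])), 0) / (2 * dt_s))
  w <- rnorm(n)
  Re(fft(fft(w) * g, inverse = TRUE)) / n
}

#' Welch cross-spectral estimate
#'
#' Hann-windowed, overlapping-segment estimate of the one-sided
#' cross-spectral density matrix of a multichannel series; the independent
#' estimator used to validate [predict_csd()] against
#' [integrate_time_domain()].
#'
#' @param x time x channels matrix
#' @param fs sampling rate (Hz)
#' @param nseg segment length (samples)
#' @param overlap fractional overlap
#' @return `cross_spectrum` on the positive-frequency grid
#' @export
welch_csd <- function(x, fs, nseg = 2^12, overlap = 0.5) {
  x <- as.matrix(x)
  nch <- ncol(x); n <- nrow(x)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  U <- mean(win^2)
  nf <- nseg %/% 2
  acc <- array(complex(real = 0), dim = c(nch, nch, nf))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Fm <- mvfft(seg * win)[1 + seq_len(nf), , drop = FALSE]
    for (k in seq_len(nf))
      acc[, , k] <- acc[, , k] + Fm[k, ] %*% Conj(t(Fm[k, ]))
  }
  acc <- acc * (2 / (fs * nseg * U * length(starts)))
  structure(list(grid = (seq_len(nf)) * fs / nseg, csd = acc,
                 condition = NULL, channels = colnames(x)),
            class = "cross_spectrum")
}

#' Stimulus definition for evoked responses
#'
#' A boundary pulse smoothed with a Gaussian edge (analytically, via the
#' normal CDF): `amp * (pnorm(t, onset, rise) - pnorm(t, onset + duration,
#' rise))`.
#'
#' @param onset_ms stimulus onset
#' @param duration_ms pulse duration; may be a named vector per condition
#' @param rise_ms Gaussian edge SD
#' @param amp drive amplitude (mV/s)
#' @export
erp_stimulus <- function(onset_ms = 100, duration_ms = 70, rise_ms = 8,
                         amp = 80) {
  structure(list(onset_ms = onset_ms, duration_ms = duration_ms,
                 rise_ms = rise_ms, amp = amp), class = "erp_stimulus")
}

stimulus_drive <- function(stim, t_ms, condition = NULL) {
  dur <- stim$duration_ms
  if (!is.null(names(dur))) {
    dur <- if (!is.null(condition) && condition %in% names(dur))
      dur[[condition]] else dur[[1]]
  }
  stim$amp * (pnorm(t_ms, stim$onset_ms, stim$rise_ms) -
                pnorm(t_ms, stim$onset_ms + dur, stim$rise_ms))
}

#' 40-Hz click-train drive (the auditory steady-state stimulus)
#'
#' @param t_ms time axis (ms)
#' @param rate_hz click rate
#' @param n_clicks number of clicks
#' @param onset_ms time of the first click
#' @param width_ms Gaussian width of each click
#' @param amp peak drive per click (mV/s)
#' @export
click_train_drive <- function(t_ms, rate_hz = 40, n_clicks = 16,
                              onset_ms = 0, width_ms = 2, amp = 100) {
  centers <- onset_ms + (seq_len(n_clicks) - 1) * 1000 / rate_hz
  drv <- numeric(length(t_ms))
  for (ct in centers) drv <- drv + amp * exp(-(t_ms - ct)^2 / (2 * width_ms^2))
  drv
}

#' Simulate event-related potentials per condition
#'
#' For each condition the condition's B deltas are applied to the network,
#' the fixed point re-derived, and the stimulus response integrated; traces
#' are baseline-corrected on the pre-onset window.
#'
#' @param net a [cmc_network()]
#' @param stim an [erp_stimulus()]
#' @param conditions condition labels; each must be resolvable through
#'   `net$B` (an empty/absent entry means no modulation)
#' @param dur_ms epoch length
#' @param dt_ms integration step
#' @param decim decimation factor for the stored traces
#' @return object of class `erp_series`: `time_ms`, `traces` (named list of
#'   time x channel matrices), `stim`
#' @export
simulate_erp <- function(net, stim = erp_stimulus(),
                         conditions = c("standard", "deviant"),
                         dur_ms = 500, dt_ms = 0.1, decim = 5L) {
  for (cn in conditions)
    if (!is.null(net$B[[cn]])) {
      known <- names(network_vec(net))
      bad <- setdiff(names(net$B[[cn]]), known)
      if (length(bad)) stop("condition '", cn, "' references unknown ",
                            "parameters: ", paste(bad, collapse = ", "))
    }
  t_full <- seq(0, dur_ms, by = dt_ms)
  traces <- list()
  for (cn in conditions) {
    drv <- stimulus_drive(stim, t_full, cn)
    r <- integrate_time_domain(net, drv, dt_ms, condition = cn, decim = decim)
    obs <- r$obs
    # the Gaussian-smoothed pulse has support slightly before onset; the
    # baseline window therefore ends 3 rise-SDs earlier
    base <- r$time_ms < stim$onset_ms - 3 * stim$rise_ms
    if (!any(base)) base <- r$time_ms < stim$onset_ms
    if (any(base)) obs <- sweep(obs, 2, colMeans(obs[base, , drop = FALSE]))
    traces[[cn]] <- obs
  }
  structure(list(time_ms = seq(0, by = dt_ms * decim,
                               length.out = nrow(traces[[1]])),
                 traces = traces, stim = stim), class = "erp_series")
}
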