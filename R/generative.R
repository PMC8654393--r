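# Generative maps from named free parameters to observation vectors, one per
# paradigm. A generative closure applies the prior map (expand_theta) to get
# parameter-path deltas, splits them into network paths and forward-model
# settings ("input:*"), and runs the paradigm's forward model.

split_paths <- function(deltas) {
  isinp <- startsWith(names(deltas), "input:")
  list(net = deltas[!isinp], input = deltas[isinp])
}

# fixed parameters with nonzero prior means (e.g. an empirical operating
# point) must enter every prediction alongside the free parameters
theta_with_fixed <- function(priors, theta) {
  tb <- priors$table
  fx <- tb$var == 0 & tb$mean != 0 & !(tb$name %in% names(theta))
  if (any(fx)) theta <- c(setNames(tb$mean[fx], tb$name[fx]), theta)
  theta
}

#' Vectorize a cross-spectrum for fitting
#'
#' Concatenates, per frequency, the real diagonal and the real and imaginary
#' parts of the upper triangle.
#'
#' @param cs a `cross_spectrum`
#' @return numeric vector
#' @export
csd_to_vec <- function(cs) {
  nch <- dim(cs$csd)[[1]]
  nf <- length(cs$grid)
  A <- matrix(cs$csd, nch * nch, nf)
  diag_idx <- (seq_len(nch) - 1L) * nch + seq_len(nch)
  ut <- which(upper.tri(matrix(0, nch, nch)))
  as.vector(rbind(Re(A[diag_idx, , drop = FALSE]),
                  if (length(ut)) Re(A[ut, , drop = FALSE]),
                  if (length(ut)) Im(A[ut, , drop = FALSE])))
}

#' Configuration of the ASSR forward model
#'
#' @param grid frequency grid
#' @param center input bump center (Hz)
#' @param width base bump width (Hz); the `input:width` parameter scales it
#' @param amp base bump amplitude; the `input:amp` parameter scales it
#' @param floor_frac broadband floor as a fraction of the amplitude
#' @param noise a [noise_model()] used in the prediction
#' @export
assr_config <- function(grid = default_grid("assr"), center = 40, width = 4,
                        amp = 1e-3, floor_frac = 0.02,
                        noise = noise_model(channel_white = 2e-10)) {
  list(grid = grid, center = center, width = width, amp = amp,
       floor_frac = floor_frac, noise = noise)
}

#' Generative model for ASSR cross-spectral densities
#'
#' @param net base network (default [assr_network()])
#' @param priors a [prior_spec()] whose map routes parameters into the
#'   network and the input bump
#' @param config an [assr_config()]
#' @return function: named theta -> observation vector (see [csd_to_vec()])
#' @export
generative_csd <- function(net = assr_network(), priors, config = assr_config()) {
  function(theta) {
    d <- split_paths(expand_theta(priors, theta_with_fixed(priors, theta)))
    net2 <- apply_deltas(net, d$net, validate = FALSE)
    wsc <- if (!is.na(d$input["input:width"])) exp(d$input[["input:width"]]) else 1
    asc <- if (!is.na(d$input["input:amp"])) exp(d$input[["input:amp"]]) else 1
    inp <- gaussian_bump_input(config$center, config$width * wsc,
                               config$amp * asc, config$grid,
                               floor = config$floor_frac * config$amp * asc)
    csd_to_vec(predict_csd(net2, inp, config$noise, config$grid))
  }
}

#' Configuration of the resting-spectrum forward model
#' @param grid frequency grid
#' @param amp,exponent,floor_frac power-law input parameters
#' @param noise a [noise_model()]
#' @export
rest_config <- function(grid = default_grid("rest"), amp = 1, exponent = 1,
                        floor_frac = 0.01,
                        noise = noise_model(channel_white = 1e-9)) {
  list(grid = grid, amp = amp, exponent = exponent, floor_frac = floor_frac,
       noise = noise)
}

#' Generative model for resting power spectra (diagonal auto-spectra)
#' @inheritParams generative_csd
#' @param config a [rest_config()]
#' @export
generative_rest <- function(net = single_column_network(), priors,
                            config = rest_config()) {
  function(theta) {
    d <- split_paths(expand_theta(priors, theta_with_fixed(priors, theta)))
    net2 <- apply_deltas(net, d$net, validate = FALSE)
    asc <- if (!is.na(d$input["input:amp"])) exp(d$input[["input:amp"]]) else 1
    inp <- powerlaw_input(config$amp * asc, config$exponent, config$grid,
                          floor = config$floor_frac * config$amp * asc)
    cs <- predict_csd(net2, inp, config$noise, config$grid)
    nch <- dim(cs$csd)[[1]]
    as.vector(vapply(seq_along(cs$grid),
                     function(k) Re(diag(matrix(cs$csd[, , k], nch, nch))),
                     numeric(nch)))
  }
}

#' Configuration of the MMN evoked-response forward model
#'
#' The fitted observation is the set of source-space virtual-electrode
#' traces (one channel per area), per condition, downsampled to
#' `obs_dt_ms`; the conventional "virtual Fz" feature (the equal-weight sum
#' of the areas) is derived from these for the difference-wave analyses.
#'
#' @param stim an [erp_stimulus()]
#' @param conditions condition labels
#' @param dur_ms epoch length
#' @param dt_ms integration step
#' @param obs_dt_ms sampling step of the fitted observation
#' @export
mmn_config <- function(stim = erp_stimulus(onset_ms = 100, duration_ms = 70,
                                           amp = 80),
                       conditions = c("standard", "deviant"),
                       dur_ms = 450, dt_ms = 0.2, obs_dt_ms = 2,
                       ar_whiten = 0.9) {
  list(stim = stim, conditions = conditions, dur_ms = dur_ms, dt_ms = dt_ms,
       obs_dt_ms = obs_dt_ms, ar_whiten = ar_whiten)
}

#' AR(1) temporal whitening of a blocked observation vector
#'
#' EEG noise is strongly autocorrelated; fitting it as white makes
#' posteriors overconfident. The evoked-response observation model therefore
#' whitens data and predictions with a first-order autoregressive filter
#' (`x[t] - phi x[t-1]` within each condition block) before the Gaussian
#' likelihood is evaluated.
#'
#' @param x observation vector
#' @param blocks list of index vectors (condition blocks)
#' @param phi AR(1) coefficient at the observation sampling step
#' @export
whiten_ar1 <- function(x, blocks, phi) {
  if (phi == 0) return(x)
  for (b in blocks) {
    xb <- x[b]
    x[b] <- c(xb[1] * sqrt(1 - phi^2), xb[-1] - phi * xb[-length(xb)])
  }
  x
}

#' Generative model for MMN evoked responses
#' @inheritParams generative_csd
#' @param net base network (default [mmn_network()] with the standard
#'   deviant modulation)
#' @param config an [mmn_config()]
#' @return function: named theta -> concatenated per-condition traces
#' @export
generative_erp <- function(net = NULL, priors, config = mmn_config()) {
  if (is.null(net))
    net <- apply_deltas(mmn_network(), .cmc$mmn_deviant_B)
  decim <- max(1L, round(config$obs_dt_ms / config$dt_ms))
  function(theta) {
    d <- split_paths(expand_theta(priors, theta_with_fixed(priors, theta)))
    net2 <- apply_deltas(net, d$net, validate = FALSE)
    erp <- simulate_erp(net2, config$stim, config$conditions,
                        dur_ms = config$dur_ms, dt_ms = config$dt_ms,
                        decim = decim)
    unlist(lapply(erp$traces, as.numeric), use.names = FALSE)
  }
}

#' Block structure of an MMN observation (one block per condition x
#' source channel, used both for noise hyperparameters and whitening)
#' @param config an [mmn_config()]
#' @param n_chan number of source channels
#' @export
mmn_blocks <- function(config = mmn_config(), n_chan = 3) {
  decim <- max(1L, round(config$obs_dt_ms / config$dt_ms))
  nt <- length(seq(0, config$dur_ms, by = config$dt_ms))
  nrec <- (nt - 1L) %/% decim + 1L
  k <- length(config$conditions) * n_chan
  lapply(seq_len(k), function(i) (i - 1L) * nrec + seq_len(nrec))
}
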