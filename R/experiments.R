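# In-silico studies: the five-model resting-EEG perturbation study, the
# sensitivity analyses for the evoked and steady-state paradigms, and the
# end-to-end per-paradigm pipelines (fit / model selection / group
# inference) over synthetic cohorts.

#' The five microcircuit perturbation models of the resting-EEG study
#'
#' 1: loss of all inter-population connectivity; 2: loss of pyramidal
#' connections to or from interneurons; 3: interneuron disinhibition (less
#' ii self-inhibition); 4: increased interneuron self-inhibition; 5:
#' increased superficial-pyramidal self-inhibition. Increases are coded +1,
#' decreases -1.
#'
#' @return named list; each entry has `edges` (intrinsic connection names)
#'   and `dir`
#' @export
perturbation_models <- function() {
  list(
    model1 = list(edges = c("ss_sp", "sp_ss", "sp_ii", "ii_sp",
                            "ii_dp", "dp_ii"), dir = -1),
    model2 = list(edges = c("sp_ii", "ii_sp", "ii_dp", "dp_ii"), dir = -1),
    model3 = list(edges = "ii_ii", dir = -1),
    model4 = list(edges = "ii_ii", dir = +1),
    model5 = list(edges = "sp_sp", dir = +1))
}

#' Five-model resting-EEG perturbation study
#'
#' For each perturbation model, simulates a sequence of normalized resting
#' spectra from the baseline column (step 0) to the most extreme change,
#' multiplying the perturbed connection strengths by `(1 + step_frac)` per
#' increment (compounding). Band powers of the 1/f-adjusted spectra are
#' compared with step 0, and each model is classified by which of the
#' characteristic changes (theta up, beta down, gamma up) it reproduces
#' monotonically with an endpoint above `rel_threshold` of the largest
#' (non-alpha) endpoint change. Alpha deltas are reported but excluded from
#' classification (the column does not generate an alpha peak). The beta
#' peak frequency (largest adjusted power in 13-30 Hz) is tracked per step.
#'
#' @param steps number of simulations per model (including baseline)
#' @param step_frac fractional parameter change per increment
#' @param grid frequency grid
#' @param config a [rest_config()] for the forward model
#' @param rel_threshold classification threshold (fraction of the largest
#'   endpoint band change among theta/beta/gamma)
#' @return named list per model: `deltas` (steps x bands), `pattern` (named
#'   logical: theta_up, beta_down, gamma_up), `beta_peak_hz` per step,
#'   `failed_steps`
#' @export
rseeg_perturbation_study <- function(steps = 10, step_frac = 0.03,
                                     grid = default_grid("rest"),
                                     config = rest_config(grid = grid),
                                     rel_threshold = 0.15) {
  stopifnot(steps >= 2, step_frac > 0)
  inp <- powerlaw_input(config$amp, config$exponent, grid,
                        floor = config$floor_frac * config$amp)
  bands <- default_bands()
  spec_of <- function(net) {
    cs <- predict_csd(net, inp, config$noise, grid)
    pw <- Re(cs$csd[1, 1, ])
    adjust_onef(grid, pw / sum(pw))
  }
  bpk <- function(adj) {
    sel <- grid >= 13 & grid <= 30
    grid[sel][which.max(adj$adjusted[sel])]
  }
  base <- spec_of(single_column_network())
  bp0 <- band_power(base, bands)
  out <- list()
  for (mn in names(perturbation_models())) {
    mdl <- perturbation_models()[[mn]]
    deltas <- matrix(NA_real_, steps, 4,
                     dimnames = list(NULL, bands$name))
    pks <- rep(NA_real_, steps)
    failed <- integer()
    for (k in seq_len(steps)) {
      lam <- mdl$dir * log(1 + step_frac) * (k - 1)
      net <- apply_deltas(single_column_network(),
                          setNames(rep(lam, length(mdl$edges)),
                                   paste0("ctx:G:", mdl$edges)))
      adj <- tryCatch(spec_of(net), error = function(e) NULL)
      if (is.null(adj)) { failed <- c(failed, k); next }
      deltas[k, ] <- band_power(adj, bands) - bp0
      pks[k] <- bpk(adj)
    }
    ok <- !is.na(deltas[, 1])
    mono_up <- function(x) all(diff(x[ok]) > 0)
    mono_dn <- function(x) all(diff(x[ok]) < 0)
    endd <- deltas[max(which(ok)), ]
    thr <- rel_threshold * max(abs(endd[c("theta", "beta", "gamma")]))
    pattern <- c(
      theta_up = unname(mono_up(deltas[, "theta"]) && endd[["theta"]] > thr),
      beta_down = unname(mono_dn(deltas[, "beta"]) && endd[["beta"]] < -thr),
      gamma_up = unname(mono_up(deltas[, "gamma"]) && endd[["gamma"]] > thr))
    out[[mn]] <- list(deltas = deltas, pattern = pattern,
                      beta_peak_hz = pks, failed_steps = failed)
  }
  out
}

#' Sensitivity of paradigm data features to single parameters
#'
#' Simulates the paradigm's forward model over a grid of log-scaling deltas
#' for each named parameter and reports the feature trajectory: for the
#' mismatch paradigm, amplitude and latency of the difference wave; for the
#' steady-state paradigm, summed 35-45 Hz power.
#'
#' @param paradigm `"mmn"` or `"assr"`
#' @param parameters named list: parameter label -> parameter path deltas of
#'   1 unit (a named numeric over paths); or a character vector of paths
#' @param delta_grid log-scaling deltas to apply
#' @param config forward config for the paradigm
#' @return data.frame with one row per (parameter, delta)
#' @export
sensitivity_analysis <- function(paradigm = c("mmn", "assr"),
                                 parameters = NULL,
                                 delta_grid = seq(0, 0.6, by = 0.2),
                                 config = NULL) {
  paradigm <- match.arg(paradigm)
  if (is.null(parameters)) {
    parameters <- if (paradigm == "mmn")
      list(sp_self_deviant = c("B:deviant:IFG:G:sp_sp" = 1))
    else
      list(sp_self = c("L_A1:G:sp_sp" = 1, "R_A1:G:sp_sp" = 1),
           sp_ii = c("L_A1:G:sp_ii" = 1, "R_A1:G:sp_ii" = 1))
  }
  parameters <- lapply(parameters, function(p)
    if (is.character(p)) setNames(rep(1, length(p)), p) else p)
  rows <- list()
  if (paradigm == "mmn") {
    cfg <- config %||% mmn_config()
    for (pn in names(parameters)) {
      for (d in delta_grid) {
        net <- apply_deltas(mmn_network(), .cmc$mmn_deviant_B)
        net <- apply_deltas(net, parameters[[pn]] * d)
        erp <- simulate_erp(net, cfg$stim, cfg$conditions,
                            dur_ms = cfg$dur_ms, dt_ms = cfg$dt_ms,
                            decim = max(1L, round(cfg$obs_dt_ms / cfg$dt_ms)))
        fz <- lapply(erp$traces, rowSums)
        mw <- mismatch_wave(fz$standard, fz$deviant, erp$time_ms,
                            stim_onset_ms = cfg$stim$onset_ms)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = pn, delta = d, amplitude = mw$amplitude,
          abs_amplitude = abs(mw$amplitude), latency_ms = mw$latency_ms)
      }
    }
  } else {
    cfg <- config %||% assr_config()
    inp <- gaussian_bump_input(cfg$center, cfg$width, cfg$amp, cfg$grid,
                               floor = cfg$floor_frac * cfg$amp)
    base_net <- apply_deltas(assr_network(), assr_operating_deltas())
    for (pn in names(parameters)) {
      for (d in delta_grid) {
        net <- apply_deltas(base_net, parameters[[pn]] * d)
        cs <- predict_csd(net, inp, cfg$noise, cfg$grid)
        sel <- cfg$grid >= 35 & cfg$grid <= 45
        pw <- sum(vapply(which(sel), function(k)
          sum(Re(diag(matrix(cs$csd[, , k], dim(cs$csd)[1], dim(cs$csd)[1])))),
          numeric(1)))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = pn, delta = d, gamma_power = pw)
      }
    }
  }
  do.call(rbind, rows)
}

#' Fit one subject and score the paradigm's model space by Bayesian model
#' reduction
#'
#' The richest model of the paradigm is fitted by variational Laplace; the
#' evidence of every other model-space member is then obtained analytically
#' by BMR of that single fit (reduced models pin or re-center the prior of
#' the parameters they remove).
#'
#' @param data_vec observation vector
#' @param paradigm `"mmn"` or `"assr"`
#' @param config forward config
#' @param settings a [vl_settings()]
#' @param free_subset optional character vector restricting the fitted
#'   parameters (the rest stay at their prior means); model scoring is then
#'   skipped
#' @return list with `fit`, `evidence` (named per model), `posteriors`
#'   (BMR posterior per model)
#' @export
fit_subject <- function(data_vec, paradigm = c("mmn", "assr"),
                        config = NULL, settings = vl_settings(),
                        free_subset = NULL) {
  paradigm <- match.arg(paradigm)
  full_id <- if (paradigm == "mmn") "6G,D,T" else "full"
  priors <- default_priors(paradigm, full_id)
  if (!is.null(free_subset)) {
    keep <- priors$table$name %in% free_subset | priors$table$var == 0
    fix <- priors$table$name[!keep & priors$table$var > 0]
    priors$table$var[priors$table$name %in% fix] <- 0
  }
  if (paradigm == "mmn") {
    cfg <- config %||% mmn_config()
    gen0 <- generative_erp(priors = priors, config = cfg)
    blocks <- mmn_blocks(cfg)
    phi <- cfg$ar_whiten %||% 0
    gen <- function(theta) whiten_ar1(gen0(theta), blocks, phi)
    data_vec <- whiten_ar1(data_vec, blocks, phi)
  } else {
    cfg <- config %||% assr_config()
    gen <- generative_csd(priors = priors, config = cfg)
    blocks <- NULL
  }
  fit <- fit_variational_laplace(gen, data_vec, priors, blocks, settings)
  out <- list(fit = fit)
  if (is.null(free_subset)) {
    ids <- model_space(paradigm)
    ev <- setNames(numeric(length(ids)), ids)
    posts <- list()
    full_mean <- free_mean(priors); full_var <- free_var(priors)
    for (id in ids) {
      pri_id <- default_priors(paradigm, id)
      tb <- pri_id$table
      red_mean <- full_mean; red_var <- full_var
      for (nm in names(full_mean)) {
        row <- which(tb$name == nm)
        if (!length(row) || tb$var[[row]] == 0) {
          red_var[[nm]] <- 1e-8
          red_mean[[nm]] <- if (length(row)) tb$mean[[row]] else 0
        } else {
          red_var[[nm]] <- tb$var[[row]]
          red_mean[[nm]] <- tb$mean[[row]]
        }
      }
      r <- bayesian_model_reduction(fit$mean, fit$cov, full_mean,
                                    diag(full_var, length(full_var)),
                                    red_mean, diag(red_var, length(red_var)))
      ev[[id]] <- fit$F + r$dF
      posts[[id]] <- r
    }
    out$evidence <- ev
    out$posteriors <- posts
  }
  out
}

#' Run a full paradigm pipeline over a synthetic cohort
#'
#' Per-subject variational-Laplace fits of the paradigm's full model,
#' model-space scoring by Bayesian model reduction, random-effects Bayesian
#' model selection, and parametric-empirical-Bayes contrasts on the selected
#' parameters. Deterministic given the cohort and `seed`.
#'
#' @param paradigm `"mmn"` or `"assr"`
#' @param cohort a [generate_cohort()] result containing the paradigm's data
#' @param scheme design scheme for [make_design()]
#' @param parameter_selection parameters taken to the second level (default:
#'   sensible per paradigm)
#' @param free_subset optional restriction of fitted parameters (speeds up
#'   recovery studies; disables model selection)
#' @param settings a [vl_settings()]
#' @param config forward config
#' @param seed seed for the model-selection Monte Carlo
#' @param use_covariates include age/sex/smoking covariates in the design
#' @param exclude_nonconverged drop subjects whose fit did not converge
#' @return list: `fits`, `evidence` matrix, `bms`, `peb`, `design`,
#'   `report` (R^2 summary, excluded subjects, winning model)
#' @export
run_paradigm_pipeline <- function(paradigm = c("mmn", "assr"), cohort,
                                  scheme = c("groups", "risk"),
                                  parameter_selection = NULL,
                                  free_subset = NULL,
                                  settings = vl_settings(),
                                  config = NULL, seed = 1,
                                  use_covariates = FALSE,
                                  exclude_nonconverged = TRUE) {
  paradigm <- match.arg(paradigm)
  scheme <- match.arg(scheme)
  if (!paradigm %in% cohort$paradigms)
    stop("cohort has no ", paradigm, " data")
  subs <- cohort$subjects
  datavec <- lapply(subs, function(s) {
    if (paradigm == "mmn") unlist(lapply(s$data$mmn$traces, as.numeric),
                                  use.names = FALSE)
    else csd_to_vec(s$data$assr)
  })
  fits <- lapply(datavec, fit_subject, paradigm = paradigm, config = config,
                 settings = settings, free_subset = free_subset)
  conv <- vapply(fits, function(f) isTRUE(f$fit$converged), logical(1))
  keep <- if (exclude_nonconverged) conv else rep(TRUE, length(fits))
  excluded <- vapply(subs, function(s) s$id, character(1))[!keep]

  evidence <- NULL; bms <- NULL; win <- NULL
  if (is.null(free_subset)) {
    evidence <- do.call(rbind, lapply(fits[keep], function(f) f$evidence))
    bms <- bms_random_effects(evidence, seed = seed)
    win <- colnames(evidence)[which.max(bms$pxp)]
  }
  group <- vapply(subs, function(s) s$group, character(1))[keep]
  covs <- if (use_covariates) {
    data.frame(age = vapply(subs, function(s) s$covariates$age, numeric(1)),
               male = vapply(subs, function(s) s$covariates$male, numeric(1)),
               smoker = vapply(subs, function(s) s$covariates$smoker,
                               numeric(1)))[keep, , drop = FALSE]
  } else NULL
  X <- make_design(group, scheme, covs)
  sf <- lapply(fits[keep], function(f) f$fit)
  if (is.null(parameter_selection)) {
    nm <- names(sf[[1]]$mean)
    parameter_selection <- if (paradigm == "mmn")
      grep("^B:", nm, value = TRUE) else grep("^G:", nm, value = TRUE)
  }
  peb <- peb_fit(sf, X, parameter_selection)
  r2 <- vapply(sf, function(f) f$R2, numeric(1))
  list(fits = fits, evidence = evidence, bms = bms, peb = peb, design = X,
       report = list(
         n = length(sf), excluded = excluded, winning_model = win,
         r2_mean = mean(r2), r2_sd = sd(r2),
         r2_hist = quantile(r2, c(0, 0.25, 0.5, 0.75, 1))))
}
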