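# Synthetic cohorts with the statistical structure the hierarchical analysis
# assumes: subject-level parameters drawn around group means (group contrasts
# as log-scale deltas), symptom scores linearly coupled to named parameters,
# demographic covariates, and per-paradigm observation noise. Everything is
# reproducible from the spec's seed.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the study's structure: three groups (controls n=107,
#' people with schizophrenia diagnoses n=108, first-degree relatives n=57),
#' a diagnosis effect of +0.25 log units on superficial-pyramidal
#' self-inhibition, a genetic-risk effect of -0.2 on sp->ii connectivity,
#' positive/negative symptom scales (0-49 / 0-28) coupled to auditory-area
#' disinhibition, and demographic covariates (age ~ N(39.4, 14), sex and
#' smoking Bernoulli). Between-subject parameter SDs and noise levels are
#' package choices (see the methods vignette); effect sizes of 0.2-0.3 log
#' units correspond to parameter changes of roughly 20-30%.
#'
#' @param n named group sizes
#' @param effects list of contrast effects; each has `groups` (which groups
#'   carry the delta) and per-paradigm named delta vectors over free
#'   parameter names of that paradigm's full model
#' @param between_sd between-subject SD (log units) for connectivity and
#'   condition-effect parameters (names starting `G:` or `B:`)
#' @param between_sd_nuisance between-subject SD for operating-point
#'   parameters (time constants, gains, lead fields, input settings), which
#'   are treated as paradigm-level calibrations with only small individual
#'   variation
#' @param symptoms list describing the linear symptom model per scale:
#'   `intercepts` per group, `coupling` (named, over ASSR parameter names),
#'   `sd` residual SD, `range` clip range
#' @param covariates list with age mean/sd, sex and smoking probabilities,
#'   and antipsychotic dose-equivalent parameters (dose in the PScz group
#'   only)
#' @param noise list: `rest_log_sd` multiplicative log-normal SD for resting
#'   spectra; `mmn_frac` MMN noise SD as a fraction of the signal SD with
#'   AR(1) coefficient `mmn_ar`; `assr_dof` complex-Wishart degrees of
#'   freedom for ASSR cross-spectra
#' @param seed master seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(
    n = c(Con = 107, PScz = 108, Rel = 57),
    effects = list(
      diagnosis = list(
        groups = "PScz",
        assr = c("G:sp_sp:L_A1" = 0.25, "G:sp_sp:R_A1" = 0.25),
        mmn = c("B:G:sp_sp:IFG" = 0.25)),
      genetic_risk = list(
        groups = c("PScz", "Rel"),
        assr = c("G:sp_ii" = -0.2))),
    between_sd = 0.15,
    between_sd_nuisance = 0.01,
    symptoms = list(
      positive = list(intercepts = c(Con = 2, PScz = 14.4, Rel = 5),
                      coupling = c("G:sp_sp:L_A1" = -25,
                                   "G:sp_sp:R_A1" = -25),
                      sd = 5, range = c(0, 49)),
      negative = list(intercepts = c(Con = 1, PScz = 7.3, Rel = 3),
                      coupling = c("G:sp_ii" = 15),
                      sd = 3, range = c(0, 28))),
    covariates = list(age_mean = 39.4, age_sd = 14,
                      p_male = c(Con = 0.68, PScz = 0.59, Rel = 0.6),
                      p_smoker = c(Con = 0.39, PScz = 0.33, Rel = 0.35),
                      cpz_meanlog = 5.5, cpz_sdlog = 0.6),
    noise = list(rest_log_sd = 0.2, mmn_frac = 0.05, mmn_ar = 0.9,
                 assr_dof = 160),
    seed = 1) {
  stopifnot(all(n >= 1), between_sd >= 0, between_sd_nuisance >= 0)
  structure(list(n = n, effects = effects, between_sd = between_sd,
                 between_sd_nuisance = between_sd_nuisance,
                 symptoms = symptoms, covariates = covariates,
                 noise = noise, seed = seed), class = "cohort_spec")
}

# true free-parameter vector for one subject of a given group in a paradigm
.draw_theta <- function(spec, paradigm, group, priors) {
  mu <- free_mean(priors)
  for (eff in spec$effects) {
    if (!group %in% eff$groups) next
    d <- eff[[paradigm]]
    if (is.null(d)) next
    common <- intersect(names(d), names(mu))
    mu[common] <- mu[common] + d[common]
  }
  sds <- ifelse(grepl("^(G|B):", names(mu)),
                spec$between_sd,
                spec$between_sd_nuisance %||% spec$between_sd)
  mu + rnorm(length(mu), 0, sds)
}

#' Generate per-paradigm data for one set of true parameters
#'
#' Resting spectra get multiplicative log-normal noise; evoked responses get
#' additive AR(1) noise scaled to the signal; ASSR cross-spectra get a
#' complex-Wishart resampling that preserves the Hermitian
#' positive-semidefinite structure. With all noise parameters zero /
#' infinite degrees of freedom, the data equal the forward predictions.
#'
#' @param theta named list of true free-parameter vectors per paradigm
#' @param paradigms which paradigms to generate
#' @param noise noise list as in [cohort_spec()]
#' @param seed RNG seed (the draw is fully reproducible)
#' @param configs optional list of per-paradigm forward configs
#' @return named list of per-paradigm data
#' @export
generate_subject_data <- function(theta, paradigms = c("rest", "mmn", "assr"),
                                  noise = cohort_spec()$noise, seed = 1,
                                  configs = list()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  if ("rest" %in% paradigms) {
    cfg <- configs$rest %||% rest_config()
    pri <- default_priors("rest")
    gen <- generative_rest(priors = pri, config = cfg)
    mu <- gen(theta$rest)
    eps <- if (noise$rest_log_sd > 0) rnorm(length(mu), 0, noise$rest_log_sd) else 0
    out$rest <- list(grid = cfg$grid, power = mu * exp(eps))
  }
  if ("mmn" %in% paradigms) {
    cfg <- configs$mmn %||% mmn_config()
    pri <- default_priors("mmn", "6G")
    gen <- generative_erp(priors = pri, config = cfg)
    mu <- gen(theta$mmn)
    n_chan <- 3L
    blocks <- mmn_blocks(cfg, n_chan)
    if (noise$mmn_frac > 0) {
      sig_sd <- sd(mu)
      for (b in blocks) {
        e <- as.numeric(arima_sim_ar1(length(b), noise$mmn_ar))
        mu[b] <- mu[b] + e / sd(e) * sig_sd * noise$mmn_frac
      }
    }
    ncond <- length(cfg$conditions)
    nrec <- length(mu) / (ncond * n_chan)
    traces <- lapply(seq_len(ncond), function(j) {
      m <- matrix(mu[(j - 1) * nrec * n_chan + seq_len(nrec * n_chan)],
                  nrec, n_chan)
      colnames(m) <- c("A1", "STG", "IFG")
      m
    })
    names(traces) <- cfg$conditions
    out$mmn <- list(time_ms = seq(0, by = cfg$obs_dt_ms, length.out = nrec),
                    traces = traces,
                    fz = vapply(traces, rowSums, numeric(nrec)),
                    stim_onset_ms = cfg$stim$onset_ms)
  }
  if ("assr" %in% paradigms) {
    cfg <- configs$assr %||% assr_config()
    pri <- default_priors("assr", "full")
    d <- split_paths(expand_theta(pri, theta$assr))
    net <- apply_deltas(assr_network(), d$net)
    wsc <- if (!is.na(d$input["input:width"])) exp(d$input[["input:width"]]) else 1
    asc <- if (!is.na(d$input["input:amp"])) exp(d$input[["input:amp"]]) else 1
    inp <- gaussian_bump_input(cfg$center, cfg$width * wsc, cfg$amp * asc,
                               cfg$grid, floor = cfg$floor_frac * cfg$amp * asc)
    cs <- predict_csd(net, inp, cfg$noise, cfg$grid)
    if (is.finite(noise$assr_dof)) cs <- wishart_resample(cs, noise$assr_dof)
    out$assr <- cs
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

arima_sim_ar1 <- function(n, phi) {
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(1 - phi^2)
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + e[i + 1]
  x
}

#' Complex-Wishart resampling of a cross-spectrum
#'
#' Replaces S(f) by the average outer product of `dof` complex-normal draws
#' with covariance S(f); the result is Hermitian positive semidefinite by
#' construction, with relative variability ~ 1/sqrt(dof).
#'
#' @param cs a `cross_spectrum`
#' @param dof degrees of freedom
#' @export
wishart_resample <- function(cs, dof) {
  nch <- dim(cs$csd)[[1]]
  for (k in seq_along(cs$grid)) {
    S <- matrix(cs$csd[, , k], nch, nch)
    S <- (S + Conj(t(S))) / 2
    eg <- eigen(S, symmetric = TRUE)
    rt <- eg$vectors %*% diag(sqrt(pmax(Re(eg$values), 0)), nch)
    Z <- (matrix(rnorm(dof * nch), dof, nch) +
            1i * matrix(rnorm(dof * nch), dof, nch)) / sqrt(2)
    X <- Z %*% Conj(t(rt))
    cs$csd[, , k] <- Conj(t(X)) %*% X / dof
  }
  cs
}

#' Generate a synthetic cohort
#'
#' Subject parameters are the full-model prior means plus the group's
#' contrast deltas plus between-subject Gaussian noise; symptom scores come
#' from the linear coupling model; data come from the forward models plus
#' observation noise. Every subject carries its own sub-seed so records can
#' be regenerated exactly.
#'
#' @param spec a [cohort_spec()]
#' @param paradigms paradigms to generate data for
#' @param configs optional per-paradigm forward configs
#' @param max_retry redraw budget for unstable parameter draws
#' @return object of class `cohort`: list of subject records plus the spec
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            paradigms = c("rest", "mmn", "assr"),
                            configs = list(), max_retry = 20) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  groups <- rep(names(spec$n), spec$n)
  nsub <- length(groups)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nsub)
  priors <- list(rest = default_priors("rest"),
                 mmn = default_priors("mmn", "6G"),
                 assr = default_priors("assr", "full"))
  subjects <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    g <- groups[[i]]
    set.seed(sub_seeds[[i]])
    rec <- NULL
    for (attempt in seq_len(max_retry)) {
      theta <- lapply(setNames(paradigms, paradigms), function(pd)
        .draw_theta(spec, pd, g, priors[[pd]]))
      cov_ <- list(
        age = rnorm(1, spec$covariates$age_mean, spec$covariates$age_sd),
        male = rbinom(1, 1, spec$covariates$p_male[[g]]),
        smoker = rbinom(1, 1, spec$covariates$p_smoker[[g]]),
        cpz = if (g == "PScz")
          rlnorm(1, spec$covariates$cpz_meanlog, spec$covariates$cpz_sdlog)
          else 0)
      sym <- lapply(spec$symptoms, function(sm) {
        val <- sm$intercepts[[g]] + rnorm(1, 0, sm$sd)
        if ("assr" %in% paradigms) {
          cm <- intersect(names(sm$coupling), names(theta$assr))
          mu0 <- free_mean(priors$assr)
          val <- val + sum(sm$coupling[cm] * (theta$assr[cm] - mu0[cm]))
        }
        min(max(val, sm$range[[1]]), sm$range[[2]])
      })
      data_seed <- sample.int(.Machine$integer.max - 1L, 1)
      dat <- tryCatch(
        generate_subject_data(theta, paradigms, spec$noise, data_seed,
                              configs),
        error = function(e) NULL)
      if (!is.null(dat)) {
        rec <- list(id = sprintf("S%03d", i), group = g, covariates = cov_,
                    symptoms = sym, theta = theta, data = dat,
                    seed = sub_seeds[[i]], data_seed = data_seed,
                    attempt = attempt)
        break
      }
    }
    if (is.null(rec))
      stop("subject ", i, " (", g, "): no stable parameter draw in ",
           max_retry, " attempts")
    subjects[[i]] <- rec
  }
  structure(list(subjects = subjects, spec = spec, paradigms = paradigms),
            class = "cohort")
}

#' Write / read a cohort as a directory (manifest + one file per subject)
#' @param cohort a [generate_cohort()] result
#' @param dir directory path (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort$subjects, function(s) s$id, character(1))
  write_container(list(spec = unclass(cohort$spec),
                       paradigms = cohort$paradigms, ids = ids),
                  file.path(dir, "manifest.json"),
                  meta = list(config = unclass(cohort$spec)))
  for (s in cohort$subjects)
    write_container(s, file.path(dir, paste0(s$id, ".json")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- read_container(file.path(dir, "manifest.json"))$payload
  subjects <- lapply(man$ids, function(id)
    read_container(file.path(dir, paste0(id, ".json")))$payload)
  spec <- man$spec; class(spec) <- "cohort_spec"
  structure(list(subjects = subjects, spec = spec,
                 paradigms = man$paradigms), class = "cohort")
}
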