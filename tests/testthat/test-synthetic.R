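test_that("the default cohort has the study's group structure", {
  spec <- cohort_spec()
  expect_equal(spec$n, c(Con = 107, PScz = 108, Rel = 57))
  small <- cohort_spec(n = c(Con = 3, PScz = 4, Rel = 2), seed = 5)
  coh <- generate_cohort(small, paradigms = "rest")
  expect_length(coh$subjects, 9)
  counts <- table(vapply(coh$subjects, function(s) s$group, character(1)))
  expect_equal(as.vector(counts[c("Con", "PScz", "Rel")]), c(3L, 4L, 2L))
  # symptoms stay inside their scales
  pos <- vapply(coh$subjects, function(s) s$symptoms$positive, numeric(1))
  neg <- vapply(coh$subjects, function(s) s$symptoms$negative, numeric(1))
  expect_true(all(pos >= 0 & pos <= 49))
  expect_true(all(neg >= 0 & neg <= 28))
})

test_that("a degenerate spec collapses all subjects onto one parameter set", {
  spec <- cohort_spec(n = c(Con = 3), effects = list(), between_sd = 0,
                      between_sd_nuisance = 0,
                      noise = list(rest_log_sd = 0, mmn_frac = 0,
                                   mmn_ar = 0, assr_dof = Inf), seed = 2)
  coh <- generate_cohort(spec, paradigms = c("rest", "assr"),
                         configs = list(assr = quick_assr_config()))
  th <- lapply(coh$subjects, function(s) s$theta$assr)
  expect_identical(th[[1]], th[[2]])
  expect_identical(coh$subjects[[1]]$data$rest$power,
                   coh$subjects[[3]]$data$rest$power)
  # zero noise: data equal the forward prediction exactly
  pri <- default_priors("assr", "full")
  gen <- generative_csd(priors = pri, config = quick_assr_config())
  expect_equal(csd_to_vec(coh$subjects[[1]]$data$assr),
               gen(th[[1]]), tolerance = 1e-12)
})

test_that("cohorts and subject data are reproducible from their seeds", {
  spec <- cohort_spec(n = c(Con = 2, PScz = 2), seed = 11)
  c1 <- generate_cohort(spec, paradigms = "assr",
                        configs = list(assr = quick_assr_config()))
  c2 <- generate_cohort(spec, paradigms = "assr",
                        configs = list(assr = quick_assr_config()))
  expect_identical(c1$subjects[[3]]$theta, c2$subjects[[3]]$theta)
  expect_identical(c1$subjects[[3]]$data$assr$csd, c2$subjects[[3]]$data$assr$csd)
  s <- c1$subjects[[2]]
  re <- generate_subject_data(s$theta, "assr", spec$noise, s$data_seed,
                              configs = list(assr = quick_assr_config()))
  expect_identical(re$assr$csd, s$data$assr$csd)
})

test_that("group contrast deltas appear in the true parameters", {
  spec <- cohort_spec(n = c(PScz = 40, Rel = 40), seed = 3)
  coh <- generate_cohort(spec, paradigms = "assr",
                         configs = list(assr = quick_assr_config()))
  sp <- vapply(coh$subjects, function(s)
    mean(s$theta$assr[c("G:sp_sp:L_A1", "G:sp_sp:R_A1")]), numeric(1))
  grp <- vapply(coh$subjects, function(s) s$group, character(1))
  dd <- mean(sp[grp == "PScz"]) - mean(sp[grp == "Rel"])
  expect_lt(abs(dd - 0.25), 3 * 0.2 * sqrt(2 / 40))
})

test_that("resampled cross-spectra keep the Hermitian PSD structure", {
  set.seed(9)
  grid <- seq(34, 46, by = 1)
  net <- apply_deltas(assr_network(), assr_operating_deltas())
  cs <- predict_csd(net, gaussian_bump_input(40, 4, 1e-3, grid),
                    noise_model(channel_white = 1e-10), grid)
  for (dof in c(8, 40, 160)) {
    for (rep in 1:10) {
      noisy <- wishart_resample(cs, dof)
      expect_true(isTRUE(check_cross_spectrum(noisy)))
    }
  }
})

test_that("recovery error vanishes as observation noise is removed", {
  fs <- c("G:sp_sp:L_A1", "G:sp_sp:R_A1")
  pri <- default_priors("assr", "full")
  th <- free_mean(pri)
  th[fs] <- th[fs] + 0.3
  errs <- vapply(c(20, 160, Inf), function(dof) {
    dat <- generate_subject_data(
      list(assr = th), "assr",
      noise = list(rest_log_sd = 0, mmn_frac = 0, mmn_ar = 0,
                   assr_dof = dof),
      seed = 21, configs = list(assr = quick_assr_config()))
    r <- fit_subject(csd_to_vec(dat$assr), "assr",
                     config = quick_assr_config(),
                     free_subset = c(fs, "G:sp_ii", "G:ii_sp"),
                     settings = vl_settings(max_iter = 24))
    mean(abs(r$fit$mean[fs] - th[fs]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[[3]], 0.02)
})

test_that("fitting regenerated subjects recovers the key parameter ranking", {
  cfg <- assr_config()   # full grid: the ranking check is about information
  spec <- cohort_spec(n = c(Con = 20), effects = list(), seed = 31)
  coh <- generate_cohort(spec, paradigms = "assr",
                         configs = list(assr = cfg))
  fs <- c("G:sp_sp:L_A1", "G:sp_sp:R_A1", "G:sp_ii", "G:ii_sp")
  est <- vapply(coh$subjects, function(s) {
    fit_subject(csd_to_vec(s$data$assr), "assr", config = cfg,
                free_subset = fs,
                settings = vl_settings(max_iter = 12))$fit$mean[["G:sp_sp:L_A1"]]
  }, numeric(1))
  true_sp <- vapply(coh$subjects, function(s)
    s$theta$assr[["G:sp_sp:L_A1"]], numeric(1))
  expect_gte(cor(true_sp, est, method = "spearman"), 0.6)
})

test_that("cohorts round-trip through the directory container", {
  spec <- cohort_spec(n = c(Con = 2), seed = 7)
  coh <- generate_cohort(spec, paradigms = "rest")
  d <- file.path(tempdir(), "coh_test")
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(back$subjects[[1]]$theta$rest, coh$subjects[[1]]$theta$rest)
  expect_equal(back$subjects[[2]]$data$rest$power,
               coh$subjects[[2]]$data$rest$power)
  unlink(d, recursive = TRUE)
})
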