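test_that("linear-Gaussian inversion matches the conjugate closed form", {
  toy <- linear_toy()
  ref <- linear_conjugate(toy)
  fit <- fit_variational_laplace(
    toy$model, toy$y, toy$priors,
    settings = vl_settings(hyper_fixed = TRUE,
                           hyper_init = log(1 / toy$noise_sd^2)))
  expect_equal(unname(fit$mean), ref$mean, tolerance = 1e-8)
  expect_equal(fit$cov, ref$cov, tolerance = 1e-8)
  expect_equal(fit$F, ref$logZ, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("free energy is monotone over accepted iterations", {
  toy <- linear_toy(seed = 9)
  fit <- fit_variational_laplace(toy$model, toy$y, toy$priors)
  expect_true(all(diff(fit$trace) > -1e-9))
  # also on a nonlinear model
  model_nl <- function(th) exp(0.3 * drop(toy$J %*% th)) - 1
  y_nl <- model_nl(toy$theta) + rnorm(length(toy$y), 0, 0.05)
  fit2 <- fit_variational_laplace(model_nl, y_nl, toy$priors)
  expect_true(all(diff(fit2$trace) > -1e-9))
})

test_that("inversion is invariant to log-scale translation of the problem", {
  toy <- linear_toy(seed = 5)
  delta <- 0.4
  fit1 <- fit_variational_laplace(toy$model, toy$y, toy$priors)
  pri2 <- toy$priors
  pri2$mean <- pri2$mean + delta
  model2 <- function(th) toy$model(th - delta)
  fit2 <- fit_variational_laplace(model2, toy$y, pri2)
  expect_equal(fit2$F, fit1$F, tolerance = 1e-4)
  expect_equal(unname(fit2$mean - delta), unname(fit1$mean),
               tolerance = 1e-5)
})

test_that("noiseless data at the prior mean are recovered trivially", {
  pri <- default_priors("assr", "full")
  gen <- generative_csd(priors = pri, config = quick_assr_config())
  y <- gen(free_mean(pri))
  fit <- fit_variational_laplace(gen, y, pri,
                                 settings = vl_settings(max_iter = 8))
  expect_lt(max(abs(fit$mean - free_mean(pri))), 0.05)
  expect_gt(fit$R2, 0.99)
})

test_that("hyperparameters track the true noise level", {
  toy <- linear_toy(n = 200, seed = 3, noise_sd = 0.2)
  fit <- fit_variational_laplace(toy$model, toy$y, toy$priors)
  expect_equal(exp(-fit$lambda / 2), 0.2, tolerance = 0.25)
})

test_that("fit quality follows the variance-explained definition", {
  y <- c(1, 2, 3, 4)
  expect_equal(fit_quality(y, y), 1)
  expect_equal(fit_quality(rep(mean(y), 4), y), 0)
  expect_lt(fit_quality(rev(y), y), 0)
  expect_error(fit_quality(y, rep(2, 4)), "variance")
  expect_error(fit_quality(y[-1], y), "mismatch")
})
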