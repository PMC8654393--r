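test_that("reducing to the identical prior changes nothing", {
  toy <- linear_toy()
  ref <- linear_conjugate(toy)
  r <- bayesian_model_reduction(ref$mean, ref$cov, rep(0, 3), diag(3),
                                rep(0, 3), diag(3))
  expect_equal(r$dF, 0, tolerance = 1e-10)
  expect_equal(r$mean, ref$mean, tolerance = 1e-10)
})

test_that("model reduction equals direct inversion under the reduced prior", {
  toy <- linear_toy()
  full <- linear_conjugate(toy)
  red_var <- c(1e-6, 1, 0.25)
  red <- linear_conjugate(toy, pv = red_var)
  r <- bayesian_model_reduction(full$mean, full$cov, rep(0, 3), diag(3),
                                rep(0, 3), diag(red_var))
  expect_equal(unname(r$mean), red$mean, tolerance = 1e-6)
  expect_equal(r$cov, red$cov, tolerance = 1e-6)
  expect_equal(r$dF, red$logZ - full$logZ, tolerance = 1e-6)
})

test_that("pinning an uninformed parameter increases the evidence", {
  set.seed(1)
  n <- 50
  J <- cbind(rnorm(n), 0)            # second parameter never enters the data
  y <- J[, 1] * 0.5 + rnorm(n, 0, 0.1)
  post <- linear_conjugate(list(J = J, y = y, noise_sd = 0.1))
  r <- bayesian_model_reduction(post$mean, post$cov, c(0, 0), diag(2),
                                c(0, 0), diag(c(1, 1e-8)))
  expect_gt(r$dF, 0)
})

test_that("BMR rejects degenerate reduced precisions", {
  expect_error(
    bayesian_model_reduction(c(0, 0), diag(2) * 10, c(0, 0), diag(2) * 0.01,
                             c(0, 0), diag(2) * 100),
    "positive definite")
})

test_that("design matrices implement both contrast schemes", {
  g <- rep(c("Con", "PScz", "Rel"), times = c(4, 4, 4))
  X1 <- make_design(g, "groups")
  expect_setequal(colnames(X1), c("mean", "PScz>Con", "Rel>Con"))
  X2 <- make_design(g, "risk", covariates = data.frame(age = rnorm(12)))
  expect_setequal(colnames(X2), c("mean", "risk", "diagnosis", "age"))
  expect_equal(unname(colMeans(X2[, -1])), rep(0, 3), tolerance = 1e-12)
  expect_error(make_design(g, "groups",
                           covariates = data.frame(a = 1:12, b = 2 * (1:12))),
               "rank deficient")
})

test_that("a homogeneous cohort yields the common mean and no effects", {
  set.seed(4)
  fits <- lapply(1:12, function(i) shrunk_post(c(a = 0.31, b = -0.12)))
  X <- cbind(1, rep(c(-0.5, 0.5), 6))
  colnames(X) <- c("mean", "grp")
  peb <- peb_fit(fits, X)
  expect_equal(unname(peb$beta[, "mean"]), c(0.31, -0.12), tolerance = 0.05)
  expect_true(all(peb$prob[, "grp"] < 0.95))
})

test_that("PEB recovers a built-in group difference with the right sign", {
  set.seed(8)
  n <- 24
  grp <- rep(c(-0.5, 0.5), each = n / 2)
  fits <- lapply(seq_len(n), function(i)
    shrunk_post(c(a = 0.3 * grp[i] + rnorm(1, 0, 0.05),
                  b = rnorm(1, 0, 0.05)), info = 200))
  X <- cbind(mean = rep(1, n), grp = grp)
  peb <- peb_fit(fits, X)
  expect_gt(peb$beta["a", "grp"], 0.1)
  expect_gt(peb$prob["a", "grp"], 0.95)
  expect_lt(peb$prob["b", "grp"], 0.95)
  pr <- peb_prune(peb)
  expect_true(pr$kept["a", "grp"])
  expect_lt(abs(pr$bma_mean["b", "grp"]), abs(peb$beta["b", "grp"]) + 1e-9)
})

test_that("a single subject with identity design returns its own posterior", {
  f <- shrunk_post(c(a = 0.2))
  peb <- peb_fit(list(f), matrix(1, 1, 1, dimnames = list(NULL, "mean")))
  # shrunk toward the second-level prior mean of zero, but dominated by the
  # subject's own evidence
  expect_gt(unname(peb$beta[1, 1]), 0.12)
  expect_lt(unname(peb$beta[1, 1]), 0.21)
})

test_that("random-effects selection is symmetric, decisive and exchangeable", {
  set.seed(6)
  L <- matrix(rnorm(60, 0, 0.01), 20, 3)
  b <- bms_random_effects(L, samples = 5e4, seed = 2)
  expect_equal(sum(b$pxp), 1, tolerance = 1e-9)
  expect_true(all(abs(b$pxp - 1 / 3) < 0.05))
  expect_gt(b$bor, 0.8)
  # a dominant model
  L2 <- L; L2[, 3] <- L2[, 3] + 10
  b2 <- bms_random_effects(L2, samples = 5e4, seed = 2)
  expect_gt(b2$pxp[[3]], 0.99)
  # permuting models permutes the outputs
  perm <- c(3, 1, 2)
  b3 <- bms_random_effects(L2[, perm], samples = 5e4, seed = 2)
  expect_equal(b3$expected_p, b2$expected_p[perm], tolerance = 1e-9)
  expect_equal(b3$pxp, b2$pxp[perm], tolerance = 0.01)
  expect_error(bms_random_effects(L[, 1, drop = FALSE]), "2 models")
})
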