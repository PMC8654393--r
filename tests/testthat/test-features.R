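test_that("the aperiodic fit recovers pure power laws exactly", {
  grid <- seq(2, 48, by = 0.25)
  pw <- 3 * grid^-2
  a <- adjust_onef(grid, pw)
  expect_equal(a$slope, -2, tolerance = 1e-10)
  expect_lt(max(abs(a$adjusted)), 1e-10 * max(pw))
  flat <- adjust_onef(grid, rep(2.5, length(grid)))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_error(adjust_onef(grid, -pw), "positive")
})

test_that("an oscillatory bump survives aperiodic removal at its frequency", {
  grid <- seq(2, 48, by = 0.25)
  pw <- grid^-1.5 + 0.5 * dnorm(grid, 10, 1)
  a <- adjust_onef(grid, pw)
  expect_equal(grid[which.max(a$adjusted)], 10, tolerance = 0.5)
})

test_that("relative residuals are invariant to power-law rescaling", {
  grid <- seq(2, 48, by = 0.25)
  pw <- grid^-1.2 + 0.3 * dnorm(grid, 20, 3)
  a1 <- adjust_onef(grid, pw)
  a2 <- adjust_onef(grid, pw * 5 * grid^-0.7)
  expect_equal(a2$adjusted / a2$fitted, a1$adjusted / a1$fitted,
               tolerance = 1e-8)
  expect_equal(a2$slope, a1$slope - 0.7, tolerance = 1e-8)
})

test_that("band powers integrate the adjusted spectrum over closed bands", {
  grid <- seq(2, 48, by = 0.25)
  a <- adjust_onef(grid, grid^-1)
  a$adjusted <- rep(0, length(grid))
  expect_equal(unname(band_power(a)), rep(0, 4))
  # unit bump wholly inside theta
  a$adjusted <- ifelse(grid >= 4 & grid <= 6, 1, 0)
  bp <- band_power(a)
  expect_gt(bp[["theta"]], 0)
  expect_equal(unname(bp[c("alpha", "beta", "gamma")]), rep(0, 3))
  expect_error(band_power(a, data.frame(name = "x", low = 100, high = 120)),
               "empty")
})

test_that("peak gamma uses the 35-45 window with a lower tie-break", {
  grid <- seq(30, 50, by = 0.25)
  a <- list(grid = grid, adjusted = dnorm(grid, 40, 2))
  expect_equal(peak_gamma(a), 40)
  a$adjusted <- dnorm(grid, 39.5, 2)
  expect_equal(peak_gamma(a), 39.5)
  a$adjusted <- ifelse(grid %in% c(38, 42), 1, 0)
  expect_equal(peak_gamma(a), 38)
  expect_error(peak_gamma(a, c(100, 110)), "outside")
})

test_that("time-frequency power is baseline-normalized exactly", {
  dt <- 2
  t_ms <- seq(-200, 600, by = dt)
  set.seed(1)
  x <- sin(2 * pi * 40 * t_ms / 1000) * (t_ms > 0) + rnorm(length(t_ms), 0, 0.05)
  tf <- time_frequency_power(x, t_ms, freqs = seq(30, 50, 2),
                             baseline = c(-200, -10), stim_onset_ms = 0)
  bsel <- t_ms >= -200 & t_ms <= -10
  expect_equal(unname(rowMeans(tf$power[, bsel])), rep(1, nrow(tf$power)))
  post <- t_ms > 100 & t_ms < 500
  hot <- which.max(rowMeans(tf$power[, post]))
  expect_equal(tf$freqs[hot], 40)
  expect_error(time_frequency_power(x, t_ms, 40, baseline = c(-10, 50),
                                    stim_onset_ms = 0), "baseline")
})

test_that("pure noise gives a flat normalized time-frequency map", {
  set.seed(2)
  t_ms <- seq(-200, 400, by = 2)
  x <- matrix(rnorm(length(t_ms) * 20), length(t_ms), 20)
  tf <- time_frequency_power(x, t_ms, freqs = c(20, 40),
                             baseline = c(-200, -10), stim_onset_ms = 0)
  expect_lt(max(abs(tf$power - 1)), 1)
  expect_lt(abs(mean(tf$power) - 1), 0.1)
})

test_that("mismatch waves difference, locate and antisymmetrize correctly", {
  t_ms <- seq(0, 400, by = 2)
  s <- dnorm(t_ms, 180, 30)
  d <- 1.5 * dnorm(t_ms, 200, 30)
  mw <- mismatch_wave(s, d, t_ms, window = c(150, 250))
  expect_equal(mw$difference, d - s)
  expect_gte(mw$latency_ms, 150); expect_lte(mw$latency_ms, 250)
  mw0 <- mismatch_wave(s, s, t_ms)
  expect_equal(mw0$amplitude, 0)
  swap <- mismatch_wave(d, s, t_ms)
  expect_equal(swap$difference, -mw$difference)
  expect_error(mismatch_wave(s, d[-1], t_ms[-1]), "length")
})
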