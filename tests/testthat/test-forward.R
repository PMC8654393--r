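test_that("gaussian bump input has the documented shape", {
  grid <- default_grid("assr")
  expect_error(gaussian_bump_input(40, 0, 1, grid), "width")
  b <- gaussian_bump_input(40, 4, 1, grid, floor = 0)
  expect_equal(grid[which.max(b$density)], 40)
  # value one width from the center is exp(-1/2) of the peak
  expect_equal(b$density[grid == 44] / b$density[grid == 40], exp(-0.5))
  # the wider bump holds relatively more power at 44 Hz
  b1 <- gaussian_bump_input(40, 1, 1, grid, floor = 0)
  expect_gt(b$density[grid == 44] / b$density[grid == 40],
            b1$density[grid == 44] / b1$density[grid == 40])
  expect_true(all(gaussian_bump_input(40, 4, 1, grid)$density > 0))
})

test_that("transfer function is low-pass and flags unstable fixed points", {
  net <- single_column_network()
  H <- transfer_function(net, c(10, 500, 2000))
  expect_lt(Mod(H[3, 1]), Mod(H[1, 1]) / 50)
  # removing the self-inhibition loops destabilizes the column
  net2 <- apply_deltas(net, c("ctx:G:ss_ss" = -6, "ctx:G:sp_sp" = -6,
                              "ctx:G:ii_ii" = -6, "ctx:G:dp_dp" = -6))
  expect_error(transfer_function(net2, c(10, 20)), "unstable|not converge")
})

test_that("engine transfer matches the closed-form one-population resonance", {
  # single second-order population: dv = i, di = -2k i - k^2 v + k u
  # => H(w) = k / (iw + k)^2 at unit observation
  kap <- 1 / 0.01
  A0 <- rbind(c(0, 1), c(-kap^2, -2 * kap))
  B <- matrix(c(0, kap), 2, 1)
  C <- matrix(c(1, 0), 1, 2)
  zero <- matrix(0, 2, 2)
  w <- 2 * pi * c(5, 15, 40)
  H <- cpp_transfer(A0, zero, zero, 0, 0, B, C, w)
  Hexp <- kap / (1i * w + kap)^2
  expect_equal(as.vector(H[1, 1, ]), Hexp, tolerance = 1e-10)
})

test_that("a pure transmission delay changes phase, not gain", {
  kap <- 1 / 0.01
  blk <- rbind(c(0, 1), c(-kap^2, -2 * kap))
  zero4 <- matrix(0, 4, 4)
  A0 <- zero4; A0[1:2, 1:2] <- blk; A0[3:4, 3:4] <- blk
  Ae <- zero4; Ae[4, 1] <- 50 * kap   # population 1 -> population 2, delayed
  B <- matrix(c(0, kap, 0, 0), 4, 1)
  C <- matrix(c(0, 0, 1, 0), 1, 4)    # observe the downstream population
  w <- 2 * pi * c(5, 20, 45)
  H0 <- cpp_transfer(A0, zero4, Ae, 0, 0, B, C, w)
  H1 <- cpp_transfer(A0, zero4, Ae, 0, 0.010, B, C, w)
  expect_equal(Mod(H1[1, 1, ]), Mod(H0[1, 1, ]), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(Arg(H1[1, 1, ]), Arg(H0[1, 1, ]))))
})

test_that("predicted cross-spectra satisfy the Hermitian PSD invariants", {
  grid <- seq(30, 50, by = 1)
  set.seed(7)
  for (rep in 1:8) {
    net <- apply_deltas(assr_network(), assr_operating_deltas())
    nudge <- rnorm(4, 0, 0.2)
    net <- apply_deltas(net, setNames(
      nudge, c("L_A1:G:sp_sp", "R_A1:G:sp_sp", "L_A1:G:sp_ii", "R_A1:G:ii_sp")))
    cs <- predict_csd(net, gaussian_bump_input(40, 4, 1e-3, grid),
                      noise_model(channel_white = 1e-10,
                                  source_white = 1e-10), grid)
    expect_true(isTRUE(check_cross_spectrum(cs)))
  }
})

test_that("with no input and no source noise the CSD is the channel noise", {
  grid <- seq(30, 50, by = 1)
  nm <- noise_model(channel_white = 3e-9, channel_pink = 1e-9)
  cs <- predict_csd(assr_network(), gaussian_bump_input(40, 4, 0, grid,
                                                        floor = 0), nm, grid)
  for (k in seq_along(grid)) {
    S <- matrix(cs$csd[, , k], 2, 2)
    expect_equal(Re(diag(S)), rep(3e-9 + 1e-9 / grid[k], 2))
    expect_equal(S[1, 2], 0 + 0i)
  }
})

test_that("the steady-state model peaks in the gamma band under 40-Hz drive", {
  grid <- default_grid("assr")
  net <- apply_deltas(assr_network(), assr_operating_deltas())
  cs <- predict_csd(net, gaussian_bump_input(40, 4, 1e-3, grid),
                    noise_model(channel_white = 1e-12), grid)
  pk <- grid[which.max(Re(cs$csd[1, 1, ]))]
  expect_gte(pk, 35); expect_lte(pk, 45)
})

test_that("time-domain integration is deterministic and respects equilibria", {
  net <- single_column_network()
  st <- fixed_point(net)
  drv <- rep(0, 2001)
  r1 <- integrate_time_domain(net, drv, dt_ms = 0.1, init = st)
  r2 <- integrate_time_domain(net, drv, dt_ms = 0.1, init = st)
  expect_identical(r1$obs, r2$obs)
  expect_lt(max(abs(r1$obs)), 1e-10)
})

test_that("small sinusoidal drive reproduces the linear transfer gain", {
  net <- single_column_network()
  f0 <- 40
  H <- transfer_function(net, f0)
  dt <- 5e-4
  tt <- seq(0, 3, by = dt)
  r <- integrate_time_domain(net, 0.01 * sin(2 * pi * f0 * tt),
                             dt_ms = dt * 1e3)
  sel <- r$time_ms > 2000
  amp <- (max(r$obs[sel, 1]) - min(r$obs[sel, 1])) / 2
  expect_equal(amp / 0.01, unname(Mod(H[1, 1])), tolerance = 0.02)
})

test_that("evoked responses behave linearly and respect condition plumbing", {
  net <- mmn_network()   # no B: conditions identical
  cfg_stim <- erp_stimulus(onset_ms = 100, duration_ms = 60, amp = 40)
  erp <- simulate_erp(net, cfg_stim, dur_ms = 350, dt_ms = 0.2, decim = 10)
  expect_equal(erp$traces$standard, erp$traces$deviant)
  # baseline flat after correction (away from the smoothed stimulus edge)
  expect_lt(max(abs(erp$traces$standard[erp$time_ms < 60, ])),
            1e-3 * max(abs(erp$traces$standard)))
  # halving the stimulus halves the response
  half <- simulate_erp(net, erp_stimulus(onset_ms = 100, duration_ms = 60,
                                         amp = 20),
                       dur_ms = 350, dt_ms = 0.2, decim = 10)
  expect_equal(2 * half$traces$standard, erp$traces$standard,
               tolerance = 0.01)
  # unknown parameters inside a condition's modulation are rejected
  net_bad <- net
  net_bad$B$deviant <- c("XX:G:sp_sp" = 1)
  expect_error(simulate_erp(net_bad, cfg_stim, dur_ms = 100), "unknown")
})

test_that("a 16-click 40-Hz train entrains the observed response near 40 Hz", {
  net <- apply_deltas(assr_network(), assr_operating_deltas())
  dt <- 0.2
  tt <- seq(0, 700, by = dt)
  drv <- click_train_drive(tt, rate_hz = 40, n_clicks = 16, onset_ms = 100,
                           amp = 30)
  r <- integrate_time_domain(net, drv, dt_ms = dt)
  x <- r$obs[r$time_ms >= 100 & r$time_ms <= 500, 1]
  x <- x - mean(x)
  n <- length(x)
  fs <- 1000 / dt
  pw <- Mod(fft(x))[1:(n / 2)]^2
  fr <- (seq_len(n / 2) - 1) * fs / n
  sel <- fr >= 20 & fr <= 60
  pk <- fr[sel][which.max(pw[sel])]
  expect_gt(pk, 35); expect_lt(pk, 45)
})

test_that("halving the integration step leaves observed traces unchanged", {
  net <- mmn_network()
  stim <- erp_stimulus(onset_ms = 50, duration_ms = 60, amp = 40)
  a <- simulate_erp(net, stim, conditions = "standard", dur_ms = 250,
                    dt_ms = 0.2, decim = 10)
  b <- simulate_erp(net, stim, conditions = "standard", dur_ms = 250,
                    dt_ms = 0.1, decim = 20)
  expect_equal(a$traces$standard, b$traces$standard,
               tolerance = 1e-4)
})
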