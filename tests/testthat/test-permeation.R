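cfg <- paper_cfg()

test_that("cumulative permeation applies the sampling-replacement correction", {
  s0 <- receptor_series("z", c(1, 2, 4), c(0, 0, 0))
  expect_equal(cumulative_permeation(s0, cfg)$Q, c(0, 0, 0))

  s1 <- receptor_series("one", 1, 1)
  expect_equal(cumulative_permeation(s1, cfg)$Q, 5 / 0.64)  # 7.8125

  s2 <- receptor_series("two", c(1, 2), c(1, 2))
  expect_equal(cumulative_permeation(s2, cfg)$Q,
               c(5 / 0.64, (5 * 2 + 0.3 * 1) / 0.64))  # 7.8125, 16.09375
})

test_that("segment fit recovers an exact line and rejects degenerate input", {
  t <- c(2, 4, 6, 8)
  prof <- structure(list(replicate = "x", times = t, Q = 2 * (t - 1)),
                    class = "permeation_profile")
  f <- fit_steady_state(prof)
  expect_equal(f$slope, 2)
  expect_equal(f$lag_time, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points, 4L)

  flat <- structure(list(replicate = "x", times = t, Q = rep(3, 4)),
                    class = "permeation_profile")
  expect_error(fit_steady_state(flat), "non-positive flux")

  zero <- structure(list(replicate = "x", times = t, Q = rep(0, 4)),
                    class = "permeation_profile")
  expect_error(fit_steady_state(zero), "no positive cumulative permeation")

  jagged <- structure(list(replicate = "x", times = t, Q = c(0, 5, 1, 6)),
                      class = "permeation_profile")
  expect_error(fit_steady_state(jagged, r2_threshold = 0.999),
               "no linear segment")
})

test_that("segment fit excludes the diffusional burn-in on a Fickian curve", {
  # short lag: the full window is above the R^2 threshold yet visibly
  # biased; backward elimination must still discard the burn-in
  tr <- truth_from_lag_flux(lag = 1.33, flux = 1.69)
  f <- fit_steady_state(simulated_profile(tr))
  expect_lt(abs(f$lag_time - tr$true_lag) / tr$true_lag, 0.10)
  expect_lt(abs(f$slope - tr$true_flux) / tr$true_flux, 0.02)

  # moderate lag within the closed-form validity band at the default
  # 8-point schedule
  tr4 <- truth_from_lag_flux(lag = 4, flux = 0.34)
  f4 <- fit_steady_state(simulated_profile(tr4))
  expect_lt(abs(f4$lag_time - 4) / 4, 0.10)
  expect_lt(abs(f4$slope - 0.34) / 0.34, 0.02)

  # long lag (8 h) requires a denser terminal schedule; the default
  # 8-point schedule leaves t = 8 h deep in the transient
  tr8 <- simulation_truth(D = 2e-5, K = 1, h = 0.031, C = 1000)
  dense_times <- c(0, 1, 2, 4, 6, 8, 12, 14, 16, 18, 20, 22, 24)
  f8 <- fit_steady_state(simulated_profile(tr8, times = dense_times))
  expect_lt(abs(f8$lag_time - tr8$true_lag) / tr8$true_lag, 0.10)
})

test_that("permeability coefficient is flux over donor concentration", {
  expect_equal(permeability_coefficient(0.34, 1000) * 1e4, 3.40)
  expect_equal(permeability_coefficient(1.69, 1000) * 1e4, 16.90)
  expect_equal(permeability_coefficient(0, 1000), 0)
  expect_error(permeability_coefficient(1, 0), "> 0")
  # linear in flux
  expect_equal(permeability_coefficient(2 * 0.34, 1000),
               2 * permeability_coefficient(0.34, 1000))
})

test_that("diffusion coefficient follows the lag-time relation", {
  expect_equal(diffusion_coefficient(0.06, 6), 1e-4)
  expect_equal(diffusion_coefficient(0.031, 4.16), 0.031^2 / (6 * 4.16))
  expect_equal(round(diffusion_coefficient(0.031, 4.16) * 1e5, 2), 3.85)
  expect_equal(round(diffusion_coefficient(0.031, 1.33) * 1e5, 3), 12.043)
  expect_error(diffusion_coefficient(0.031, 0), "positive")
  expect_error(diffusion_coefficient(0.031, -1), "positive")
})

test_that("dense-channel count tiles 1 sq.cm with nearest-integer rounding", {
  expect_equal(dense_channel_count(9267.40), 10791)
  expect_equal(dense_channel_count(8567.11), 11673)
  expect_equal(dense_channel_count(1e8), 1)
  expect_error(dense_channel_count(0), "> 0")
})

test_that("dense flux scales by the channel-count ratio", {
  expect_equal(round(dense_flux(1.69, 10791, 100), 2), 182.37)
  expect_equal(round(dense_flux(0.34, 11673, 69), 2), 57.52)
  expect_equal(dense_flux(1.69, 500, 500), 1.69)
  expect_error(dense_flux(1, 10, 0), ">= 1")
})

test_that("steady-state plasma concentration converts to ug/L and is linear in flux", {
  css8 <- steady_state_css(0.64, dense_flux(1.69, 10791, 100), 118)
  expect_lt(abs(css8 - 988.92) / 988.92, 0.005)
  css2 <- steady_state_css(0.64, dense_flux(0.34, 11673, 69), 118)
  expect_lt(abs(css2 - 311.58) / 311.58, 0.005)
  expect_equal(steady_state_css(0.64, 0, 118), 0)
  expect_equal(steady_state_css(0.64, 2 * 57.52, 118),
               2 * steady_state_css(0.64, 57.52, 118))
  expect_error(steady_state_css(0.64, 1, 0), "> 0")
})

test_that("required array area inverts the plasma-concentration extrapolation", {
  a <- required_array_area(337, 118, 182.37)
  expect_equal(a, 337 * 118 / (1000 * 182.37))
  expect_equal(round(a, 3), 0.218)
  expect_equal(required_array_area(0, 118, 182.37), 0)
  expect_equal(required_array_area(337, 118, 2 * 182.37), a / 2)
  expect_error(required_array_area(337, 118, 0), "> 0")
})

test_that("group summary averages per replicate first, with n-1 SD", {
  tr <- truth_from_lag_flux(lag = 4, flux = 0.34)
  tr2 <- truth_from_lag_flux(lag = 5, flux = 0.40)
  profs <- list(simulated_profile(tr), simulated_profile(tr2))
  profs[[1]]$replicate <- "r1"; profs[[2]]$replicate <- "r2"
  s <- summarize_group("g", profs, cfg)

  lags <- s$replicates$t_lag
  h <- cfg$skin_thickness
  # per-replicate-then-average differs from transform-of-the-mean (Jensen)
  expect_equal(s$mean$d, mean(h^2 / (6 * lags)))
  expect_equal(s$d_of_mean_lag, h^2 / (6 * mean(lags)))
  expect_gt(s$mean$d, s$d_of_mean_lag)
  expect_equal(s$sd$j_area, sd(s$replicates$j_area))

  # identical replicates give zero SD; a single replicate is flagged
  s2 <- summarize_group("g", list(profs[[1]], profs[[1]]), cfg)
  expect_equal(s2$sd$t_lag, 0)
  s1 <- summarize_group("g", profs[1], cfg)
  expect_true(s1$single_replicate)
  expect_equal(s1$sd$q24, 0)
})

test_that("dense extrapolation feeds the per-replicate Css in group summaries", {
  tr <- truth_from_lag_flux(lag = 1.33, flux = 1.69)
  prof <- simulated_profile(tr)
  s <- summarize_group("g", list(prof), cfg, n_dense = 10791, n_actual = 100)
  expect_equal(s$replicates$j_dense, s$replicates$j_area * 10791 / 100)
  expect_equal(s$replicates$css,
               1000 * 0.64 * s$replicates$j_dense / 118)
})
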