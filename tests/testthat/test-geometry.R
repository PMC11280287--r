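test_that("area fractions reproduce the published chain and saturate correctly", {
  p8 <- pore_set("50-8A", area = rep(9267.40, 10), n_expected = 100)
  a8 <- area_fractions(p8, base_side = 164.03, permeation_area = 0.64,
                       n_channels = 100)
  expect_equal(round(a8$fraction_of_permeation_area, 2), 1.45)
  expect_equal(a8$total_channel_area_cm2, 9267.40 * 100 / 1e8)
  expect_equal(round(a8$total_channel_area_cm2, 4), 0.0093)

  p2 <- pore_set("50-2A", area = rep(8567.11, 10), n_expected = 69)
  a2 <- area_fractions(p2, base_side = 162.20, permeation_area = 0.64,
                       n_channels = 69)
  expect_equal(round(a2$fraction_of_permeation_area, 2), 0.92)
  expect_equal(round(a2$total_channel_area_cm2, 4), 0.0059)

  # saturation: pores as large as the base, tiling the whole area
  side <- 100
  n <- 0.64 * 1e8 / side^2
  ps <- pore_set("sat", area = rep(side^2, 5), n_expected = n)
  asat <- area_fractions(ps, base_side = side, permeation_area = 0.64,
                         n_channels = n)
  expect_equal(asat$fraction_of_base_area, 100)
  expect_equal(asat$fraction_of_permeation_area, 100)

  expect_error(area_fractions(pore_set("e", intensity = c(1, 2)),
                              base_side = 100, permeation_area = 0.64,
                              n_channels = 10),
               "no area column")
})

test_that("permeation-area fraction is linear in channel count", {
  p <- pore_set("g", area = rep(9000, 5), n_expected = 100)
  one <- area_fractions(p, 164, 0.64, n_channels = 1)$fraction_of_permeation_area
  many <- area_fractions(p, 164, 0.64, n_channels = 37)$fraction_of_permeation_area
  expect_equal(many, 37 * one)
})

test_that("penetration efficiency is the observed/expected percentage", {
  expect_equal(penetration_efficiency(100, 100), 100)
  expect_equal(penetration_efficiency(69, 100), 69)
  expect_equal(penetration_efficiency(0, 100), 0)
  expect_warning(penetration_efficiency(110, 100), "exceeds")
  expect_error(penetration_efficiency(10, 0), ">= 1")
})

test_that("depth fraction relates channel depth to needle length", {
  expect_equal(round(depth_fraction(74.00, 393.46), 2), 18.81)
  expect_equal(round(depth_fraction(99.00, 449.82), 2), 22.01)
  expect_equal(depth_fraction(250, 250), 100)
})

test_that("uniformity summary counts zero-intensity pores within n", {
  p <- pore_set("g", intensity = c(0, 0, 10, 10))
  u <- uniformity_summary(p)
  expect_equal(u$mean, 5)
  expect_equal(u$n, 4)
  expect_equal(u$n_zero, 2)

  same <- uniformity_summary(pore_set("g", intensity = rep(7, 6)))
  expect_equal(same$sd, 0)

  expect_error(uniformity_summary(pore_set("g", area = c(1, 2))),
               "intensity")
})

test_that("uniformity summary is permutation-invariant and recovers simulated PPI", {
  set.seed(42)
  v <- rnorm(30, 50, 10)
  u1 <- uniformity_summary(pore_set("g", intensity = v))
  u2 <- uniformity_summary(pore_set("g", intensity = sample(v)))
  expect_equal(u1$mean, u2$mean)
  expect_equal(u1$sd, u2$sd)

  sim <- simulate_pores("50-8A", n_expected = 99, area_mean = 9267.4,
                        area_sd = 0, intensity_mean = 33.4,
                        intensity_sd = 14.33, seed = 7)
  u <- uniformity_summary(sim)
  se <- 14.33 / sqrt(99)
  expect_lt(abs(u$mean - 33.4), 3 * se)
})

test_that("spacing comparison distinguishes shifted groups but not identical ones", {
  same <- pore_set("a", spacing = c(500, 510, 520, 530))
  res <- compare_spacing(same, same)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)

  set.seed(11)
  a <- pore_set("a", spacing = rnorm(10, 500, 5))
  b <- pore_set("b", spacing = rnorm(10, 550, 5))  # 10 SD apart
  expect_lt(compare_spacing(a, b)$p.value, 0.001)

  deg <- pore_set("a", spacing = rep(500, 3))
  deg2 <- pore_set("b", spacing = rep(510, 3))
  expect_error(compare_spacing(deg, deg2), "zero variance")

  # the published scenario: overlapping spacing distributions are usually
  # indistinguishable
  set.seed(3)
  hits <- sum(replicate(20, {
    x <- pore_set("a", spacing = rnorm(10, 519.56, 4.93))
    y <- pore_set("b", spacing = rnorm(10, 521.59, 4.24))
    compare_spacing(x, y)$p.value < 0.05
  }))
  expect_lt(hits, 10)
})

test_that("geometry summary assembles fractions, depth and penetration efficiency", {
  p <- simulate_pores("g", n_expected = 100, area_mean = 9267.4, area_sd = 0,
                      depth_mean = 99, depth_sd = 0, intensity_mean = 33.4,
                      intensity_sd = 0, miss_rate = 0, seed = 5)
  g <- geometry_summary(p, base_side = 164.03, needle_length = 449.82,
                        permeation_area = 0.64)
  expect_equal(g$n_pores, 100)
  expect_equal(g$penetration_efficiency, 100)
  expect_equal(round(g$depth_fraction_of_length, 2), 22.01)
  expect_equal(g$intensity$mean, 33.4)
})
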