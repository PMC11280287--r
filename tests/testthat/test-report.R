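# End-to-end orchestration on a fully simulated study bundle.

make_bundle <- function(dir, noise_cv = 0, seed = 1L) {
  cfg <- paper_cfg()
  times <- paper_times()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # two microneedle groups, two replicates each, known ground truth
  truths <- list(mn_2a = truth_from_lag_flux(4.16, 0.34),
                 mn_8a = truth_from_lag_flux(1.33, 1.69))
  series <- list()
  gm <- NULL
  for (g in names(truths)) {
    for (r in 1:2) {
      id <- paste0(g, "_r", r)
      sim <- simulate_franz(truths[[g]], cfg, times, noise_cv = noise_cv,
                            replicate = id, seed = seed + r +
                              10L * match(g, names(truths)))
      series[[id]] <- sim$series
      gm <- rbind(gm, data.frame(replicate = id, group = g))
    }
  }
  write_receptor_csv(series, file.path(dir, "receptor.csv"))
  write.csv(gm, file.path(dir, "groups.csv"), row.names = FALSE)

  pores <- rbind(
    data.frame(group = "mn_2a", pore_id = 1:10, area_um2 = 8567.11,
               depth_um = 74, spacing_um = 519.56, intensity = 41.3),
    data.frame(group = "mn_8a", pore_id = 1:10, area_um2 = 9267.40,
               depth_um = 99, spacing_um = 521.59, intensity = 33.4))
  write.csv(pores, file.path(dir, "pores.csv"), row.names = FALSE)

  integ <- rbind(
    simulate_integrity("untreated", 156.25, 30.68, 4.50, cfg, seed = 1),
    simulate_integrity("mn_8a", 10, 46.85, 2.14, cfg, seed = 2))
  write.csv(integ, file.path(dir, "integrity.csv"), row.names = FALSE)

  disp <- data.frame(group = rep(c("mn_2a", "untreated"), each = 2),
                     replicate = 1:4,
                     epidermis_ug_cm2 = c(1.2, 1.3, 1.2, 1.3),
                     dermis_ug_cm2 = c(2.1, 2.2, 1.3, 1.2),
                     q24_ug_cm2 = c(6.1, 6.2, 0, 0))
  write.csv(disp, file.path(dir, "disposition.csv"), row.names = FALSE)

  x <- 10^seq(-3, 2, length.out = 21)
  rheo <- rbind(
    data.frame(kind = "amplitude", x = x, g_prime_pa = 100 / x,
               g_double_prime_pa = 100),
    data.frame(kind = "thixotropy", x = seq(0, 400, by = 10),
               g_prime_pa = rep(c(1000, 1058.5), c(11, 30)),
               g_double_prime_pa = 300))
  write.csv(rheo, file.path(dir, "rheology.csv"), row.names = FALSE)

  yaml::write_yaml(unclass(cfg), file.path(dir, "cell.yaml"))
  bundle <- list(config = file.path(dir, "cell.yaml"),
                 receptor = file.path(dir, "receptor.csv"),
                 group_map = file.path(dir, "groups.csv"),
                 pores = file.path(dir, "pores.csv"),
                 integrity = file.path(dir, "integrity.csv"),
                 disposition = file.path(dir, "disposition.csv"),
                 rheology = file.path(dir, "rheology.csv"),
                 needle = list(length_um = 449.82, base_side_um = 164.03,
                               n_needles = 100),
                 dense_extrapolate = TRUE,
                 css_target_ug_l = 337)
  yaml::write_yaml(bundle, file.path(dir, "study.yaml"))
  list(bundle = file.path(dir, "study.yaml"), truths = truths)
}

test_that("full analysis reproduces simulator truth and writes every report", {
  dir <- withr::local_tempdir()
  b <- make_bundle(file.path(dir, "in"))
  out <- file.path(dir, "out")
  res <- run_ivpt_analysis(b$bundle, out)

  files <- c("table2.csv", "per_replicate.json", "geometry.json",
             "integrity_report.json", "disposition.csv", "rheo.json",
             "manifest.json")
  expect_true(all(file.exists(file.path(out, files))))

  tab <- read.csv(file.path(out, "table2.csv"))
  for (g in names(b$truths)) {
    row <- tab[tab$group == g, ]
    expect_lt(abs(row$j_mean - b$truths[[g]]$true_flux) /
                b$truths[[g]]$true_flux, 0.02)
    expect_lt(abs(row$t_lag_mean - b$truths[[g]]$true_lag) /
                b$truths[[g]]$true_lag, 0.10)
  }
  # dense extrapolation feeds Css: mn_8a row uses the 9267.40 pore area
  row8 <- tab[tab$group == "mn_8a", ]
  jd <- row8$j_mean * dense_channel_count(9267.40) / 100
  expect_equal(row8$css_mean, steady_state_css(0.64, jd, 118),
               tolerance = 1e-10)
  expect_true(all(tab$required_area_cm2 > 0))

  rheo <- jsonlite::read_json(file.path(out, "rheo.json"))
  expect_equal(rheo$recovery_percent, 105.85)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$package, "ivptr")
  expect_length(manifest$inputs, 7L)
})

test_that("repeated runs of the same bundle give identical numeric reports", {
  dir <- withr::local_tempdir()
  b <- make_bundle(file.path(dir, "in"), noise_cv = 0.05, seed = 7L)
  run_ivpt_analysis(b$bundle, file.path(dir, "o1"))
  run_ivpt_analysis(b$bundle, file.path(dir, "o2"))
  for (f in c("table2.csv", "disposition.csv", "rheo.json", "geometry.json")) {
    expect_identical(readLines(file.path(dir, "o1", f)),
                     readLines(file.path(dir, "o2", f)))
  }
})

test_that("a failing stage names itself and leaves no partial outputs", {
  dir <- withr::local_tempdir()
  b <- make_bundle(file.path(dir, "in"))
  bl <- yaml::read_yaml(b$bundle)
  bl$pores <- NULL
  expect_error(run_ivpt_analysis(bl, file.path(dir, "bad")),
               "dense extrapolation")

  bl2 <- yaml::read_yaml(b$bundle)
  bl2$integrity <- file.path(dir, "in", "missing.csv")
  expect_error(run_ivpt_analysis(bl2, file.path(dir, "bad2")), "integrity")
  expect_false(file.exists(file.path(dir, "bad2", "table2.csv")))
})
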