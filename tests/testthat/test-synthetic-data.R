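test_that("noiseless precipitation lies exactly on the local meteoric line", {
  s <- generator_settings(seed = 5, precip_noise_sd = 0)
  p <- generate_precipitation(s)
  expect_equal(nrow(p), 26L)
  expect_equal(p$d2H_permil - 7.8 * p$d18O_permil - 12.2, rep(0, 26),
               tolerance = 1e-12)
  expect_true(all(p$d18O_permil >= -15 & p$d18O_permil <= 5))
})

test_that("default precipitation noise SD inverts the R^2 definition", {
  # independent re-derivation: R^2 = s^2 v / (s^2 v + sigma^2), v = 400/12
  sigma <- sqrt(7.8^2 * (400 / 12) * (1 / 0.963 - 1))
  expect_equal(generator_settings()$precip_noise_sd, sigma, tolerance = 1e-12)
  expect_equal(sigma, 8.8, tolerance = 0.05)
})

test_that("default precipitation recovers the reported regression", {
  fit <- fit_meteoric_line(generate_precipitation(generator_settings(seed = 1)))
  expect_equal(fit$slope, 7.8, tolerance = 0.1 * 7.8)
  expect_equal(fit$intercept, 12.2, tolerance = 4)
  expect_equal(fit$n, 26L)
  expect_error(generate_precipitation(generator_settings(n_precip_events = 0)),
               "invalid settings")
})

test_that("soil profile follows the exponential depth curve", {
  s <- generator_settings(seed = 6, soil_layer_sd_dD = 0, soil_layer_sd_d18O = 0)
  site <- ck_site()
  site$soil_surface_delta <- -70; site$soil_deep_delta <- -110
  site$profile_scale <- 45
  soil <- generate_soil_profile(site, s)
  src <- summarize_sources(soil)
  # strictly decreasing with depth when noise is zero
  expect_true(all(diff(src$mean_d2H) < 0))
  # a layer whose midpoint equals the e-folding depth sits at deep + range/e
  site$profile_scale <- 30  # midpoint of 20-40 cm
  soil2 <- generate_soil_profile(site, s)
  src2 <- summarize_sources(soil2)
  expect_equal(src2$mean_d2H[src2$layer == "20-40 cm"], -110 + 40 / exp(1),
               tolerance = 1e-10)
  # scale -> infinity: all layers at the surface value
  site$profile_scale <- 1e12
  src3 <- summarize_sources(generate_soil_profile(site, s))
  expect_equal(src3$mean_d2H, rep(-70, 8), tolerance = 1e-6)
})

test_that("the control-site profile spans roughly 30-35 permil surface to deep", {
  s <- generator_settings(seed = 7, soil_layer_sd_dD = 0, soil_layer_sd_d18O = 0)
  soil <- generate_soil_profile(ck_site(), s)
  drop <- max(soil$d2H_permil) - min(soil$d2H_permil)
  expect_gt(drop, 28)
  expect_lt(drop, 36)
})

test_that("xylem truth vectors live on the simplex with the configured main mass", {
  s <- generator_settings(seed = 8)
  src <- suppressWarnings(summarize_sources(generate_soil_profile(ck_site(), s)))
  grp <- default_depth_groups()
  for (g in c("shrub", "semi-shrub", "herb")) {
    xy <- generate_xylem(ck_site(), g, src, s)
    p <- xy$true_proportions
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  xy <- generate_xylem(ck_site(), "shrub", src, s, target = 0.523)
  expect_equal(sum(xy$true_proportions[grp[names(xy$true_proportions)] == "40-100 cm"]),
               0.523, tolerance = 1e-12)
  expect_error(generate_xylem(ck_site(), "vine", src, s), "unknown group")
})

test_that("a degenerate single-source truth reproduces that source exactly", {
  s <- generator_settings(seed = 9, xylem_residual_sd_dD = 0,
                          xylem_residual_sd_d18O = 0)
  src <- make_sources(c(-60, -90, -110), labels = c("0-20 cm", "20-40 cm", "40-100 cm"))
  grp <- c("0-20 cm" = "0-20 cm", "20-40 cm" = "20-40 cm", "40-100 cm" = "40-100 cm")
  xy <- generate_xylem(ck_site(), "herb", src, s, target = 1 - 1e-15, groups = grp)
  # essentially all mass on the shallow source
  expect_equal(unname(xy$true_proportions[1]), 1, tolerance = 1e-12)
  expect_equal(xy$samples$d2H_permil, rep(-60, nrow(xy$samples)), tolerance = 1e-9)
})

test_that("chronosequence generation is deterministic and complete", {
  d1 <- generate_chronosequence(generator_settings(seed = 10))
  d2 <- generate_chronosequence(generator_settings(seed = 10))
  expect_identical(d1, d2)
  d3 <- generate_chronosequence(generator_settings(seed = 11))
  expect_false(identical(d1$xylem, d3$xylem))

  expect_equal(length(unique(d1$sites$site_id)), 9L)
  expect_setequal(unique(d1$soil$site_id), d1$sites$site_id)
  # semi-shrubs present only in the documented subset
  semi_sites <- unique(d1$truth$site_id[d1$truth$group == "semi-shrub"])
  expect_setequal(semi_sites, c("1995a", "2009a", "2015a", "2020a", "CK"))
  # delta sanity envelope
  for (tab in list(d1$precipitation, d1$soil, d1$xylem)) {
    expect_true(all(tab$d2H_permil > -200 & tab$d2H_permil < 50))
    expect_true(all(tab$d18O_permil > -200 & tab$d18O_permil < 50))
  }
})

test_that("true shrub deep-water shares correlate with restoration age as designed", {
  d <- generate_chronosequence(generator_settings(seed = 12))
  tr <- d$truth[d$truth$group == "shrub" & !d$truth$is_control, ]
  r <- cor(tr$restoration_age, tr$true_main_pct)
  expect_equal(r, 0.862, tolerance = 0.01)
})

test_that("generator settings validate their invariants", {
  expect_error(generator_settings(precip_noise_sd = -1), "SDs")
  expect_error(generator_settings(n_precip_events = 2), "n_precip_events")
  expect_error(generator_settings(n_replicates = 0), "n_replicates")
})
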