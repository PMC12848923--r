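test_that("a single candidate source short-circuits to proportion 1", {
  src <- make_sources(-85)
  post <- run_mixing(make_mixture(c(-85, -84)), src,
                     mixing_config(iterations = 1000, burn_in = 500))
  expect_true(all(post$draws == 1))
  expect_equal(ncol(post$draws), 1L)
})

test_that("two symmetric sources with a midpoint mixture split 50/50", {
  src <- make_sources(c(-60, -110))
  mix <- make_mixture(rep(-85, 3))
  post <- suppressWarnings(run_mixing(mix, src, fast_mixing(seed = 2)))
  sm <- summarize_posterior(post)
  expect_equal(sm$mean_pct, c(50, 50), tolerance = 4)
  expect_true(all(abs(rowSums(post$draws) - 1) < 1e-9))
})

test_that("MCMC posterior matches a dense grid oracle on a 2-source problem", {
  # single isotope, fixed residual SD: posterior density over p computable
  # by direct normalization of prior x likelihood on a fine grid
  mu <- c(-60, -110)
  y <- c(-75, -73, -78)
  sigma <- 2
  grid <- seq(5e-4, 1 - 5e-4, by = 1e-3)
  log_dens <- vapply(grid, function(p) {
    sum(dnorm(y, p * mu[1] + (1 - p) * mu[2], sigma, log = TRUE))
  }, numeric(1))
  dens <- exp(log_dens - max(log_dens)); dens <- dens / sum(dens)

  src <- make_sources(mu)
  cfg <- mixing_config(iterations = 15000, burn_in = 5000, thin = 2,
                       seed = 3, residual_sd_fixed = sigma, isotopes = "d2H")
  post <- run_mixing(make_mixture(y), src, cfg)
  draws <- post$draws[, 1]

  breaks <- seq(0, 1, length.out = 16)
  mcmc_bin <- table(cut(draws, breaks)) / length(draws)
  grid_bin <- tapply(dens, cut(grid, breaks), sum)
  grid_bin[is.na(grid_bin)] <- 0
  tv <- 0.5 * sum(abs(as.numeric(mcmc_bin) - as.numeric(grid_bin)))
  expect_lt(tv, 0.05)
})

test_that("with no data the posterior reproduces the Dirichlet prior", {
  src <- make_sources(c(-60, -85, -110))
  post <- run_mixing(make_mixture(numeric(0)), src, fast_mixing(seed = 4),
                     prior_only = TRUE)
  # Dirichlet(1,1,1): mean 1/3, var = 2/(9*4) = 1/18 per component
  expect_equal(colMeans(post$draws), rep(1 / 3, 3), tolerance = 0.03,
               ignore_attr = TRUE)
  expect_equal(apply(post$draws, 2, var), rep(1 / 18, 3), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("permuting source order permutes the posterior summaries identically", {
  src <- make_sources(c(-65, -90, -108))
  mix <- make_mixture(c(-80, -81, -79))
  post1 <- suppressWarnings(run_mixing(mix, src, fast_mixing(seed = 5)))
  post2 <- suppressWarnings(run_mixing(mix, src[c(3, 1, 2), ], fast_mixing(seed = 5)))
  sm1 <- summarize_posterior(post1)
  sm2 <- summarize_posterior(post2)
  m2 <- sm2$mean_pct[match(sm1$source, sm2$source)]
  expect_equal(sm1$mean_pct, m2, tolerance = 2.5)
})

test_that("layer aggregation sums member proportions per draw", {
  draws <- matrix(c(0.1, 0.1, 0.3, 0.2, 0.3,
                    0.2, 0.2, 0.2, 0.2, 0.2), 2, byrow = TRUE,
                  dimnames = list(NULL, paste0("L", 1:5)))
  post <- fake_posterior(rbind(draws, draws))
  agg <- aggregate_layers(post, c(L1 = "A", L2 = "A", L3 = "B", L4 = "C", L5 = "C"))
  expect_equal(unname(agg$draws[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(agg$draws[2, ]), c(0.4, 0.2, 0.4))
  # identity grouping leaves draws unchanged
  ident <- aggregate_layers(post, setNames(paste0("L", 1:5), paste0("L", 1:5)))
  expect_equal(ident$draws, post$draws)
  # collapsing everything conserves total mass
  all_one <- aggregate_layers(post, setNames(rep("all", 5), paste0("L", 1:5)))
  expect_equal(unname(all_one$draws[, 1]), rep(1, 4))
  expect_error(aggregate_layers(post, c(L1 = "A")), "mapping error")
})

test_that("posterior summaries report percent mean/SD/CI and enforce draw count", {
  const <- fake_posterior(matrix(0.5, 200, 2, dimnames = list(NULL, c("a", "b"))))
  sm <- summarize_posterior(const)
  expect_equal(sm$mean_pct, c(50, 50))
  expect_equal(sm$sd_pct, c(0, 0))
  expect_equal(sm$ci_low_pct, c(50, 50))
  expect_equal(sm$ci_high_pct, c(50, 50))
  few <- fake_posterior(matrix(0.5, 50, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(summarize_posterior(few), "insufficient sampling")
})

test_that("degenerate and ill-posed inputs raise the documented conditions", {
  src0 <- make_sources(c(-60, -90))[0, ]
  expect_error(run_mixing(make_mixture(-80), src0, fast_mixing()), "no sources")
  expect_error(run_mixing(make_mixture(numeric(0)), make_sources(c(-60, -90)),
                          fast_mixing()), "empty")
  twin <- make_sources(c(-80, -80.01))
  expect_warning(run_mixing(make_mixture(c(-80, -80)), twin,
                            mixing_config(iterations = 600, burn_in = 300,
                                          thin = 3, seed = 6)),
                 "near-identical")
})

test_that("simplex conservation holds for every retained draw, raw and aggregated", {
  s <- generator_settings(seed = 13)
  src <- suppressWarnings(summarize_sources(generate_soil_profile(ck_site(), s)))
  xy <- generate_xylem(ck_site(), "shrub", src, s)
  post <- suppressWarnings(run_mixing(xy$samples[1:3, ], src, fast_mixing(seed = 7)))
  expect_true(all(post$draws >= 0))
  expect_true(all(abs(rowSums(post$draws) - 1) < 1e-9))
  agg <- aggregate_layers(post)
  expect_true(all(abs(rowSums(agg$draws) - 1) < 1e-9))
  expect_equal(nrow(post$draws), 3 * (6000 - 3000) / 3)
})

test_that("recovery harness reports near-zero bias in the identifiable noiseless limit", {
  # two well-separated sources and noiseless xylem: the posterior must
  # concentrate at the injected truth (the mixing system is square here)
  s <- generator_settings(seed = 14, soil_layer_sd_dD = 0.2,
                          soil_layer_sd_d18O = 0.05,
                          xylem_residual_sd_dD = 0, xylem_residual_sd_d18O = 0)
  scheme2 <- data.frame(layer = c("0-20 cm", "20-150 cm"),
                        depth_top_cm = c(0, 20), depth_bottom_cm = c(20, 150),
                        stringsAsFactors = FALSE)
  grouping2 <- c("0-20 cm" = "0-20 cm", "20-150 cm" = "40-100 cm")
  rep <- suppressWarnings(recovery_experiment(
    s, n_repeats = 2, groups = "shrub",
    config = fast_mixing(seed = 8),
    scheme = scheme2, grouping = grouping2))
  expect_equal(nrow(rep), 1L)
  expect_lt(abs(rep$bias_pct), 2)
  expect_true(all(c("bias_pct", "rmse_pct", "coverage_pct") %in% names(rep)))
})

test_that("recovery harness tracks coverage under default noise on the full scheme", {
  s <- generator_settings(seed = 15)
  rep <- suppressWarnings(recovery_experiment(
    s, n_repeats = 3, groups = "shrub",
    config = mixing_config(iterations = 3000L, burn_in = 1500L, thin = 3L,
                           seed = 9)))
  expect_true(rep$coverage_pct >= 0 && rep$coverage_pct <= 100)
  expect_true(is.finite(rep$rmse_pct) && rep$rmse_pct > 0)
})
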