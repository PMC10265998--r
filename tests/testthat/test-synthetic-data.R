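test_that("identical seeds give bit-identical datasets", {
  cfg <- scenario_config("subestuary", seed = 42, n_sites = 8, n_years = 10)
  s1 <- generate_subestuary_scenario(cfg)
  s2 <- generate_subestuary_scenario(cfg)
  expect_identical(s1$beds, s2$beds)
  expect_identical(s1$drivers, s2$drivers)
  expect_identical(s1$analysis, s2$analysis)
  s3 <- generate_subestuary_scenario(
    scenario_config("subestuary", seed = 43, n_sites = 8, n_years = 10))
  expect_false(identical(s1$analysis$change, s3$analysis$change))
})

test_that("the null configuration produces white-noise change", {
  cfg <- scenario_config("subestuary", seed = 17, n_sites = 200,
                         n_years = 5,
                         path_coefficients = setNames(numeric(0),
                                                      character(0)),
                         random_intercept_sd = 0, ar1_phi = 0,
                         residual_sd = 0.1, zero_threshold = 0)
  sim <- generate_subestuary_scenario(cfg)
  ch <- sim$analysis$change[!is.na(sim$analysis$change)]
  expect_gte(length(ch), 500)
  expect_equal(sd(ch), 0.1, tolerance = 0.05)
  expect_lt(abs(cor(ch[-1], ch[-length(ch)])), 0.1)
})

test_that("configured path signs surface in the generated data", {
  cfg <- scenario_config(
    "subestuary", seed = 5, n_sites = 40, n_years = 30,
    path_coefficients = c("nonpoint_N->change" = -0.05),
    zero_threshold = 0, residual_sd = 0.05)
  sim <- generate_subestuary_scenario(cfg)
  d <- dplyr::filter(sim$analysis, !is.na(change))
  expect_gte(nrow(d), 1000)
  expect_lt(cor(d$nonpoint_N, d$change), 0)

  cfgm <- scenario_config(
    "mainchannel", seed = 6, n_sites = 40, n_years = 30,
    skip_years = integer(0),
    path_coefficients = c("salinity->change" = 0.06),
    zero_threshold = 0, residual_sd = 0.05)
  simm <- generate_main_channel_scenario(cfgm)
  dm <- dplyr::filter(simm$analysis, !is.na(change))
  expect_gt(coef(lm(change ~ salinity, dm))[2], 0)
})

test_that("the zero floor and clipping keep cover in bounds", {
  cfg <- scenario_config("subestuary", seed = 9, n_sites = 10,
                         n_years = 12, zero_threshold = 1)
  sim <- generate_subestuary_scenario(cfg)
  expect_true(all(sim$analysis$cover == 0)) # degenerate floor
  expect_true(all(sim$beds$area_ha == 0))

  cfg2 <- scenario_config("subestuary", seed = 9, n_sites = 10,
                          n_years = 20)
  sim2 <- generate_subestuary_scenario(cfg2)
  expect_true(all(sim2$analysis$cover >= 0 & sim2$analysis$cover <= 1))
  # boom-bust defaults must exercise the 3-zero filter downstream
  cs <- build_cover_series(sim2$beds)
  expect_gt(sum(cs$filtered), 0)
})

test_that("invalid configurations are refused", {
  expect_error(scenario_config("subestuary", n_sites = 1), "n_sites")
  expect_error(scenario_config("subestuary", n_years = 3), "n_years")
  expect_error(scenario_config("subestuary", ar1_phi = 1), "ar1_phi")
  expect_error(scenario_config("subestuary", residual_sd = 0),
               "residual_sd")
  expect_error(
    scenario_config("subestuary",
                    path_coefficients = c("salinity->change" = 0.2)),
    "allowed")
  expect_error(
    scenario_config("mainchannel",
                    path_coefficients = c("flow->change" = 0.2)),
    "allowed")
  expect_error(
    scenario_config("subestuary",
                    lag_interaction_coefficients = c(chla = 0.1)),
    "drivers of change")
})

test_that("the main-channel default layout skips the 1988 survey", {
  cfg <- scenario_config("mainchannel", seed = 2)
  expect_equal(cfg$n_sites, 51)
  sim <- generate_main_channel_scenario(cfg)
  yrs <- sort(unique(sim$beds$year))
  expect_equal(length(yrs), 35) # 1984-2019 minus 1988
  expect_false(1988 %in% yrs)
  expect_true(all(is.na(
    sim$analysis$change[sim$analysis$year == 1989])))
})

test_that("bed observations reconstruct the generated cover", {
  cfg <- scenario_config("subestuary", seed = 30, n_sites = 6,
                         n_years = 10)
  sim <- generate_subestuary_scenario(cfg)
  dw <- density_weighted_cover(sim$beds$area_ha, sim$beds$density)
  expect_equal(dw, sim$analysis$cover * cfg$site_area_ha,
               tolerance = 1e-10)
})

test_that("the mixed-model harness matches its stated moments", {
  d <- simulate_lmm_dataset(50, 20, beta = c(0.8, -0.5), phi = 0.4,
                            sigma_b = 0.3, sigma = 1, seed = 100)
  expect_equal(nrow(d), 1000)
  expect_identical(d, simulate_lmm_dataset(50, 20, beta = c(0.8, -0.5),
                                           phi = 0.4, sigma_b = 0.3,
                                           sigma = 1, seed = 100))
  resid <- d$y - 0.8 * d$x1 + 0.5 * d$x2
  expect_equal(sd(resid), sqrt(1 + 0.3^2), tolerance = 0.1)
})

test_that("piecewise SEM recovers generating coefficients under gentle dynamics", {
  # gentle annual steps and no zero floor keep the [0,1] clipping rare,
  # so the latent linear structure is observable
  graph <- causal_graph(rbind(
    c("frac_agriculture", "nonpoint_N"), c("flow", "nonpoint_N"),
    c("nonpoint_N", "change"), c("flow", "change")), group = "site_id")
  paths <- c("frac_agriculture->nonpoint_N" = 0.5, "flow->nonpoint_N" = 0.4,
             "nonpoint_N->change" = -0.02, "flow->change" = -0.015)
  # drivers are generated with unit variance, so the generating raw
  # coefficients are the standardized effects up to the realized
  # response scale; checking the 95% CI on the estimation scale checks
  # the standardized recovery without adding sample-SD jitter
  n_rep <- 100
  hits <- matrix(0L, n_rep, 4,
                 dimnames = list(NULL, names(paths)))
  for (r in seq_len(n_rep)) {
    cfg <- scenario_config("subestuary", seed = 5000 + r, n_sites = 30,
                           n_years = 30, path_coefficients = paths,
                           residual_sd = 0.02, random_intercept_sd = 0.003,
                           ar1_phi = 0.3, zero_threshold = 0)
    sim <- generate_subestuary_scenario(cfg)
    d <- dplyr::filter(sim$analysis, !is.na(change))
    fit <- fit_sem(graph, d)
    td <- tidy(fit)
    for (key in names(paths)) {
      parts <- strsplit(key, "->", fixed = TRUE)[[1]]
      row <- td[td$equation == parts[2] & td$term == parts[1], ]
      tcrit <- qt(0.975, fit$equations[[parts[2]]]$df_resid)
      lo <- row$estimate - tcrit * row$std.error
      hi <- row$estimate + tcrit * row$std.error
      hits[r, key] <- as.integer(paths[[key]] >= lo & paths[[key]] <= hi)
    }
  }
  coverage <- colMeans(hits)
  expect_true(all(coverage >= 0.9),
              info = paste(names(paths), round(coverage, 2),
                           collapse = "; "))
})
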