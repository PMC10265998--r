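test_that("with no random intercept and no correlation the fit is OLS", {
  d <- simulate_lmm_dataset(8, 10, beta = c(0.8, -0.5), seed = 42)
  fit <- fit_lmm(d, "y", c("x1", "x2"), group = "site", time = "year",
                 correlation = "none", random_intercept = FALSE)
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  # ML deviance equals the OLS deviance (sigma2 = RSS / n)
  n <- nrow(d)
  s2 <- sum(resid(ols)^2) / n
  ll_ols <- -0.5 * n * (log(2 * pi * s2) + 1)
  expect_equal(fit$loglik, ll_ols, tolerance = 1e-6)
})

test_that("a single-group intercept-only model returns the sample mean", {
  d <- tibble::tibble(site = "only", year = 1:12, y = rnorm(12, 3))
  fit <- fit_lmm(d, "y", character(), group = "site", time = "year",
                 correlation = "none")
  expect_equal(unname(fit$coefficients), mean(d$y))
  expect_equal(fit$sigma_b2, 0) # no random intercept with one group
})

test_that("estimates agree with the nlme reference implementation", {
  skip_if_not_installed("nlme")
  d <- simulate_lmm_dataset(20, 15, beta = c(0.8, -0.5), intercept = 1,
                            phi = 0.4, sigma_b = 0.3, sigma = 0.5,
                            seed = 7)
  d2 <- d[!(d$year == 8 | (d$site == "g001" & d$year > 12)), ]
  fit <- fit_lmm(d2, "y", c("x1", "x2"), group = "site", time = "year")
  ref <- nlme::lme(y ~ x1 + x2, random = ~1 | site,
                   correlation = nlme::corAR1(form = ~year | site),
                   data = d2, method = "ML")
  expect_equal(unname(fit$coefficients), unname(nlme::fixef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$phi,
               as.numeric(coef(ref$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(fit$sigma2, ref$sigma^2, tolerance = 1e-3)
})

test_that("richer covariance structures never lose log-likelihood", {
  d <- simulate_lmm_dataset(15, 12, beta = 0.6, phi = 0.5, sigma_b = 0.2,
                            seed = 3)
  full <- fit_lmm(d, "y", "x1", group = "site", time = "year")
  no_ar <- fit_lmm(d, "y", "x1", group = "site", time = "year",
                   correlation = "none")
  no_re <- fit_lmm(d, "y", "x1", group = "site", time = "year",
                   random_intercept = FALSE)
  expect_gte(full$loglik, no_ar$loglik - 1e-6)
  expect_gte(full$loglik, no_re$loglik - 1e-6)
  expect_true(abs(full$phi) < 1)
  expect_gte(full$sigma_b2, 0)
  expect_true(all(full$p_values >= 0 & full$p_values <= 1))
  expect_lte(full$r2_marginal, full$r2_conditional)
})

test_that("fits are invariant to group relabeling and predictor units", {
  d <- simulate_lmm_dataset(10, 10, beta = c(0.7, -0.3), phi = 0.3,
                            sigma_b = 0.2, seed = 12)
  base <- fit_lmm(d, "y", c("x1", "x2"), group = "site", time = "year")
  relab <- d
  relab$site <- factor(relab$site,
                       labels = rev(sprintf("new%02d", 1:10)))
  f2 <- fit_lmm(relab, "y", c("x1", "x2"), group = "site", time = "year")
  expect_equal(f2$coefficients, base$coefficients, tolerance = 1e-6)
  expect_equal(f2$loglik, base$loglik, tolerance = 1e-6)

  reunit <- d
  reunit$x1 <- d$x1 * 1000 # e.g. kg -> g
  f3 <- fit_lmm(reunit, "y", c("x1", "x2"), group = "site", time = "year")
  expect_equal(unname(f3$coefficients["x1"] * 1000),
               unname(base$coefficients["x1"]), tolerance = 1e-6)
  std_base <- standardize_coefficients(base)
  std3 <- standardize_coefficients(f3)
  expect_equal(std3$std_estimate, std_base$std_estimate, tolerance = 1e-6)
})

test_that("standardization scales by predictor and response SDs", {
  d <- simulate_lmm_dataset(10, 10, beta = c(0.6, 0.2), seed = 5)
  d$y <- d$y / sd(d$y)
  d$x1 <- d$x1 / sd(d$x1)
  d$x2 <- d$x2 / sd(d$x2)
  fit <- fit_lmm(d, "y", c("x1", "x2"), group = "site", time = "year",
                 correlation = "none", random_intercept = FALSE)
  std <- standardize_coefficients(fit)
  expect_equal(std$std_estimate[std$term == "x1"],
               unname(fit$coefficients["x1"]), tolerance = 1e-10)
  # interaction terms standardize via the realized product column
  fit2 <- fit_lmm(d, "y", c("x1", "x2", "x1:x2"), group = "site",
                  time = "year", correlation = "none")
  std2 <- standardize_coefficients(fit2)
  prod_sd <- sd(d$x1 * d$x2)
  i <- std2$term == "x1:x2"
  expect_equal(std2$std_estimate[i], std2$estimate[i] * prod_sd / sd(d$y),
               tolerance = 1e-10)
  dz <- d
  dz$x2 <- 1 # zero variance in fresh data
  expect_error(standardize_coefficients(fit2, data = dz), "x2")
})

test_that("variance-partition R2 behaves at its edges and recovers shares", {
  d <- simulate_lmm_dataset(10, 10, beta = 0.5, sigma_b = 0.3, seed = 6)
  null <- fit_lmm(d, "y", character(), group = "site", time = "year")
  expect_equal(unname(r2_nakagawa(null)["r2_marginal"]), 0)
  no_re <- fit_lmm(d, "y", "x1", group = "site", time = "year",
                   random_intercept = FALSE)
  r <- r2_nakagawa(no_re)
  expect_equal(unname(r["r2_marginal"]), unname(r["r2_conditional"]))

  # target partition (fixed, intercept, residual) = (0.5, 0.25, 0.25)
  d2 <- simulate_lmm_dataset(60, 30, beta = sqrt(0.5), sigma_b = 0.5,
                             sigma = 0.5, seed = 31)
  fit2 <- fit_lmm(d2, "y", "x1", group = "site", time = "year")
  r2 <- r2_nakagawa(fit2)
  expect_equal(unname(r2["r2_marginal"]), 0.5, tolerance = 0.07)
  expect_equal(unname(r2["r2_conditional"]), 0.75, tolerance = 0.07)
})

test_that("residual autocorrelation is seen raw and removed by whitening", {
  d <- simulate_lmm_dataset(40, 25, beta = 0.5, phi = 0.6, sigma_b = 0,
                            seed = 19)
  naive <- fit_lmm(d, "y", "x1", group = "site", time = "year",
                   correlation = "none", random_intercept = FALSE)
  raw <- residual_lag_correlation(naive, max_lag = 3, type = "raw")
  expect_equal(raw$correlation[1], 0.6, tolerance = 0.08)
  whitened <- residual_lag_correlation(
    fit_lmm(d, "y", "x1", group = "site", time = "year"), max_lag = 3)
  expect_lt(abs(whitened$correlation[1]), 2 / sqrt(whitened$n_pairs[1]) + 0.02)
  expect_error(residual_lag_correlation(naive, max_lag = 30), "span")
})

test_that("invalid inputs fail loudly", {
  d <- simulate_lmm_dataset(5, 6, beta = 0.5, seed = 2)
  d$x1[3] <- NA
  expect_error(fit_lmm(d, "y", "x1", group = "site", time = "year"),
               "non-finite")
  d2 <- simulate_lmm_dataset(5, 6, beta = 0.5, seed = 2)
  expect_error(fit_lmm(d2, "y", "y", group = "site", time = "year"),
               "response")
  d3 <- d2
  d3$year[2] <- d3$year[1]
  expect_error(fit_lmm(d3, "y", "x1", group = "site", time = "year"),
               "duplicate time")
})
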