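test_that("fit_distribution matches the requested moments", {
  # zero variance: point mass
  pt <- fit_distribution(0.11, 0)
  expect_equal(pt$family, "point")
  expect_equal(rdist(pt, 5), rep(0.11, 5))

  # lognormal moment matching: population moments are exact
  ln <- fit_distribution(0.24, 0.05)
  m <- exp(ln$params$meanlog + ln$params$sdlog^2 / 2)
  v <- (exp(ln$params$sdlog^2) - 1) * m^2
  expect_equal(m, 0.24)
  expect_equal(sqrt(v), 0.05)

  # ... and the sample mean of many draws is within 1%
  set.seed(42)
  expect_equal(mean(rdist(ln, 1e6)), 0.24, tolerance = 0.01)

  # truncated normal: all draws non-negative
  tn <- fit_distribution(0.11, 0.03, "normal_truncated")
  set.seed(42)
  expect_true(all(rdist(tn, 1e4) >= 0))
  # heavy truncation still yields non-negative draws
  tn2 <- fit_distribution(0.01, 0.05, "normal_truncated")
  set.seed(42)
  expect_true(all(rdist(tn2, 1e4) >= 0))

  expect_error(fit_distribution(0.1, -0.01), "non-negative")
  expect_error(fit_distribution(0, 0.05), "> 0")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  specs <- list(As = fit_distribution(0.11, 0.03),
                Pb = fit_distribution(0.24, 0.05))
  a <- simulate_tcr(specs, n_draws = 500, seed = 9)
  b <- simulate_tcr(specs, n_draws = 500, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_identical(a$exceedance_probability, b$exceedance_probability)
  c <- simulate_tcr(specs, n_draws = 500, seed = 10)
  expect_false(identical(a$draws, c$draws))
})

test_that("degenerate distributions give step-function exceedance", {
  tox <- toxicity_params()
  below <- list(As = fit_distribution(0.11, 0), Pb = fit_distribution(0.24, 0))
  sim <- simulate_tcr(below, n_draws = 100, seed = 1, threshold = 1e-4)
  expect_equal(sim$exceedance_probability, 0)
  expect_equal(sim$mc_se, 0)

  det <- as.numeric(total_cancer_risk(c(
    as.numeric(cancer_risk(edi(0.11, "As"), tox$CSF[["As"]])),
    as.numeric(cancer_risk(edi(0.24, "Pb"), tox$CSF[["Pb"]])))))
  sim_hi <- simulate_tcr(below, n_draws = 100, seed = 1,
                         threshold = det / 2)
  expect_equal(sim_hi$exceedance_probability, 1)
})

test_that("missing carcinogen specs are a configuration error", {
  expect_error(simulate_tcr(list(As = fit_distribution(0.1, 0.01)),
                            n_draws = 10, seed = 1),
               "missing distribution spec.*Pb")
  expect_error(simulate_tcr(list(As = 1, Pb = 2), n_draws = 10),
               "distribution_spec")
})

test_that("simulated TCR mean matches the deterministic chain (linearity)", {
  specs <- list(As = fit_distribution(0.11, 0.03),
                Pb = fit_distribution(0.24, 0.05))
  tox <- toxicity_params()
  sim <- simulate_tcr(specs, n_draws = 10000, seed = 13)
  det <- as.numeric(total_cancer_risk(c(
    as.numeric(cancer_risk(edi(0.11, "As"), tox$CSF[["As"]])),
    as.numeric(cancer_risk(edi(0.24, "Pb"), tox$CSF[["Pb"]])))))
  se_mean <- sd(sim$draws) / sqrt(length(sim$draws))
  expect_lt(abs(mean(sim$draws) - det), 3 * se_mean)
})

test_that("threshold sweeps are monotone and hit the trivial bounds", {
  specs <- list(As = fit_distribution(0.11, 0.03),
                Pb = fit_distribution(0.24, 0.05))
  sim <- simulate_tcr(specs, n_draws = 2000, seed = 3)
  sw <- threshold_sweep(sim, c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4))
  expect_true(all(diff(sw$exceedance_probability) <= 0))
  expect_equal(threshold_sweep(sim, min(sim$draws) / 2)$exceedance_probability, 1)
  expect_equal(threshold_sweep(sim, max(sim$draws) * 2)$exceedance_probability, 0)
  expect_error(threshold_sweep(sim, c(1e-4, 1e-6)), "sorted")
  expect_error(threshold_sweep(sim, c(-1, 1)), "positive")
})

test_that("MC standard error follows sqrt(p(1-p)/n)", {
  specs <- list(As = fit_distribution(0.11, 0.05),
                Pb = fit_distribution(0.24, 0.1))
  sim <- simulate_tcr(specs, n_draws = 4000, seed = 21,
                      threshold = 7e-7)
  p <- sim$exceedance_probability
  expect_equal(sim$mc_se, sqrt(p * (1 - p) / 4000))
  # quadrupling the draw count halves the standard error at equal p
  sim4 <- simulate_tcr(specs, n_draws = 16000, seed = 21, threshold = 7e-7)
  expect_lt(sim4$mc_se, sim$mc_se)
  expect_equal(sqrt(p * (1 - p) / 16000), sim$mc_se / 2)
})

test_that("single-element chains match closed-form lognormal quantiles", {
  # TCR = k * X with X lognormal, so quantiles are k * qlnorm(p)
  tox <- toxicity_params(CSF = c(As = 1.5), carcinogens = "As")
  spec <- fit_distribution(0.11, 0.03)
  sim <- simulate_tcr(list(As = spec), toxicity = tox,
                      n_draws = 1e5, seed = 17)
  k <- as.numeric(cancer_risk(edi(1, "As"), 1.5))
  expected <- k * qdist(spec, c(0.025, 0.5, 0.975))
  expect_equal(unname(sim$percentiles), expected, tolerance = 0.02)
})

test_that("rank-correlated draws preserve margins and induce correlation", {
  specs <- list(As = fit_distribution(0.11, 0.03),
                Pb = fit_distribution(0.24, 0.05))
  sim <- simulate_tcr(specs, n_draws = 5000, seed = 8,
                      rank_correlation = 0.8)
  rho <- cor(sim$cr[, "As"], sim$cr[, "Pb"], method = "spearman")
  expect_gt(rho, 0.6)
  expect_equal(mean(sim$cr[, "As"] > 0), 1)
})

test_that("simulate.dietary_risk runs one reproducible stream per sector", {
  x <- generate_concentrations(seed = 2)
  fit <- dietary_risk(x)
  sim <- simulate(fit, nsim = 400, seed = 77)
  expect_named(sim, c("upper", "middle", "lower"))
  sim2 <- simulate(fit, nsim = 400, seed = 77)
  expect_identical(as.data.frame(sim), as.data.frame(sim2))
  df <- as.data.frame(sim)
  expect_true(all(df$p2.5 <= df$p50 & df$p50 <= df$p97.5))
  expect_true(all(df$exceedance_probability >= 0 &
                    df$exceedance_probability <= 1))
})
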