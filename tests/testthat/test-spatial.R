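# Small clustered logistic dataset over a county grid.
spatial_sim <- function(seed, n_counties_side = 3L, cases = 15L,
                        beta_x = 0.5) {
  cfg <- sim_config(n_county_rows = n_counties_side,
                    n_county_cols = n_counties_side,
                    tracts_per_county = 3L, n_variables = 1L,
                    blocks = integer(0),
                    planted_effects = c(v0001 = beta_x),
                    sigma_v = 0.3, sigma_u = 0.4, baseline = -1,
                    cases_per_tract = cases, seed = seed)
  geo <- make_geography(cfg)
  ex <- make_exposures(cfg, geo)
  reg <- make_registry(cfg, geo, ex)
  reg$outcome <- label_outcome(reg)
  ds <- link_by_key(reg, zscore(ex), geo)
  X <- cbind(`(Intercept)` = 1, age_dx = ds$age_dx, year_dx = ds$year_dx,
             exposure = ds$exposures$values[ds$tract, 1])
  list(ds = ds, X = X, icar = build_icar(geo))
}

test_that("sampler is deterministic under a fixed seed", {
  s <- spatial_sim(41L)
  ctl <- mcmc_control(n_draws = 300L, n_warmup = 200L, seed = 7L)
  f1 <- suppressWarnings(spatial_logit(s$ds$y, s$X, s$ds$county, s$icar,
                                       control = ctl))
  f2 <- suppressWarnings(spatial_logit(s$ds$y, s$X, s$ds$county, s$icar,
                                       control = ctl))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$U_draws, f2$U_draws)
})

test_that("spatial effects satisfy the sum-to-zero constraint in every draw", {
  s <- spatial_sim(42L)
  fit <- suppressWarnings(
    spatial_logit(s$ds$y, s$X, s$ds$county, s$icar,
                  control = mcmc_control(n_draws = 400L, n_warmup = 300L,
                                         seed = 3L)))
  sums <- rowSums(fit$U_draws)
  expect_lt(max(abs(sums)), 1e-10)
  expect_true(all(fit$draws[, "sigma2_v"] > 0))
  expect_true(all(fit$draws[, "sigma2_u"] > 0))
})

test_that("counties lacking a case or a control are rejected by name", {
  s <- spatial_sim(43L)
  y <- s$ds$y
  y[s$ds$county == 5L] <- 1L            # county 5 becomes all-case
  expect_error(
    spatial_logit(y, s$X, s$ds$county, s$icar,
                  control = mcmc_control(n_draws = 50L, n_warmup = 50L)),
    s$icar$counties[5])
})

test_that("with variances pinned near zero the fit collapses to penalized logistic", {
  set.seed(44)
  n <- 800
  x <- cbind(`(Intercept)` = 1, exposure = rnorm(n))
  y <- rbinom(n, 1, plogis(drop(x %*% c(-0.5, 0.6))))
  county <- rep(c("A", "B"), each = n / 2)
  icar <- build_icar(toy_island_geography())
  pri <- spatial_priors(sigma_v_fixed = 1e-4, sigma_u_fixed = 1e-4)
  fit <- suppressWarnings(
    spatial_logit(y, x, county, icar, priors = pri,
                  control = mcmc_control(n_draws = 6000L, n_warmup = 1000L,
                                         seed = 12L)))
  ml <- stats::glm.fit(x, y, family = stats::binomial())$coefficients
  expect_equal(unname(coef(fit)), unname(ml), tolerance = 0.02)
})

test_that("corrected credible level follows the Phase 1 hit count", {
  set.seed(45)
  fit <- fake_spatial_fit(rnorm(400000))
  ci95 <- corrected_credible_interval(fit, 1)
  expect_equal(ci95[["level"]], 0.95)
  expect_equal(ci95[["lo"]], -1.96, tolerance = 0.02)
  expect_equal(ci95[["hi"]], 1.96, tolerance = 0.02)

  ci434 <- corrected_credible_interval(fit, 434)
  expect_equal(ci434[["level"]], 1 - 0.05 / 434)
  expect_equal(ci434[["level"]], 0.9998848, tolerance = 1e-7)
  # wider level, wider interval: monotone in the correction
  expect_lt(ci95[["lo"]], 0)
  expect_gt(ci434[["hi"]] - ci434[["lo"]], ci95[["hi"]] - ci95[["lo"]])

  small <- fake_spatial_fit(rnorm(500))
  expect_error(corrected_credible_interval(small, 434), "draws")
})

test_that("residual variability is the latent-scale ICC", {
  # sigma_v^2 = pi^2/3 with no spatial field gives exactly one half
  half <- fake_spatial_fit(rnorm(100), sigma2_v = rep(pi^2 / 3, 100),
                           U = matrix(0, 100, 4))
  expect_equal(residual_variability(half), 0.5)
  # both components at zero gives zero
  none <- fake_spatial_fit(rnorm(100), sigma2_v = rep(1e-12, 100),
                           U = matrix(0, 100, 4))
  expect_lt(residual_variability(none), 1e-6)
})

test_that("fitted residual variability tracks the generative plug-in value", {
  s <- spatial_sim(46L, cases = 25L)
  fit <- suppressWarnings(
    spatial_logit(s$ds$y, s$X, s$ds$county, s$icar,
                  control = mcmc_control(n_draws = 1500L, n_warmup = 800L,
                                         seed = 5L)))
  # plug the generating variances into the same formula
  gen <- (0.3^2 + 0.4^2) / (0.3^2 + 0.4^2 + pi^2 / 3)
  expect_equal(residual_variability(fit), gen, tolerance = 0.1)
})
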