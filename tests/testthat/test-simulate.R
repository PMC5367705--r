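test_that("county grids have rook adjacency and FIPS-nested tract keys", {
  g22 <- make_geography(sim_config(n_county_rows = 2L, n_county_cols = 2L))
  expect_equal(length(g22$counties), 4L)
  expect_equal(nrow(g22$edges), 4L)

  g11 <- make_geography(sim_config(n_county_rows = 1L, n_county_cols = 1L))
  expect_equal(length(g11$counties), 1L)
  expect_equal(nrow(g11$edges), 0L)
  expect_equal(g11$n_neighbors[[1]], 0L)

  g33 <- make_geography(sim_config(n_county_rows = 3L, n_county_cols = 3L))
  deg <- sort(unname(g33$n_neighbors))
  expect_equal(deg, c(2, 2, 2, 2, 3, 3, 3, 3, 4))

  expect_true(all(substr(names(g33$tract_to_county), 1, 5) ==
                    unname(g33$tract_to_county)))
  expect_true(all(nchar(names(g33$tract_to_county)) == 11L))
})

test_that("block correlation and unit scale are realized in exposures", {
  cfg <- sim_config(n_county_rows = 5L, n_county_cols = 5L,
                    tracts_per_county = 20L, n_variables = 12L,
                    blocks = c(10L), block_rho = 0.9, spatial_sd = 0.25,
                    planted_effects = numeric(0), seed = 81L)
  ex <- make_exposures(cfg)                 # 500 tracts
  block_vals <- ex$values[, 1:10]
  cors <- stats::cor(block_vals)
  mean_pair <- mean(cors[upper.tri(cors)])
  expect_gt(mean_pair, 0.85)
  expect_lt(mean_pair, 0.95)
  # unblocked variables stay near-uncorrelated with the block
  expect_lt(abs(mean(stats::cor(ex$values[, 11], block_vals))), 0.2)
  expect_lt(abs(mean(colMeans(ex$values))), 0.1)
  expect_true(all(abs(apply(ex$values, 2, stats::sd) - 1) < 0.15))
})

test_that("spatially smooth exposures show positive spatial autocorrelation", {
  skip_if_not_installed("ape")
  cfg <- sim_config(n_county_rows = 5L, n_county_cols = 4L,
                    tracts_per_county = 1L, n_variables = 1L,
                    blocks = integer(0), block_rho = 0, spatial_sd = 0.8,
                    planted_effects = numeric(0))
  geo <- make_geography(cfg)
  icar <- build_icar(geo)
  W <- -icar$Q; diag(W) <- 0
  positive <- vapply(1:20, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 810L + r
    ex <- make_exposures(cfg_r, geo)
    ape::Moran.I(ex$values[, 1], W)$observed > 0
  }, logical(1))
  expect_gte(mean(positive), 0.9)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 82L, n_variables = 6L, blocks = c(3L),
                    planted_effects = c(v0001 = 0.3),
                    n_county_rows = 2L, n_county_cols = 2L,
                    tracts_per_county = 3L, cases_per_tract = 8)
  d1 <- simulate_nwas(cfg)
  d2 <- simulate_nwas(cfg)
  expect_identical(d1$exposures$values, d2$exposures$values)
  expect_identical(d1$registry, d2$registry)
})

test_that("outcome labels round-trip and the null model is balanced", {
  cfg <- sim_config(n_county_rows = 2L, n_county_cols = 2L,
                    tracts_per_county = 10L, n_variables = 2L,
                    blocks = integer(0), planted_effects = numeric(0),
                    sigma_v = 0, sigma_u = 0, baseline = 0, beta_age = 0,
                    cases_per_tract = 50, seed = 83L)
  reg <- make_registry(cfg)
  truth <- attr(reg, "truth")
  lab <- label_outcome(reg)
  expect_identical(as.integer(lab == "aggressive"), as.integer(truth$y))
  n <- nrow(reg)
  frac <- mean(truth$y)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("a planted effect is recovered by an independent logistic refit", {
  cfg <- sim_config(n_county_rows = 3L, n_county_cols = 3L,
                    tracts_per_county = 20L, n_variables = 3L,
                    blocks = integer(0), planted_effects = c(v0002 = 0.3),
                    sigma_v = 0, sigma_u = 0, baseline = -1,
                    cases_per_tract = 30, seed = 84L)
  geo <- make_geography(cfg)
  ex <- make_exposures(cfg, geo)
  reg <- make_registry(cfg, geo, ex)
  truth <- attr(reg, "truth")
  tract_i <- match(reg$tract_key, ex$tract_keys)
  d <- data.frame(y = truth$y, x = ex$values[tract_i, "v0002"],
                  age = reg$age_dx, year = reg$year_dx)
  fit <- stats::glm(y ~ age + year + x, binomial, d)
  est <- coef(summary(fit))["x", ]
  expect_lt(abs(est[["Estimate"]] - 0.3), 3 * est[["Std. Error"]])
})

test_that("every county holds at least one case and one control", {
  for (seed in 85:88) {
    cfg <- sim_config(n_county_rows = 3L, n_county_cols = 2L,
                      tracts_per_county = 2L, n_variables = 1L,
                      blocks = integer(0), planted_effects = numeric(0),
                      baseline = -3, cases_per_tract = 8, seed = seed)
    geo <- make_geography(cfg)
    reg <- make_registry(cfg, geo, make_exposures(cfg, geo))
    y <- as.integer(label_outcome(reg) == "aggressive")
    county <- substr(reg$tract_key, 1, 5)
    byc <- tapply(y, county, function(v) min(sum(v), sum(1 - v)))
    expect_true(all(byc >= 1))
  }
})

test_that("dataset writers and readers round-trip the simulation", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_county_rows = 2L, n_county_cols = 2L,
                    tracts_per_county = 3L, n_variables = 4L,
                    blocks = c(2L), planted_effects = c(v0001 = 0.3),
                    miss_rate = 0.05, cases_per_tract = 6, seed = 89L)
  d <- simulate_nwas(cfg, out_dir = dir)
  reg <- read_registry(file.path(dir, "registry.tsv"))
  ex <- read_exposures(file.path(dir, "exposures.tsv"))
  geo <- read_geography(file.path(dir, "tract_map.tsv"),
                        file.path(dir, "adjacency.txt"))
  expect_equal(nrow(reg), nrow(d$registry))
  expect_equal(sort(ex$variable_ids), sort(d$exposures$variable_ids))
  expect_equal(sum(ex$missing_mask), sum(d$exposures$missing_mask))
  expect_equal(geo$n_neighbors, d$geography$n_neighbors)
  expect_identical(readLines(file.path(dir, "truth.tsv"))[1],
                   "variable_id\tlog_or_per_sd")
})
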