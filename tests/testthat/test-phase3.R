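test_that("two perfectly correlated variables collapse onto one component", {
  x <- rnorm(40)
  ex <- exposure_table(cbind(a = x, b = 2 * x + 1),
                       sprintf("t%02d", 1:40), c("a", "b"))
  pca <- pca_correlation(ex)
  expect_equal(pca$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(pca$cum_fraction[1], 1)
  expect_equal(retain_components(pca$eigenvalues, 0.90), 1L)
})

test_that("independent variables give near-unit eigenvalues", {
  set.seed(71)
  vals <- matrix(rnorm(2000 * 5), 2000, 5,
                 dimnames = list(NULL, letters[1:5]))
  ex <- exposure_table(vals, sprintf("t%04d", 1:2000), letters[1:5])
  pca <- pca_correlation(ex)
  expect_true(all(abs(pca$eigenvalues - 1) < 0.15))
})

test_that("block-structured exposures are recovered exactly", {
  cfg <- sim_config(n_county_rows = 3L, n_county_cols = 3L,
                    tracts_per_county = 56L, n_variables = 16L,
                    blocks = c(6L, 5L, 4L), block_rho = 0.9,
                    spatial_sd = 0, planted_effects = numeric(0), seed = 72L)
  geo <- make_geography(cfg)
  ex <- make_exposures(cfg, geo)
  truth <- attr(ex, "truth")
  pca <- pca_correlation(ex)
  k <- retain_components(pca$eigenvalues, 0.90)
  expect_gte(k, 3L)
  membership <- assign_membership(pca$loadings, 3L)
  # membership must equal the generating blocks up to component relabeling
  tab <- table(truth$block, membership)
  expect_equal(sort(apply(tab, 1L, max)), sort(rowSums(tab)))
  expect_equal(length(unique(apply(tab, 1L, which.max))), 3L)
})

test_that("component retention respects the cumulative-variance target", {
  expect_equal(retain_components(c(5, 3, 1.5, 0.5), 0.90), 3L)
  expect_equal(retain_components(7, 0.90), 1L)
  expect_equal(retain_components(c(2, 1, 1, 0), 1.0), 3L)
})

test_that("membership uses maximal absolute loading with low-index ties", {
  load <- rbind(a = c(0.9, 0.1), b = c(-0.2, 0.7), c = c(0.5, 0.5))
  colnames(load) <- c("PC1", "PC2")
  mem <- assign_membership(load, 2L)
  expect_equal(unname(mem), c(1L, 2L, 1L))
})

test_that("top hits minimize credible-interval length with documented ties", {
  p2 <- structure(data.frame(
    variable_id = c("a", "b", "c", "d", "e"),
    post_mean = c(0.30, 0.10, -0.50, 0.20, 0.20),
    ci_length = c(0.08, 0.11, 0.05, 0.05, 0.07),
    significant = TRUE, stringsAsFactors = FALSE),
    class = c("phase2_result", "data.frame"))
  mem <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 2L)
  top <- select_top_hits(mem, p2)
  expect_equal(top[["1"]], "a")           # 0.08 < 0.11
  expect_equal(top[["2"]], "c")           # tie at 0.05: |-0.50| > |0.20|

  # ties on both length and |effect| fall back to lexicographic id
  p2$post_mean <- 0.2
  p2$ci_length <- 0.05
  expect_equal(select_top_hits(mem, p2)[["2"]], "c")

  # agreement with a brute-force argmin oracle over random lengths
  set.seed(73)
  for (rep in 1:20) {
    p2$ci_length <- round(runif(5, 0.01, 0.2), 3)
    p2$post_mean <- rnorm(5)
    top <- select_top_hits(mem, p2)
    for (comp in c("1", "2")) {
      ids <- names(mem)[mem == as.integer(comp)]
      sub <- p2[p2$variable_id %in% ids, ]
      best <- sub$variable_id[order(sub$ci_length, -abs(sub$post_mean),
                                    sub$variable_id)][1]
      expect_equal(top[[comp]], best)
    }
  }
})

test_that("the full phase groups hits and returns one top hit per component", {
  cfg <- sim_config(n_county_rows = 3L, n_county_cols = 3L,
                    tracts_per_county = 56L, n_variables = 12L,
                    blocks = c(5L, 4L, 3L), block_rho = 0.9,
                    spatial_sd = 0, planted_effects = numeric(0), seed = 74L)
  ex <- make_exposures(cfg, make_geography(cfg))
  set.seed(75)
  p2 <- structure(data.frame(
    variable_id = ex$variable_ids,
    post_mean = rnorm(12, 0.3, 0.05),
    odds_ratio = 1.3, ci_lo = 0.1, ci_hi = 0.5,
    ci_length = runif(12, 0.05, 0.2),
    significant = TRUE, stringsAsFactors = FALSE),
    class = c("phase2_result", "data.frame"))
  rep3 <- phase3_components(p2, ex, target = 0.90)
  expect_s3_class(rep3, "component_report")
  expect_equal(sum(!is.na(rep3$top_hits)), rep3$k_retained)
  expect_true(all(diff(rep3$eigenvalues) <= 1e-12))
  expect_true(all(rep3$cum_fraction <= 1 + 1e-12))
  expect_true(!anyDuplicated(stats::na.omit(rep3$top_hits)))
  # each generating block contributes exactly one of the leading top hits
  truth <- attr(ex, "truth")
  lead_hits <- rep3$top_hits[as.character(1:3)]
  blocks_hit <- truth$block[match(lead_hits, truth$variable_id)]
  expect_equal(sort(blocks_hit), 1:3)
})

test_that("degenerate inputs are rejected", {
  ex <- exposure_table(cbind(a = rnorm(10)), sprintf("t%02d", 1:10), "a")
  expect_error(pca_correlation(ex), "2 variables")
})
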