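# Independent oracles and small builders shared across test files.

# Ordinary logistic regression via stats::glm plus the HC0 sandwich,
# independent of the package's GEE code path.
oracle_glm_hc0 <- function(y, x) {
  fit <- stats::glm.fit(x, y, family = stats::binomial())
  beta <- fit$coefficients
  mu <- fit$fitted.values
  r <- y - mu
  bread <- t(x) %*% (x * mu * (1 - mu))
  meat <- t(x) %*% (x * r^2)
  vc <- solve(bread) %*% meat %*% solve(bread)
  list(beta = beta, se = sqrt(diag(vc)))
}

# Direct moment-formula estimate of the exchangeable working correlation,
# given coefficients (usually from the fit under test).
oracle_alpha_moment <- function(y, x, id, beta) {
  mu <- stats::plogis(drop(x %*% beta))
  e <- (y - mu) / sqrt(mu * (1 - mu))
  p <- ncol(x)
  phi <- sum(e^2) / (length(y) - p)
  ids <- unique(id)
  num <- sum(vapply(ids, function(g) {
    eg <- e[id == g]
    (sum(eg)^2 - sum(eg^2)) / 2
  }, numeric(1)))
  nsz <- table(id)
  num / (phi * (sum(nsz * (nsz - 1) / 2) - p))
}

# Posterior mean of (b0, b1) for the random-intercept logistic toy
#   logit p = b0 + b1 x + V_county,  V ~ N(0, sv^2) fixed sv,
# by dense grid quadrature over (b0, b1) with trapezoid integration over V
# per county. Independent of the MCMC code path.
oracle_quadrature_toy <- function(y, x, county, sv, beta_sd = 10,
                                  b0_range = c(-3, 3), b1_range = c(-3, 3),
                                  n_grid = 101, n_v = 201) {
  vgrid <- seq(-6 * sv, 6 * sv, length.out = n_v)
  dv <- vgrid[2] - vgrid[1]
  wv <- stats::dnorm(vgrid, 0, sv) * dv
  b0g <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1g <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  groups <- split(seq_along(y), county)
  post <- matrix(0, n_grid, n_grid)
  for (i in seq_along(b0g)) {
    for (j in seq_along(b1g)) {
      lp <- stats::dnorm(b0g[i], 0, beta_sd, log = TRUE) +
        stats::dnorm(b1g[j], 0, beta_sd, log = TRUE)
      for (idx in groups) {
        eta <- b0g[i] + b1g[j] * x[idx]
        lk <- vapply(vgrid, function(v) {
          e <- eta + v
          sum(y[idx] * e - log1p(exp(e)))
        }, numeric(1))
        lp <- lp + log(sum(exp(lk - max(lk)) * wv)) + max(lk)
      }
      post[i, j] <- lp
    }
  }
  post <- exp(post - max(post))
  post <- post / sum(post)
  c(b0 = sum(rowSums(post) * b0g), b1 = sum(colSums(post) * b1g))
}

# Two isolated counties ("A", "B"), one nominal tract each.
toy_island_geography <- function(keys = c("A", "B")) {
  geography(stats::setNames(keys, paste0("t_", keys)),
            matrix(character(0), ncol = 2))
}

# Registry data.frame builder with sane defaults for single-field tweaks.
make_records <- function(n, ...) {
  out <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                    tract_key = "42001000001",
                    address_type = "street",
                    age_dx = 65, year_dx = 2000,
                    stage = 2, gleason = 5, race = "white",
                    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# Minimal stand-in posterior fit for interval/ICC unit tests.
fake_spatial_fit <- function(exposure_draws, sigma2_v = NULL, U = NULL) {
  nd <- length(exposure_draws)
  draws <- cbind(`(Intercept)` = 0, exposure = exposure_draws,
                 sigma2_v = sigma2_v %||% rep(0.1, nd),
                 sigma2_u = rep(0.1, nd))
  structure(list(draws = draws,
                 U_draws = U %||% matrix(0, nd, 3),
                 coef_names = c("(Intercept)", "exposure")),
            class = "spatial_logit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
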