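#' Priors for the spatial hierarchical logistic model
#'
#' Fixed effects get independent Normal(0, `beta_sd`^2) priors. The two
#' variance components get conjugate Gamma priors on the precisions,
#' 1/sigma^2 ~ Gamma(`prec_shape`, `prec_rate`), a common weakly-informative
#' default in the disease-mapping literature. Either variance can instead be
#' pinned to a fixed value (useful for oracle comparisons and for the
#' no-random-effect limit).
#'
#' @param beta_sd Prior SD of fixed effects.
#' @param prec_shape,prec_rate Gamma prior on both precisions.
#' @param sigma_v_fixed,sigma_u_fixed If non-`NULL`, fix the iid / spatial SD
#'   at this value instead of sampling it.
#' @return A list of class `nwas_priors`.
#' @export
spatial_priors <- function(beta_sd = 10, prec_shape = 1, prec_rate = 5e-4,
                           sigma_v_fixed = NULL, sigma_u_fixed = NULL) {
  structure(list(beta_sd = beta_sd, prec_shape = prec_shape,
                 prec_rate = prec_rate, sigma_v_fixed = sigma_v_fixed,
                 sigma_u_fixed = sigma_u_fixed),
            class = "nwas_priors")
}

#' MCMC control settings for [spatial_logit()]
#'
#' @param n_draws Posterior draws kept after warmup.
#' @param n_warmup Adaptation/warmup iterations (discarded).
#' @param seed Integer seed; the sampler is deterministic given the seed.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_draws = 4000L, n_warmup = 1500L, seed = 1L,
                         thin = 1L) {
  structure(list(n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "mcmc_control")
}

#' Bayesian hierarchical logistic regression with county random effects
#'
#' Fits, by Markov chain Monte Carlo, the model
#' \deqn{\mathrm{logit}\,p_i = x_i'\beta + V_{j(i)} + U_{j(i)}}
#' where \eqn{j(i)} is the county of case \eqn{i}, \eqn{V_j \sim N(0,
#' \sigma_v^2)} are exchangeable (globally smoothing) county effects and
#' \eqn{U} follows an intrinsic CAR (Besag) prior over the county adjacency
#' graph with conditional variance \eqn{\sigma_u^2 / n_j} (locally smoothing),
#' under a sum-to-zero constraint per connected component. The sampler is an
#' adaptive Metropolis-within-Gibbs: per-coordinate random-walk updates for
#' the fixed effects and the county effects (proposal scales adapted during
#' warmup toward 44% acceptance), conjugate Gibbs draws for the two
#' precisions, and a per-component recentring move that shifts the mean of
#' \eqn{U} into the intercept.
#'
#' Every county must contain at least one case and one control; violations
#' are an error naming the counties.
#'
#' @param y Binary response (0/1).
#' @param x Model matrix including intercept (first column).
#' @param county County index (1-based integers into `icar$counties`) or
#'   county keys.
#' @param icar An `icar_structure` from [build_icar()].
#' @param priors A [spatial_priors()] list.
#' @param control An [mcmc_control()] list.
#' @return An object of class `spatial_logit`: `draws` (matrix with columns
#'   for fixed effects, `sigma2_v`, `sigma2_u`), `U_draws`, `V_draws`,
#'   `diagnostics` (per-parameter `ess`, `mcse`, `rhat`), `accept` rates,
#'   `converged_ok` flag, plus the inputs' metadata.
#' @export
spatial_logit <- function(y, x, county, icar, priors = spatial_priors(),
                          control = mcmc_control()) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  p <- ncol(x)
  stopifnot(nrow(x) == n, all(y %in% c(0, 1)), inherits(icar, "icar_structure"))
  if (is.character(county)) county <- match(county, icar$counties)
  county <- as.integer(county)
  J <- length(icar$counties)
  stopifnot(all(county >= 1L & county <= J))

  ncase <- tabulate(county, nbins = J)
  case1 <- rowsum(y, factor(county, levels = seq_len(J)))[, 1L]
  bad <- which(ncase > 0L & (case1 == 0 | case1 == ncase))
  if (length(bad)) {
    stop("county/counties without both a case and a control: ",
         paste(icar$counties[bad], collapse = ", "), call. = FALSE)
  }

  set.seed(control$seed)
  # Internally center non-intercept columns: removes the near-collinearity of
  # the intercept with large-scale covariates (calendar year, age) that would
  # cripple coordinate-wise sampling. The intercept prior applies to the
  # centered intercept; draws are transformed back before returning.
  is_int <- apply(x, 2L, function(col) all(col == 1))
  center <- ifelse(is_int, 0, colMeans(x))
  x <- sweep(x, 2L, center, "-")
  members <- split(seq_len(n), factor(county, levels = seq_len(J)))
  deg <- unname(icar$n_neighbors)
  island <- deg == 0L
  free_u <- which(!island)                 # all non-island counties carry U
  comp <- icar$component

  n_iter <- control$n_warmup + control$n_draws * control$thin
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))

  beta <- rep(0, p)
  pbar <- min(max(mean(y), 1e-3), 1 - 1e-3)
  beta[1L] <- log(pbar / (1 - pbar))
  V <- rep(0, J)
  U <- rep(0, J)
  s2v <- (priors$sigma_v_fixed %||% 0.25)^2
  s2u <- (priors$sigma_u_fixed %||% 0.25)^2
  sample_s2v <- is.null(priors$sigma_v_fixed)
  sample_s2u <- is.null(priors$sigma_u_fixed)
  rank_u <- length(free_u) - sum(tabulate(comp[free_u]) > 0L)

  eta_fix <- drop(x %*% beta)
  eta <- eta_fix + V[county] + U[county]
  llv <- y * eta - log1pexp(eta)           # per-case log-likelihood

  ls_beta <- rep(log(0.1), p)              # log proposal scales
  ls_v <- rep(log(0.3), J)
  ls_u <- rep(log(0.3), J)
  acc_beta <- rep(0, p); acc_v <- rep(0, J); acc_u <- rep(0, J)
  prior_prec_b <- 1 / priors$beta_sd^2

  keep <- matrix(NA_real_, control$n_draws, p + 2L,
                 dimnames = list(NULL, c(cn, "sigma2_v", "sigma2_u")))
  keepU <- matrix(NA_real_, control$n_draws, J)
  keepV <- matrix(NA_real_, control$n_draws, J)
  kept <- 0L

  adapt <- function(ls, acc, it, target = 0.44) {
    ls + (acc - target) / sqrt(it / 25 + 1)
  }

  for (it in seq_len(n_iter)) {
    warm <- it <= control$n_warmup
    ## fixed effects: per-coordinate random walk
    for (k in seq_len(p)) {
      prop <- stats::rnorm(1, 0, exp(ls_beta[k]))
      eta2 <- eta + x[, k] * prop
      llv2 <- y * eta2 - log1pexp(eta2)
      bk <- beta[k]
      lr <- sum(llv2 - llv) +
        0.5 * prior_prec_b * (bk^2 - (bk + prop)^2)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        beta[k] <- bk + prop
        eta <- eta2; llv <- llv2
        acc_beta[k] <- acc_beta[k] + 1
        if (warm) ls_beta[k] <- adapt(ls_beta[k], 1, it)
      } else if (warm) ls_beta[k] <- adapt(ls_beta[k], 0, it)
    }
    ## iid county effects
    for (j in which(ncase > 0L)) {
      idx <- members[[j]]
      prop <- stats::rnorm(1, 0, exp(ls_v[j]))
      e2 <- eta[idx] + prop
      l2 <- y[idx] * e2 - log1pexp(e2)
      lr <- sum(l2 - llv[idx]) +
        0.5 * (V[j]^2 - (V[j] + prop)^2) / s2v
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        V[j] <- V[j] + prop
        eta[idx] <- e2; llv[idx] <- l2
        acc_v[j] <- acc_v[j] + 1
        if (warm) ls_v[j] <- adapt(ls_v[j], 1, it)
      } else if (warm) ls_v[j] <- adapt(ls_v[j], 0, it)
    }
    ## counties with no cases still need a V draw from the prior
    empty <- which(ncase == 0L)
    if (length(empty)) V[empty] <- stats::rnorm(length(empty), 0, sqrt(s2v))
    ## ICAR county effects (islands pinned at 0)
    for (j in free_u) {
      nbj <- icar$neighbors[[j]]
      m_j <- mean(U[nbj])
      prop <- stats::rnorm(1, 0, exp(ls_u[j]))
      unew <- U[j] + prop
      lr <- 0.5 * deg[j] * ((U[j] - m_j)^2 - (unew - m_j)^2) / s2u
      idx <- members[[j]]
      if (length(idx)) {
        e2 <- eta[idx] + prop
        l2 <- y[idx] * e2 - log1pexp(e2)
        lr <- lr + sum(l2 - llv[idx])
      }
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        U[j] <- unew
        if (length(idx)) { eta[idx] <- e2; llv[idx] <- l2 }
        acc_u[j] <- acc_u[j] + 1
        if (warm) ls_u[j] <- adapt(ls_u[j], 1, it)
      } else if (warm) ls_u[j] <- adapt(ls_u[j], 0, it)
    }
    ## recentre U per component, absorbing the shift into the intercept
    if (length(free_u)) {
      shift <- numeric(J)
      for (cc in unique(comp[free_u])) {
        mem <- free_u[comp[free_u] == cc]
        m_c <- mean(U[mem])
        U[mem] <- U[mem] - m_c
        shift[mem] <- m_c
      }
      wmean <- sum(shift * ncase) / max(sum(ncase), 1L)
      beta[1L] <- beta[1L] + wmean
      eta <- drop(x %*% beta) + V[county] + U[county]
      llv <- y * eta - log1pexp(eta)
    }
    ## variance components (conjugate)
    if (sample_s2v) {
      s2v <- 1 / stats::rgamma(1, priors$prec_shape + J / 2,
                               priors$prec_rate + sum(V^2) / 2)
    }
    if (sample_s2u && rank_u > 0L) {
      quad <- sum((U[icar$edges[, 1L]] - U[icar$edges[, 2L]])^2)
      s2u <- 1 / stats::rgamma(1, priors$prec_shape + rank_u / 2,
                               priors$prec_rate + quad / 2)
    }
    ## joint rescale moves (sigma, effects) along the prior-scale direction:
    ## break the mutual-shrinkage trap between a variance and its effects
    if (sample_s2v) {
      del <- stats::rnorm(1, 0, 0.4)
      cc <- exp(del / 2)
      eta2 <- eta + (cc - 1) * V[county]
      llv2 <- y * eta2 - log1pexp(eta2)
      lr <- sum(llv2 - llv) + (2 - 2 * priors$prec_shape) * (del / 2) -
        priors$prec_rate / s2v * (cc^-2 - 1)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        V <- cc * V; s2v <- cc^2 * s2v
        eta <- eta2; llv <- llv2
      }
    }
    if (sample_s2u && rank_u > 0L) {
      del <- stats::rnorm(1, 0, 0.4)
      cc <- exp(del / 2)
      eta2 <- eta + (cc - 1) * U[county]
      llv2 <- y * eta2 - log1pexp(eta2)
      lr <- sum(llv2 - llv) + (2 - 2 * priors$prec_shape) * (del / 2) -
        priors$prec_rate / s2u * (cc^-2 - 1)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        U <- cc * U; s2u <- cc^2 * s2u
        eta <- eta2; llv <- llv2
      }
    }
    if (!warm && (it - control$n_warmup) %% control$thin == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- c(beta, s2v, s2u)
      keepU[kept, ] <- U
      keepV[kept, ] <- V
    }
  }

  # undo the internal covariate centering on the intercept draws
  if (any(is_int) && any(center != 0)) {
    ii <- which(is_int)[1L]
    keep[, ii] <- keep[, ii] -
      keep[, seq_len(p), drop = FALSE] %*% center
  }

  diag_tab <- mcmc_diagnostics(keep)
  ok <- all(diag_tab$mcse < 0.05 * diag_tab$sd | diag_tab$sd < 1e-12) &&
    all(diag_tab$rhat < 1.01, na.rm = TRUE)
  if (!ok) {
    warning("MCMC diagnostics below contract (MCSE >= 5% of posterior SD ",
            "or split R-hat >= 1.01 for some parameter); ",
            "consider more draws", call. = FALSE)
  }
  structure(list(draws = keep, U_draws = keepU, V_draws = keepV,
                 diagnostics = diag_tab,
                 accept = list(beta = acc_beta / n_iter,
                               v = acc_v / n_iter, u = acc_u / n_iter),
                 converged_ok = ok, seed = control$seed,
                 counties = icar$counties, component = comp,
                 island = island, n_obs = n, coef_names = cn,
                 priors = priors, control = control),
            class = "spatial_logit")
}

# Per-parameter ESS (Geyer initial positive sequence), MCSE, split R-hat.
mcmc_diagnostics <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2L, stats::sd),
                    ess = NA_real_, mcse = NA_real_, rhat = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(ncol(draws))) {
    v <- draws[, k]
    if (out$sd[k] < 1e-12) { out$ess[k] <- n; out$mcse[k] <- 0; out$rhat[k] <- 1; next }
    out$ess[k] <- ess_ips(v)
    out$mcse[k] <- out$sd[k] / sqrt(out$ess[k])
    m1 <- v[seq_len(half)]; m2 <- v[(n - half + 1L):n]
    W <- (stats::var(m1) + stats::var(m2)) / 2
    B <- half * stats::var(c(mean(m1), mean(m2)))
    varp <- (half - 1) / half * W + B / half
    out$rhat[k] <- sqrt(varp / W)
  }
  out
}

# Effective sample size by Geyer's initial-positive-sequence truncation of
# the sample autocorrelation: tau = 1 + 2*sum(rho_k), summing while the
# adjacent pair sums rho_{2m} + rho_{2m+1} stay positive.
ess_ips <- function(v) {
  n <- length(v)
  ac <- stats::acf(v, lag.max = min(n - 1L, 2000L), plot = FALSE)$acf[, 1, 1]
  s <- 0
  m <- 2L                                  # ac[1] is rho_0 = 1
  while (m <= length(ac)) {
    g <- ac[m] + if (m + 1L <= length(ac)) ac[m + 1L] else 0
    if (!is.finite(g) || g < 0) break
    s <- s + g
    m <- m + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' @export
coef.spatial_logit <- function(object, ...) {
  stats::setNames(colMeans(object$draws[, object$coef_names, drop = FALSE]),
                  object$coef_names)
}

#' @export
vcov.spatial_logit <- function(object, ...) {
  stats::cov(object$draws[, object$coef_names, drop = FALSE])
}

#' @export
print.spatial_logit <- function(x, ...) {
  cat(sprintf(
    "Bayesian spatial logistic fit: %d obs, %d counties, %d draws (seed %d)%s\n",
    x$n_obs, length(x$counties), nrow(x$draws), x$seed,
    if (x$converged_ok) "" else " [diagnostics warning]"))
  print(round(coef(x), 4))
  cat(sprintf("posterior mean sigma2_v = %.4f, sigma2_u = %.4f\n",
              mean(x$draws[, "sigma2_v"]), mean(x$draws[, "sigma2_u"])))
  invisible(x)
}

#' @export
summary.spatial_logit <- function(object, ...) {
  qs <- t(apply(object$draws, 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  tab <- cbind(mean = colMeans(object$draws), sd = apply(object$draws, 2, stats::sd),
               qs)
  out <- list(coefficients = tab, diagnostics = object$diagnostics,
              converged_ok = object$converged_ok, n_obs = object$n_obs,
              n_draws = nrow(object$draws))
  class(out) <- "summary.spatial_logit"
  out
}

#' @export
print.summary.spatial_logit <- function(x, ...) {
  cat(sprintf("Bayesian spatial logistic regression: %d obs, %d draws%s\n\n",
              x$n_obs, x$n_draws,
              if (x$converged_ok) "" else " [diagnostics warning]"))
  print(round(x$coefficients, 4))
  cat("\nDiagnostics:\n")
  print(x$diagnostics, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.spatial_logit <- function(x, parameter = "exposure", ...) {
  if (!parameter %in% colnames(x$draws)) parameter <- colnames(x$draws)[1L]
  graphics::plot(x$draws[, parameter], type = "l", xlab = "draw",
                 ylab = parameter, main = sprintf("Trace: %s", parameter), ...)
  invisible(x)
}

#' Equal-tailed credible interval at the Bonferroni-corrected level
#'
#' For `n_phase1` variables carried into Phase 2, the significance threshold
#' is 0.05 / n_phase1, so intervals are computed at level
#' `1 - 0.05 / n_phase1` from the posterior quantiles of the requested
#' coefficient. When the tail mass times the number of draws is below 20 the
#' extreme quantiles are not estimable and an error asks for more draws.
#'
#' @param fit A `spatial_logit`.
#' @param n_phase1 Number of Phase 1-significant variables (>= 1).
#' @param parameter Coefficient name (default `"exposure"`).
#' @return Named numeric vector `(lo, hi, level)` on the log-odds scale.
#' @export
corrected_credible_interval <- function(fit, n_phase1, parameter = "exposure") {
  stopifnot(inherits(fit, "spatial_logit"), n_phase1 >= 1)
  level <- 1 - 0.05 / n_phase1
  tail <- (1 - level) / 2
  nd <- nrow(fit$draws)
  if (tail * nd < 20) {
    stop(sprintf(
      "tail mass %.3g x %d draws < 20: increase n_draws to at least %d for level %.7f",
      tail, nd, ceiling(20 / tail), level), call. = FALSE)
  }
  v <- fit$draws[, parameter]
  qs <- unname(stats::quantile(v, probs = c(tail, 1 - tail), names = FALSE))
  c(lo = qs[1L], hi = qs[2L], level = level)
}

#' Residual county-level variability on the latent scale
#'
#' Posterior mean of the latent-scale intraclass correlation
#' \deqn{(\sigma_v^2 + \mathrm{var}(U)) / (\sigma_v^2 + \mathrm{var}(U) +
#' \pi^2/3)} where \eqn{\mathrm{var}(U)} is the empirical variance of the
#' spatial effect vector within each draw and \eqn{\pi^2/3} is the variance
#' of the standard logistic distribution: the share of unexplained
#' case-level risk variation attributable to county membership.
#'
#' @param fit A `spatial_logit`.
#' @return A single fraction in (0, 1).
#' @export
residual_variability <- function(fit) {
  stopifnot(inherits(fit, "spatial_logit"))
  s2v <- fit$draws[, "sigma2_v"]
  uvar <- apply(fit$U_draws, 1L, stats::var)
  if (all(!is.finite(uvar))) uvar <- 0
  icc <- (s2v + uvar) / (s2v + uvar + pi^2 / 3)
  mean(icc)
}
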