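#' GEE logistic regression with exchangeable working correlation
#'
#' Fits a marginal logistic model to clustered binary data by generalized
#' estimating equations: Fisher-scoring updates of the coefficients under a
#' working covariance \eqn{V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}} with
#' exchangeable \eqn{R}, alternating with moment updates of the working
#' correlation \eqn{\alpha} and dispersion \eqn{\phi} from Pearson residuals.
#' Standard errors come from the robust sandwich
#' \eqn{B^{-1} M B^{-1}} with bread \eqn{B = \sum_i D_i' V_i^{-1} D_i} and
#' meat \eqn{M = \sum_i D_i' V_i^{-1} r_i r_i' V_i^{-1} D_i}, which is
#' consistent even when the working correlation is wrong.
#'
#' The exchangeable inverse is applied in closed form,
#' \eqn{R^{-1} = c_1 I + c_2 J} with \eqn{c_1 = 1/(1-\alpha)} and
#' \eqn{c_2 = -\alpha / ((1-\alpha)(1 + (n_i - 1)\alpha))}, so the fit costs
#' O(n p^2) per iteration regardless of cluster sizes. With all clusters of
#' size one the fit reduces to ordinary logistic regression with HC0 robust
#' standard errors.
#'
#' @param y Binary response vector (0/1).
#' @param x Model matrix (including intercept column).
#' @param id Cluster identifiers (census tracts), any atomic type.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @param tol Convergence tolerance on \eqn{\max_k |\Delta\beta_k|}.
#' @return An object of class `gee_logit`: `coefficients`, `robust_cov`,
#'   `alpha` (working correlation), `phi` (dispersion), `n_clusters`, `n_obs`,
#'   `converged`, `n_iter`, `fitted` (probabilities).
#' @examples
#' set.seed(1)
#' n <- 400
#' id <- rep(1:100, each = 4)
#' x <- cbind(1, rnorm(n))
#' y <- rbinom(n, 1, plogis(x %*% c(-0.5, 0.4) + rep(rnorm(100, 0, 0.7), each = 4)))
#' fit <- gee_logit(y, x, id)
#' summary(fit)
#' @export
gee_logit <- function(y, x, id, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  p <- ncol(x)
  stopifnot(nrow(x) == n, length(id) == n, all(y %in% c(0, 1)))
  fid <- factor(id, levels = unique(id))
  gi <- as.integer(fid)
  g <- nlevels(fid)
  nsz <- tabulate(gi, nbins = g)           # cluster sizes
  npairs_tot <- sum(nsz * (nsz - 1) / 2)
  amax <- if (max(nsz) > 1L) 1 / (max(nsz) - 1L) else 1

  beta <- rep(0, p)
  # intercept start at logit of the mean keeps early iterations sane
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  beta[1L] <- log(pbar / (1 - pbar))
  alpha <- 0
  phi <- 1
  converged <- FALSE
  iter <- 0L
  singular <- FALSE

  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-12)) v <- pmax(v, 1e-12)
    sv <- sqrt(v)
    e <- (y - mu) / sv                     # Pearson residuals
    phi <- sum(e^2) / (n - p)
    if (npairs_tot > p) {
      se_g <- rowsum(e, gi, reorder = FALSE)
      s2_g <- rowsum(e^2, gi, reorder = FALSE)
      cross <- sum((se_g^2 - s2_g) / 2)
      alpha <- cross / (phi * (npairs_tot - p))
      alpha <- max(min(alpha, 0.999), -0.999 * amax)
    } else {
      alpha <- 0
    }
    c1 <- 1 / (1 - alpha)
    c2g <- -alpha / ((1 - alpha) * (1 + (nsz - 1) * alpha))  # per cluster

    w <- x * sv                            # A^{1/2} X
    Sg <- rowsum(w, gi, reorder = FALSE)   # per-cluster column sums of W
    tg <- drop(rowsum(e, gi, reorder = FALSE))
    bread <- crossprod(w) * c1 + crossprod(Sg, Sg * c2g)
    score <- c1 * drop(crossprod(w, e)) + drop(crossprod(Sg, c2g * tg))
    delta <- tryCatch(solve(bread, score), error = function(err) NULL)
    if (is.null(delta) || any(!is.finite(delta))) { singular <- TRUE; break }
    beta <- beta + delta
    # separation shows up as a diverging linear predictor, never as large
    # coefficients per se (covariates like calendar year give huge intercepts)
    if (max(abs(drop(x %*% beta))) > 30) { singular <- TRUE; break }
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  if (singular) {
    robust_cov <- matrix(NA_real_, p, p)
    converged <- FALSE
    mu <- stats::plogis(drop(x %*% beta))
  } else {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    sv <- sqrt(v)
    e <- (y - mu) / sv
    phi <- sum(e^2) / (n - p)
    if (npairs_tot > p) {      # refresh moment estimates at the final beta
      se_g <- rowsum(e, gi, reorder = FALSE)
      s2_g <- rowsum(e^2, gi, reorder = FALSE)
      alpha <- sum((se_g^2 - s2_g) / 2) / (phi * (npairs_tot - p))
      alpha <- max(min(alpha, 0.999), -0.999 * amax)
    } else {
      alpha <- 0
    }
    c1 <- 1 / (1 - alpha)
    c2g <- -alpha / ((1 - alpha) * (1 + (nsz - 1) * alpha))
    w <- x * sv
    Sg <- rowsum(w, gi, reorder = FALSE)
    tg <- drop(rowsum(e, gi, reorder = FALSE))
    bread <- crossprod(w) * c1 + crossprod(Sg, Sg * c2g)
    Eg <- rowsum(w * e, gi, reorder = FALSE)     # per-cluster W'e
    U <- c1 * Eg + Sg * (c2g * tg)               # per-cluster D'V^{-1} r
    meat <- crossprod(U)
    bi <- solve(bread)
    robust_cov <- bi %*% meat %*% bi
    robust_cov <- (robust_cov + t(robust_cov)) / 2
  }

  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  names(beta) <- cn
  dimnames(robust_cov) <- list(cn, cn)
  structure(list(coefficients = beta, robust_cov = robust_cov,
                 alpha = alpha, phi = phi, n_clusters = g, n_obs = n,
                 converged = converged, n_iter = iter, fitted = mu),
            class = "gee_logit")
}

#' @export
coef.gee_logit <- function(object, ...) object$coefficients

#' @export
vcov.gee_logit <- function(object, ...) object$robust_cov

#' @export
print.gee_logit <- function(x, ...) {
  cat(sprintf(
    "GEE logistic fit (exchangeable): %d obs in %d clusters, alpha = %.4f%s\n",
    x$n_obs, x$n_clusters, x$alpha,
    if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.gee_logit <- function(object, ...) {
  se <- sqrt(diag(object$robust_cov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, alpha = object$alpha, phi = object$phi,
              n_clusters = object$n_clusters, n_obs = object$n_obs,
              converged = object$converged)
  class(out) <- "summary.gee_logit"
  out
}

#' @export
print.summary.gee_logit <- function(x, ...) {
  cat(sprintf("GEE logistic regression, exchangeable working correlation\n"))
  cat(sprintf("n = %d, clusters = %d, alpha = %.4f, phi = %.4f%s\n\n",
              x$n_obs, x$n_clusters, x$alpha, x$phi,
              if (x$converged) "" else " [NOT CONVERGED]"))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.gee_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$robust_cov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Bonferroni adjustment
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0, 1]", call. = FALSE)
  pmin(1, m * p)
}
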