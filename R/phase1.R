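#' Phase 1: per-variable GEE logistic screen
#'
#' Fits one GEE logistic model per area-level variable,
#' `outcome ~ age + year + variable`, with census tracts as clusters, an
#' exchangeable working correlation and robust sandwich standard errors.
#' Two-sided Wald p-values are Bonferroni-corrected over the number of
#' variables whose fits converged; a variable is significant when the
#' corrected p-value is below `alpha_fw`. Residual per-variable missingness is
#' handled by complete-case analysis, so each variable may use a slightly
#' different case count.
#'
#' @param dataset A `linked_dataset` from [link_by_key()].
#' @param exposures Optional [exposure_table()] to screen; defaults to the
#'   exposures embedded in `dataset`. Usually Z-scored (see [zscore()]).
#' @param alpha_fw Family-wise significance level (default 0.05).
#' @param max_iter,tol Passed to [gee_logit()].
#' @return An object of class `phase1_result`: a `data.frame` sorted by
#'   p-value with columns `variable_id`, `n_used`, `beta`, `robust_se`,
#'   `odds_ratio`, `ci_lo`, `ci_hi` (95% Wald), `p_value`, `p_bonferroni`,
#'   `significant`; attributes `m` (tests counted), `skipped` (ids of
#'   non-converged fits), `alpha_fw`.
#' @export
screen_phase1 <- function(dataset, exposures = NULL, alpha_fw = 0.05,
                          max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(dataset, "linked_dataset"))
  exposures <- exposures %||% dataset$exposures
  vars <- exposures$variable_ids
  if (length(vars) == 0L) {
    warning("no variables to screen")
    out <- empty_phase1(alpha_fw)
    return(out)
  }
  xmat <- exposures$values[dataset$tract, , drop = FALSE]  # case-level
  base <- cbind(`(Intercept)` = 1, age_dx = dataset$age_dx,
                year_dx = dataset$year_dx, exposure = 0)
  rows <- vector("list", length(vars))
  skipped <- character(0)
  for (j in seq_along(vars)) {
    xv <- xmat[, j]
    ok <- !is.na(xv)
    Xj <- base[ok, , drop = FALSE]
    Xj[, "exposure"] <- xv[ok]
    fit <- gee_logit(dataset$y[ok], Xj, dataset$tract[ok],
                     max_iter = max_iter, tol = tol)
    if (!fit$converged) {
      skipped <- c(skipped, vars[j])
      warning("GEE fit did not converge for variable ", vars[j],
              "; excluded from the screen", call. = FALSE)
      next
    }
    b <- fit$coefficients[["exposure"]]
    se <- sqrt(fit$robust_cov["exposure", "exposure"])
    rows[[j]] <- data.frame(
      variable_id = vars[j], n_used = sum(ok), beta = b, robust_se = se,
      odds_ratio = exp(b),
      ci_lo = exp(b - 1.959963984540054 * se),
      ci_hi = exp(b + 1.959963984540054 * se),
      p_value = 2 * stats::pnorm(-abs(b / se)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  m <- if (is.null(res)) 0L else nrow(res)
  if (m == 0L) {
    warning("no variable converged; empty Phase 1 result")
    return(empty_phase1(alpha_fw, skipped))
  }
  res$p_bonferroni <- bonferroni(res$p_value, m)
  res$significant <- res$p_bonferroni < alpha_fw
  res <- res[order(res$p_value, res$variable_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, m = m, skipped = skipped, alpha_fw = alpha_fw,
            class = c("phase1_result", "data.frame"))
}

empty_phase1 <- function(alpha_fw, skipped = character(0)) {
  res <- data.frame(variable_id = character(0), n_used = integer(0),
                    beta = numeric(0), robust_se = numeric(0),
                    odds_ratio = numeric(0), ci_lo = numeric(0),
                    ci_hi = numeric(0), p_value = numeric(0),
                    p_bonferroni = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  structure(res, m = 0L, skipped = skipped, alpha_fw = alpha_fw,
            class = c("phase1_result", "data.frame"))
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("Phase 1 GEE screen: %d variables tested, %d significant (family-wise %.2g)\n",
              attr(x, "m"), sum(x$significant), attr(x, "alpha_fw")))
  if (length(attr(x, "skipped"))) {
    cat(sprintf("  skipped (non-converged): %d\n", length(attr(x, "skipped"))))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write a Phase 1 result table
#'
#' @param x A `phase1_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phase1 <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
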