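#' Phase 2: Bayesian spatial re-evaluation of Phase 1 hits
#'
#' Refits every Phase 1-significant variable with the hierarchical spatial
#' logistic model of [spatial_logit()] (county-level iid and ICAR random
#' effects), on per-variable complete cases, and judges significance by the
#' equal-tailed credible interval at the Bonferroni-corrected level
#' `1 - 0.05 / n`, where `n` is the number of hit variables actually passed
#' in. The credible-interval length on the log-odds scale is carried forward
#' as the Phase 3 ranking statistic.
#'
#' @param phase1_hits A `phase1_result` (only its significant rows are used)
#'   or a character vector of variable ids.
#' @param dataset A `linked_dataset`.
#' @param geo A `geography` object (county adjacency for the ICAR prior).
#' @param priors A [spatial_priors()] list.
#' @param control An [mcmc_control()] list; per-variable seeds are derived
#'   deterministically from `control$seed`.
#' @param exposures Optional [exposure_table()] (defaults to the dataset's,
#'   which should be Z-scored).
#' @return An object of class `phase2_result`: a `data.frame` with columns
#'   `variable_id`, `n_used`, `post_mean` (log-OR per SD), `odds_ratio`,
#'   `ci_lo`, `ci_hi`, `ci_level`, `ci_length`, `significant`, `resid_var`,
#'   `ess_min`, `rhat_max`, `seed`, `diag_ok`; attributes `n_phase1`,
#'   `skipped`.
#' @export
screen_phase2 <- function(phase1_hits, dataset, geo,
                          priors = spatial_priors(),
                          control = mcmc_control(),
                          exposures = NULL) {
  stopifnot(inherits(dataset, "linked_dataset"))
  hits <- if (inherits(phase1_hits, "phase1_result")) {
    phase1_hits$variable_id[phase1_hits$significant]
  } else {
    as.character(phase1_hits)
  }
  if (length(hits) == 0L) stop("no Phase 1 hits to evaluate", call. = FALSE)
  exposures <- exposures %||% dataset$exposures
  missing_vars <- setdiff(hits, exposures$variable_ids)
  if (length(missing_vars)) {
    stop("hit variable(s) absent from exposure table: ",
         paste(utils::head(missing_vars, 10L), collapse = ", "), call. = FALSE)
  }
  icar <- build_icar(geo)
  n_phase1 <- length(hits)
  tail <- 0.05 / n_phase1 / 2
  if (tail * control$n_draws < 20) {
    stop(sprintf(
      "credible level %.7f needs n_draws >= %d (tail mass x draws >= 20); got %d",
      1 - 0.05 / n_phase1, ceiling(20 / tail), control$n_draws),
      call. = FALSE)
  }
  county_key <- dataset$county_keys[dataset$county]
  rows <- vector("list", n_phase1)
  skipped <- character(0)
  for (k in seq_along(hits)) {
    vid <- hits[k]
    xv <- exposures$values[dataset$tract, vid]
    ok <- !is.na(xv)
    X <- cbind(`(Intercept)` = 1, age_dx = dataset$age_dx[ok],
               year_dx = dataset$year_dx[ok], exposure = xv[ok])
    ctl <- control
    ctl$seed <- child_seed(control$seed, k)
    fit <- tryCatch(
      spatial_logit(dataset$y[ok], X, county_key[ok], icar,
                    priors = priors, control = ctl),
      error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, vid)
      warning("Phase 2 fit failed for ", vid, ": ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    ci <- corrected_credible_interval(fit, n_phase1)
    pm <- mean(fit$draws[, "exposure"])
    dg <- fit$diagnostics
    rows[[k]] <- data.frame(
      variable_id = vid, n_used = sum(ok), post_mean = pm,
      odds_ratio = exp(pm), ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      ci_level = ci[["level"]], ci_length = ci[["hi"]] - ci[["lo"]],
      significant = ci[["lo"]] > 0 || ci[["hi"]] < 0,
      resid_var = residual_variability(fit),
      ess_min = min(dg$ess), rhat_max = max(dg$rhat, na.rm = TRUE),
      seed = ctl$seed, diag_ok = fit$converged_ok,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("every Phase 2 fit failed", call. = FALSE)
  rownames(res) <- NULL
  structure(res, n_phase1 = n_phase1, skipped = skipped,
            class = c("phase2_result", "data.frame"))
}

#' @export
print.phase2_result <- function(x, ...) {
  cat(sprintf(
    "Phase 2 spatial screen: %d variables at credible level %.7f, %d significant\n",
    attr(x, "n_phase1"), x$ci_level[1L], sum(x$significant)))
  if (length(attr(x, "skipped"))) {
    cat(sprintf("  skipped (failed fits): %d\n", length(attr(x, "skipped"))))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Write a Phase 2 result table
#'
#' @param x A `phase2_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phase2 <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
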