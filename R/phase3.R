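#' Principal components of the variable correlation matrix
#'
#' Eigen-decomposes the Pearson correlation matrix of the given variables
#' over tracts (one row per tract, mirroring haplotype-block grouping of
#' correlated markers). Tract cells still missing for these variables are
#' mean-imputed first (count reported). Component signs are fixed so that
#' each component's largest-magnitude loading is positive, making output
#' independent of eigen-solver sign conventions.
#'
#' @param exposures An [exposure_table()] restricted to (or containing) the
#'   variables of interest.
#' @param variable_ids Variables to decompose (default: all in `exposures`).
#' @return A list of class `pca_correlation`: `loadings` (variable x
#'   component), `eigenvalues` (descending, tiny negatives clamped to 0),
#'   `cum_fraction`, `n_imputed`.
#' @export
pca_correlation <- function(exposures, variable_ids = NULL) {
  stopifnot(inherits(exposures, "exposure_table"))
  variable_ids <- variable_ids %||% exposures$variable_ids
  if (length(variable_ids) < 2L) {
    stop("principal components need at least 2 variables", call. = FALSE)
  }
  vals <- exposures$values[, variable_ids, drop = FALSE]
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(vals))) {
      mj <- is.na(vals[, j])
      if (any(mj)) vals[mj, j] <- mean(vals[, j], na.rm = TRUE)
    }
  }
  cmat <- stats::cor(vals)
  eg <- eigen(cmat, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(variable_ids, paste0("PC", seq_along(ev)))
  structure(list(loadings = load, eigenvalues = ev,
                 cum_fraction = cumsum(ev) / sum(ev),
                 n_imputed = n_imputed),
            class = "pca_correlation")
}

#' Number of components reaching a cumulative-variance target
#'
#' @param eigenvalues Non-negative eigenvalues (descending).
#' @param target Cumulative variance fraction to reach (default 0.90).
#' @return Smallest `k` whose leading components explain at least `target`
#'   of the total variance.
#' @export
retain_components <- function(eigenvalues, target = 0.90) {
  stopifnot(length(eigenvalues) >= 1L, all(eigenvalues >= 0))
  frac <- cumsum(eigenvalues) / sum(eigenvalues)
  which(frac >= target - 1e-12)[1L]
}

#' Assign each variable to its dominant retained component
#'
#' A variable belongs to the retained component on which its absolute
#' loading is largest; exact ties go to the lower component index.
#'
#' @param loadings Variable x component loading matrix.
#' @param k Number of retained components.
#' @return Named integer vector: variable id -> component index (1..k).
#' @export
assign_membership <- function(loadings, k) {
  stopifnot(k >= 1L, k <= ncol(loadings))
  sub <- abs(loadings[, seq_len(k), drop = FALSE])
  stats::setNames(apply(sub, 1L, which.max), rownames(loadings))
}

#' Pick each component's top hit by Phase 2 credible-interval tightness
#'
#' Within each component, the member variable with the smallest Phase 2
#' credible-interval length (the most significant variable) represents the
#' component. Ties prefer the larger absolute posterior effect, then the
#' lexicographically smaller variable id.
#'
#' @param membership Named vector from [assign_membership()].
#' @param phase2_results A `phase2_result` covering every member variable.
#' @return Named character vector: component (`"1"`, `"2"`, ...) -> variable
#'   id; components with no members are reported as `NA` with a warning.
#' @export
select_top_hits <- function(membership, phase2_results) {
  p2 <- as.data.frame(phase2_results)
  missing_vars <- setdiff(names(membership), p2$variable_id)
  if (length(missing_vars)) {
    stop("member variable(s) lack Phase 2 results: ",
         paste(utils::head(missing_vars, 10L), collapse = ", "), call. = FALSE)
  }
  k <- max(membership)
  out <- stats::setNames(rep(NA_character_, k), as.character(seq_len(k)))
  for (comp in seq_len(k)) {
    mem <- names(membership)[membership == comp]
    if (length(mem) == 0L) {
      warning("component ", comp, " has no member variables", call. = FALSE)
      next
    }
    sub <- p2[match(mem, p2$variable_id), , drop = FALSE]
    ord <- order(sub$ci_length, -abs(sub$post_mean), sub$variable_id)
    out[[as.character(comp)]] <- sub$variable_id[ord[1L]]
  }
  out
}

#' Phase 3: component grouping and top-hit selection
#'
#' Groups Phase 2-significant variables by principal components of their
#' tract-level correlation matrix, retains the leading components explaining
#' `target` of the variance, assigns each variable to its dominant retained
#' component (variables whose dominant component is not retained are flagged
#' unassigned), and reports each retained component's top hit — the member
#' with the tightest Phase 2 credible interval.
#'
#' @param phase2_results A `phase2_result`; only significant rows enter.
#' @param exposures [exposure_table()] holding the (Z-scored) variables.
#' @param target Cumulative variance target (default 0.90).
#' @return An object of class `component_report`: `loadings`, `eigenvalues`,
#'   `cum_fraction`, `k_retained`, `membership` (component index, `NA` =
#'   unassigned), `top_hits`, `table` (per-component summary joined to Phase
#'   2 statistics), `n_imputed`.
#' @export
phase3_components <- function(phase2_results, exposures, target = 0.90) {
  p2 <- as.data.frame(phase2_results)
  sig <- p2$variable_id[p2$significant]
  if (length(sig) < 2L) {
    stop("need at least 2 Phase 2-significant variables for components",
         call. = FALSE)
  }
  pca <- pca_correlation(exposures, sig)
  k <- retain_components(pca$eigenvalues, target)
  membership <- assign_membership(pca$loadings, k)
  assigned <- membership[!is.na(membership)]
  top <- select_top_hits(assigned, phase2_results)
  tab <- data.frame(
    component = seq_len(k),
    eigenvalue = pca$eigenvalues[seq_len(k)],
    var_fraction = pca$eigenvalues[seq_len(k)] / sum(pca$eigenvalues),
    cum_fraction = pca$cum_fraction[seq_len(k)],
    n_members = as.integer(table(factor(assigned, levels = seq_len(k)))),
    top_hit = unname(top[as.character(seq_len(k))]),
    stringsAsFactors = FALSE)
  tab <- merge(tab, p2[, c("variable_id", "post_mean", "odds_ratio",
                           "ci_lo", "ci_hi", "ci_length")],
               by.x = "top_hit", by.y = "variable_id", all.x = TRUE,
               sort = FALSE)
  tab <- tab[order(tab$component), c("component", "eigenvalue", "var_fraction",
                                     "cum_fraction", "n_members", "top_hit",
                                     "post_mean", "odds_ratio", "ci_lo",
                                     "ci_hi", "ci_length")]
  rownames(tab) <- NULL
  structure(list(loadings = pca$loadings, eigenvalues = pca$eigenvalues,
                 cum_fraction = pca$cum_fraction, k_retained = k,
                 membership = membership, top_hits = top, table = tab,
                 n_imputed = pca$n_imputed),
            class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf(
    "Phase 3 components: %d retained (%.1f%% variance), %d variables grouped, %d unassigned\n",
    x$k_retained, 100 * x$cum_fraction[x$k_retained],
    sum(!is.na(x$membership)), sum(is.na(x$membership))))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write Phase 3 outputs
#'
#' Writes the per-component summary (with top hits and their Phase 2
#' statistics) and the variable membership table.
#'
#' @param x A `component_report`.
#' @param components_path,membership_path Output TSV paths.
#' @return Invisibly, the paths.
#' @export
write_phase3 <- function(x, components_path, membership_path) {
  utils::write.table(x$table, components_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mem <- data.frame(variable_id = names(x$membership),
                    component = unname(x$membership))
  mem <- mem[order(mem$component, mem$variable_id), ]
  utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(components_path, membership_path))
}
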