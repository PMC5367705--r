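#' Default pipeline configuration
#'
#' Every statistical constant of the three-phase screen is a configuration
#' key with its standard value as default: the race restriction, the
#' variable-filter thresholds (strictly >10% missingness, strictly >95%
#' modal), the family-wise Phase 1 level 0.05, the Phase 3
#' cumulative-variance target 0.90, and the Phase 2 priors and MCMC sizes.
#'
#' @param race_restriction Race value retained by the exclusion cascade
#'   (`NULL` to skip).
#' @param miss_thresh,modal_thresh Variable-filter thresholds.
#' @param alpha_fw Phase 1 family-wise level.
#' @param pca_target Phase 3 cumulative-variance target.
#' @param priors A [spatial_priors()] list.
#' @param mcmc An [mcmc_control()] list.
#' @param seed Base seed for all stochastic steps.
#' @return A list of class `nwas_config`.
#' @export
nwas_config <- function(race_restriction = "white", miss_thresh = 0.10,
                        modal_thresh = 0.95, alpha_fw = 0.05,
                        pca_target = 0.90, priors = spatial_priors(),
                        mcmc = mcmc_control(), seed = 1L) {
  mcmc$seed <- as.integer(seed)
  structure(list(race_restriction = race_restriction,
                 miss_thresh = miss_thresh, modal_thresh = modal_thresh,
                 alpha_fw = alpha_fw, pca_target = pca_target,
                 priors = priors, mcmc = mcmc, seed = as.integer(seed)),
            class = "nwas_config")
}

#' Run the full three-phase neighborhood-wide association study
#'
#' Executes preprocess (exclusion cascade, outcome labeling, variable
#' filters, Z-scoring), linkage, Phase 1 (GEE screen), Phase 2 (Bayesian
#' spatial re-evaluation of Phase 1 hits, at the credible level computed
#' from the realized Phase 1 hit count) and Phase 3 (component grouping and
#' top hits). Each phase consumes only the previous phase's significant
#' set. If Phase 1 yields no hits the pipeline stops there with empty
#' downstream results; the partial outputs are still returned (and written).
#'
#' @param registry Registry `data.frame` (see [read_registry()]) or a path.
#' @param exposures An [exposure_table()] or a path.
#' @param geo A `geography` or `c(tract_map_path, adjacency_path)`.
#' @param config An [nwas_config()].
#' @param out_dir If non-`NULL`, per-phase TSVs and a JSON-style run
#'   manifest are written there.
#' @return An object of class `nwas_run`: `exclusion_log`, `filter_log`,
#'   `dataset`, `phase1`, `phase2`, `phase3` (the latter two `NULL` when the
#'   preceding phase found nothing), `manifest`.
#' @export
nwas_run <- function(registry, exposures, geo, config = nwas_config(),
                     out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(exposures)) exposures <- read_exposures(exposures)
  if (is.character(geo)) geo <- read_geography(geo[1L], geo[2L])

  fr <- filter_registry(registry, config$race_restriction)
  fr$records$outcome <- label_outcome(fr$records)
  fv <- filter_variables(exposures, config$miss_thresh, config$modal_thresh)
  zx <- zscore(fv$exposures)
  dataset <- link_by_key(fr$records, zx, geo)

  phase1 <- screen_phase1(dataset, alpha_fw = config$alpha_fw)
  n_hits1 <- sum(phase1$significant)
  phase2 <- NULL
  phase3 <- NULL
  if (n_hits1 > 0L) {
    phase2 <- screen_phase2(phase1, dataset, geo, priors = config$priors,
                            control = config$mcmc)
    if (sum(phase2$significant) >= 2L) {
      phase3 <- phase3_components(phase2, zx, target = config$pca_target)
    }
  }

  manifest <- list(
    version = as.character(utils::packageVersion("nwas")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = list(race_restriction = config$race_restriction,
                  miss_thresh = config$miss_thresh,
                  modal_thresh = config$modal_thresh,
                  alpha_fw = config$alpha_fw,
                  pca_target = config$pca_target,
                  mcmc = unclass(config$mcmc),
                  priors = unclass(config$priors)),
    counts = list(
      n_registry_input = attr(fr$log, "n_input"),
      n_cohort = attr(fr$log, "n_output"),
      n_aggressive = sum(dataset$y),
      n_controls = sum(dataset$y == 0L),
      n_variables_input = fv$log$n_input,
      n_variables_retained = fv$log$n_retained,
      n_phase1_tested = attr(phase1, "m"),
      n_phase1_significant = n_hits1,
      n_phase2_significant = if (is.null(phase2)) 0L else
        sum(phase2$significant),
      k_components = if (is.null(phase3)) 0L else phase3$k_retained,
      n_top_hits = if (is.null(phase3)) 0L else
        sum(!is.na(phase3$top_hits))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(fr$log),
                       file.path(out_dir, "exclusion_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flog <- data.frame(
      stage = c("input", "missingness", "modal", "retained"),
      n = c(fv$log$n_input, fv$log$n_excluded_missingness,
            fv$log$n_excluded_modal, fv$log$n_retained))
    utils::write.table(flog, file.path(out_dir, "variable_filter_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_phase1(phase1, file.path(out_dir, "phase1.tsv"))
    if (!is.null(phase2)) write_phase2(phase2, file.path(out_dir, "phase2.tsv"))
    if (!is.null(phase3)) {
      write_phase3(phase3, file.path(out_dir, "phase3_components.tsv"),
                   file.path(out_dir, "phase3_membership.tsv"))
    }
    writeLines(manifest_json(manifest), file.path(out_dir, "manifest.json"))
  }
  structure(list(exclusion_log = fr$log, filter_log = fv$log,
                 dataset = dataset, phase1 = phase1, phase2 = phase2,
                 phase3 = phase3, manifest = manifest),
            class = "nwas_run")
}

# Minimal JSON serializer for the manifest (scalars, flat lists, NULLs).
manifest_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  if (is.null(x)) return("null")
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      sprintf("%s  \"%s\": %s", pad, nm, manifest_json(x[[nm]], indent + 1)),
      character(1))
    return(sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), pad))
  }
  if (length(x) != 1L) {
    return(sprintf("[%s]", paste(vapply(x, manifest_json, character(1)),
                                 collapse = ", ")))
  }
  if (is.character(x)) sprintf("\"%s\"", x)
  else if (is.logical(x)) tolower(as.character(x))
  else format(x, digits = 15)
}

#' @export
print.nwas_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("Neighborhood-wide association study run\n")
  cat(sprintf("  cohort: %d of %d cases retained (%d aggressive, %d controls)\n",
              cts$n_cohort, cts$n_registry_input, cts$n_aggressive,
              cts$n_controls))
  cat(sprintf("  variables: %d of %d retained\n",
              cts$n_variables_retained, cts$n_variables_input))
  cat(sprintf("  phase 1: %d tested, %d significant\n",
              cts$n_phase1_tested, cts$n_phase1_significant))
  cat(sprintf("  phase 2: %d significant\n", cts$n_phase2_significant))
  cat(sprintf("  phase 3: %d components, %d top hits\n",
              cts$k_components, cts$n_top_hits))
  invisible(x)
}

#' @export
summary.nwas_run <- function(object, ...) {
  print(object)
  if (!is.null(object$phase3)) {
    cat("\nTop hits:\n")
    print.data.frame(object$phase3$table, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Validate pipeline input files
#'
#' Checks schema, key linkage (every case tract present in the exposure
#' table and the tract-to-county map) and the Phase 2 precondition (every
#' county holding cases has at least one aggressive and one non-aggressive
#' case among complete records).
#'
#' @param registry_path,exposures_path,tract_map_path,adjacency_path File
#'   paths.
#' @return A character vector report; first element `"OK"` when all checks
#'   pass, otherwise one message per failure.
#' @export
validate_inputs <- function(registry_path, exposures_path, tract_map_path,
                            adjacency_path) {
  report <- character(0)
  reg <- tryCatch(read_registry(registry_path), error = function(e) e)
  if (inherits(reg, "error")) {
    return(paste("registry:", conditionMessage(reg)))
  }
  exp <- tryCatch(read_exposures(exposures_path), error = function(e) e)
  if (inherits(exp, "error")) {
    return(paste("exposures:", conditionMessage(exp)))
  }
  geo <- tryCatch(read_geography(tract_map_path, adjacency_path),
                  error = function(e) e)
  if (inherits(geo, "error")) {
    return(paste("geography:", conditionMessage(geo)))
  }
  unmatched <- setdiff(unique(reg$tract_key), exp$tract_keys)
  if (length(unmatched)) {
    report <- c(report, paste("linkage failure: registry tract(s) missing",
                              "from exposures:",
                              paste(utils::head(unmatched, 5L),
                                    collapse = ", ")))
  }
  unmapped <- setdiff(exp$tract_keys, names(geo$tract_to_county))
  if (length(unmapped)) {
    report <- c(report, paste("linkage failure: exposure tract(s) missing",
                              "from geography:",
                              paste(utils::head(unmapped, 5L),
                                    collapse = ", ")))
  }
  complete <- !is.na(reg$stage) & !is.na(reg$gleason)
  if (any(complete)) {
    cc <- reg[complete, ]
    cc <- cc[cc$tract_key %in% names(geo$tract_to_county), ]
    if (nrow(cc)) {
      county <- unname(geo$tract_to_county[cc$tract_key])
      agg <- label_outcome(cc) == "aggressive"
      byc <- table(county, factor(agg, levels = c(FALSE, TRUE)))
      bad <- rownames(byc)[byc[, 1L] == 0L | byc[, 2L] == 0L]
      if (length(bad)) {
        report <- c(report,
                    paste("phase 2 precondition: county/counties without",
                          "both a case and a control:",
                          paste(utils::head(bad, 10L), collapse = ", ")))
      }
    }
  }
  if (length(report) == 0L) "OK" else report
}
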