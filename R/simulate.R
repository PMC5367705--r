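#' Configuration for the synthetic geospatial screening data generator
#'
#' The generator emulates the structure the screening pipeline assumes:
#' nested geography (a rook-adjacency county grid containing tracts),
#' block-correlated tract-level exposures with county-level spatial
#' smoothness, per-tract case counts, and a case-level logistic outcome
#' driven by a small set of planted per-SD exposure effects plus county-level
#' iid and ICAR-structured random effects. Defaults mirror a mid-Atlantic
#' state cancer-registry setting: a 6 x 5 county grid, 10 tracts per county,
#' ~25 cases per tract, baseline log-odds -2.4 (about 8% aggressive cases),
#' county effect SDs sigma_v = 0.3 (unstructured) and sigma_u = 0.5
#' (spatial), diagnosis ages centered at 69.2 (SD 9.4), diagnosis years
#' 1995-2005.
#'
#' @param n_county_rows,n_county_cols County grid dimensions.
#' @param tracts_per_county Tracts nested in each county.
#' @param n_variables Total number of area-level variables.
#' @param blocks Integer vector of correlation-block sizes (must sum to at
#'   most `n_variables`; remaining variables are unblocked noise).
#' @param block_rho Within-block correlation of block variables.
#' @param spatial_sd Share of each variable's unit SD coming from a smooth
#'   county-level ICAR field (`spatial_sd^2 + block_rho <= 1`).
#' @param miss_rate Fraction of tract cells set missing, per variable.
#' @param planted_effects Named numeric vector: variable id -> per-SD log
#'   odds ratio on the outcome.
#' @param sigma_v,sigma_u County random-effect SDs (iid, spatial).
#' @param baseline Baseline log-odds of an aggressive case.
#' @param beta_age,beta_year Covariate log-odds per year.
#' @param cases_per_tract Mean of the per-tract Poisson case count (at least
#'   1 case is placed per tract).
#' @param age_mean,age_sd,year_range Covariate generating parameters.
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_county_rows = 6L, n_county_cols = 5L,
                       tracts_per_county = 10L, n_variables = 50L,
                       blocks = c(10L, 10L, 10L), block_rho = 0.9,
                       spatial_sd = 0.25, miss_rate = 0,
                       planted_effects = c(v0001 = 0.3, v0011 = 0.3,
                                           v0021 = 0.3),
                       sigma_v = 0.3, sigma_u = 0.5, baseline = -2.4,
                       beta_age = 0.01, beta_year = 0,
                       cases_per_tract = 25, age_mean = 69.2, age_sd = 9.4,
                       year_range = c(1995L, 2005L), seed = 1L) {
  stopifnot(sum(blocks) <= n_variables,
            block_rho >= 0, block_rho < 1,
            spatial_sd >= 0, spatial_sd^2 + block_rho <= 1,
            miss_rate >= 0, miss_rate < 1,
            sigma_v >= 0, sigma_u >= 0, cases_per_tract > 0)
  structure(list(n_county_rows = as.integer(n_county_rows),
                 n_county_cols = as.integer(n_county_cols),
                 tracts_per_county = as.integer(tracts_per_county),
                 n_variables = as.integer(n_variables),
                 blocks = as.integer(blocks), block_rho = block_rho,
                 spatial_sd = spatial_sd, miss_rate = miss_rate,
                 planted_effects = planted_effects,
                 sigma_v = sigma_v, sigma_u = sigma_u, baseline = baseline,
                 beta_age = beta_age, beta_year = beta_year,
                 cases_per_tract = cases_per_tract,
                 age_mean = age_mean, age_sd = age_sd,
                 year_range = as.integer(year_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a rook-adjacency county-grid geography
#'
#' Counties sit on an `n_county_rows` x `n_county_cols` grid with rook
#' (edge-sharing) adjacency; each holds `tracts_per_county` tracts. Keys
#' follow the FIPS convention: 5-character county key (2-char state + 3-char
#' county number), 11-character tract key whose first 5 characters are the
#' county key.
#'
#' @param config A [sim_config()].
#' @return A `geography` object.
#' @export
make_geography <- function(config) {
  nr <- config$n_county_rows
  nc <- config$n_county_cols
  J <- nr * nc
  county_keys <- sprintf("42%03d", seq_len(J))
  edges <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      j <- (r - 1L) * nc + c
      if (c < nc) edges[[length(edges) + 1L]] <- c(county_keys[j],
                                                   county_keys[j + 1L])
      if (r < nr) edges[[length(edges) + 1L]] <- c(county_keys[j],
                                                   county_keys[j + nc])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2L)
  tract_keys <- as.vector(vapply(county_keys, function(ck)
    sprintf("%s%06d", ck, seq_len(config$tracts_per_county)),
    character(config$tracts_per_county)))
  t2c <- stats::setNames(substr(tract_keys, 1L, 5L), tract_keys)
  geography(t2c, edges)
}

#' Generate block-correlated, spatially smooth tract exposures
#'
#' Each variable is built as
#' `sqrt(rho) * block factor (shared within its correlation block, iid over
#' tracts) + spatial_sd * county ICAR field (variable-specific) + iid tract
#' noise`, with the three variance shares summing to 1 so the population
#' within-block correlation equals `block_rho` and every variable has unit
#' variance. Variables beyond the configured blocks carry no block factor.
#' Missing cells are injected completely at random at `miss_rate`.
#'
#' @param config A [sim_config()].
#' @param geo Geography from [make_geography()] (defaults to generating it).
#' @return An [exposure_table()] with a `"truth"` attribute recording block
#'   membership per variable.
#' @export
make_exposures <- function(config, geo = make_geography(config)) {
  set.seed(child_seed(config$seed, 1L))
  tract_keys <- names(geo$tract_to_county)
  n_tract <- length(tract_keys)
  m <- config$n_variables
  county_idx <- match(unname(geo$tract_to_county), geo$counties)
  icar <- build_icar(geo)
  block_of <- rep(0L, m)
  if (length(config$blocks)) {
    block_of[seq_len(sum(config$blocks))] <-
      rep(seq_along(config$blocks), config$blocks)
  }
  rho <- config$block_rho
  tau <- config$spatial_sd
  vals <- matrix(NA_real_, n_tract, m)
  block_factor <- matrix(stats::rnorm(n_tract * length(config$blocks)),
                         n_tract)
  for (j in seq_len(m)) {
    b <- block_of[j]
    shared <- if (b > 0L) sqrt(rho) * block_factor[, b] else 0
    e_sd <- sqrt(1 - tau^2 - if (b > 0L) rho else 0)
    spatial <- if (tau > 0) ricar(icar, 1)[county_idx] * tau else 0
    vals[, j] <- shared + spatial + stats::rnorm(n_tract, 0, e_sd)
  }
  if (config$miss_rate > 0) {
    mask <- matrix(stats::runif(n_tract * m) < config$miss_rate, n_tract)
    vals[mask] <- NA_real_
  }
  ids <- sprintf("v%04d", seq_len(m))
  out <- exposure_table(vals, tract_keys, ids)
  attr(out, "truth") <- data.frame(variable_id = ids, block = block_of,
                                   stringsAsFactors = FALSE)
  out
}

#' Generate a synthetic case registry from the outcome model
#'
#' Places a Poisson number of cases in every tract (minimum one), draws age
#' and diagnosis year, simulates county-level iid and ICAR random effects,
#' and draws each case's aggressiveness from the logistic model
#' `logit p = baseline + beta_age * (age - age_mean) + beta_year * (year -
#' mid-year) + sum(planted log-ORs x exposure) + V_county + U_county`.
#' Tumor stage and Gleason grade are then back-filled deterministically so
#' that [label_outcome()] reproduces the simulated outcome exactly
#' (aggressive: stage 3-4 and Gleason 7-10; control: a pattern violating the
#' rule). Counties that come out with all cases or all controls are redrawn
#' (bounded retries) so the Phase 2 case/control precondition holds by
#' construction.
#'
#' @param config A [sim_config()].
#' @param geo,exposures Geography and exposures (defaults: generate).
#' @return A registry `data.frame` (see [read_registry()]) with a `"truth"`
#'   attribute: the planted effect map, the county effect vectors and the
#'   outcome probabilities used.
#' @export
make_registry <- function(config, geo = make_geography(config),
                          exposures = make_exposures(config, geo)) {
  set.seed(child_seed(config$seed, 2L))
  tract_keys <- names(geo$tract_to_county)
  n_tract <- length(tract_keys)
  county_idx <- match(unname(geo$tract_to_county), geo$counties)
  icar <- build_icar(geo)
  J <- length(geo$counties)

  n_cases <- pmax(1L, stats::rpois(n_tract, config$cases_per_tract))
  tract_i <- rep(seq_len(n_tract), n_cases)
  n <- length(tract_i)
  county_i <- county_idx[tract_i]
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 40),
                    99))
  year <- sample(seq(config$year_range[1L], config$year_range[2L]), n,
                 replace = TRUE)

  V <- stats::rnorm(J, 0, config$sigma_v)
  U <- ricar(icar, config$sigma_u)

  pe <- config$planted_effects
  pe <- pe[names(pe) %in% exposures$variable_ids]
  xb <- if (length(pe)) {
    xv <- exposures$values[, names(pe), drop = FALSE]
    xv[is.na(xv)] <- 0                      # planted effect acts through observed value
    drop(xv[tract_i, , drop = FALSE] %*% pe)
  } else 0
  midyear <- mean(config$year_range)
  eta <- config$baseline + config$beta_age * (age - config$age_mean) +
    config$beta_year * (year - midyear) + xb + V[county_i] + U[county_i]
  prob <- stats::plogis(eta)
  y <- stats::rbinom(n, 1L, prob)

  # enforce >=1 case and >=1 control per county by redrawing its outcomes
  county_balance <- function() {
    cnt <- rowsum(y, factor(county_i, levels = seq_len(J)))[, 1L]
    tot <- tabulate(county_i, nbins = J)
    which(tot > 0L & (cnt == 0 | cnt == tot))
  }
  for (tries in 1:100) {
    bad <- county_balance()
    if (!length(bad)) break
    for (j in bad) {
      idx <- which(county_i == j)
      y[idx] <- stats::rbinom(length(idx), 1L, prob[idx])
    }
  }
  bad <- county_balance()
  if (length(bad)) {
    # last resort: flip the most extreme-probability case deterministically
    for (j in bad) {
      idx <- which(county_i == j)
      flip <- if (y[idx[1L]] == 1L) idx[which.min(prob[idx])] else
        idx[which.max(prob[idx])]
      y[flip] <- 1L - y[flip]
    }
  }

  stage <- ifelse(y == 1L, 3L + (seq_len(n) %% 2L), 1L + (seq_len(n) %% 2L))
  gleason <- ifelse(y == 1L, 7L + (seq_len(n) %% 4L), 4L + (seq_len(n) %% 3L))
  records <- data.frame(
    case_id = sprintf("C%07d", seq_len(n)),
    tract_key = tract_keys[tract_i],
    address_type = "street",
    age_dx = as.numeric(age),
    year_dx = as.numeric(year),
    stage = as.numeric(stage),
    gleason = as.numeric(gleason),
    race = "white",
    stringsAsFactors = FALSE)
  attr(records, "truth") <- list(planted_effects = pe, V = V, U = U,
                                 prob = prob, y = y)
  records
}

#' Generate and optionally write a full synthetic dataset
#'
#' @param config A [sim_config()].
#' @param out_dir If non-`NULL`, write `registry.tsv`, `exposures.tsv`,
#'   `tract_map.tsv`, `adjacency.txt` and `truth.tsv` there.
#' @return A list `registry`, `exposures`, `geography`, `truth` (planted
#'   effect map as a data.frame).
#' @export
simulate_nwas <- function(config = sim_config(), out_dir = NULL) {
  geo <- make_geography(config)
  exposures <- make_exposures(config, geo)
  registry <- make_registry(config, geo, exposures)
  truth <- data.frame(
    variable_id = names(config$planted_effects),
    log_or_per_sd = unname(config$planted_effects),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    reg <- registry
    utils::write.table(reg, file.path(out_dir, "registry.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    write_exposures(exposures, file.path(out_dir, "exposures.tsv"))
    write_geography(geo, file.path(out_dir, "tract_map.tsv"),
                    file.path(out_dir, "adjacency.txt"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(registry = registry, exposures = exposures, geography = geo,
       truth = truth)
}
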