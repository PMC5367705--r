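#' Deterministic exact-count fixture for the preprocessing cascade
#'
#' Builds, without any sampling, a registry and an exposure table whose
#' preprocessing tallies equal a stated cascade specification exactly: every
#' excluded record violates exactly one exclusion rule, every filtered
#' variable fails exactly one filter stage, and the surviving records carry
#' stage/Gleason values realizing the stated aggressive/control split. The
#' default specification reproduces the published Pennsylvania prostate
#' cancer cohort tallies: 80,575 Caucasian cases, of which 112 P.O. Box,
#' 3,371 missing stage/grade, 2 missing age, 4 missing year (77,086
#' retained; 6,416 aggressive vs 70,670 controls), and 24,634 census
#' variables of which 8,092 fail the >10% missingness filter and 1,879 the
#' >95% modal filter (14,663 retained).
#'
#' @param n_total Caucasian registry records before exclusions.
#' @param n_po_box,n_missing_stage_grade,n_missing_age,n_missing_year
#'   Per-rule exclusion counts (disjoint).
#' @param n_aggressive Aggressive cases among the survivors.
#' @param n_variables Total exposure variables.
#' @param n_fail_missing Variables failing the missingness filter.
#' @param n_fail_modal Variables failing the modal filter.
#' @param n_other_race Additional non-Caucasian records (excluded by the
#'   race restriction; default 0, matching tallies that start from the
#'   race-restricted cohort).
#' @param n_tracts Number of fixture tracts (cases cycle over them).
#' @return A list `registry` (data.frame), `exposures`
#'   ([exposure_table()]), `geography` (a small 2 x 2 county-grid
#'   `geography` covering the fixture tracts).
#' @export
make_exact_count_fixture <- function(n_total = 80575L,
                                     n_po_box = 112L,
                                     n_missing_stage_grade = 3371L,
                                     n_missing_age = 2L,
                                     n_missing_year = 4L,
                                     n_aggressive = 6416L,
                                     n_variables = 24634L,
                                     n_fail_missing = 8092L,
                                     n_fail_modal = 1879L,
                                     n_other_race = 0L,
                                     n_tracts = 20L) {
  n_excl <- n_po_box + n_missing_stage_grade + n_missing_age + n_missing_year
  if (n_excl > n_total) stop("exclusion counts exceed total", call. = FALSE)
  n_retained <- n_total - n_excl
  if (n_aggressive > n_retained) stop("aggressive count exceeds cohort",
                                      call. = FALSE)
  if (n_fail_missing + n_fail_modal > n_variables) {
    stop("filtered variable counts exceed total", call. = FALSE)
  }
  if (n_tracts < 10L) stop("need >= 10 tracts for distinct values",
                           call. = FALSE)

  cfg <- sim_config(n_county_rows = 2L, n_county_cols = 2L,
                    tracts_per_county = ceiling(n_tracts / 4))
  geo <- make_geography(cfg)
  tract_keys <- sort(names(geo$tract_to_county))[seq_len(n_tracts)]

  n_rows <- n_total + n_other_race
  base_age <- 65
  base_year <- 2000
  registry <- data.frame(
    case_id = sprintf("F%07d", seq_len(n_rows)),
    tract_key = rep_len(tract_keys, n_rows),
    address_type = "street",
    age_dx = rep(base_age, n_rows),
    year_dx = rep(base_year, n_rows),
    stage = rep(2, n_rows),
    gleason = rep(5, n_rows),
    race = "white",
    stringsAsFactors = FALSE)

  i <- 0L
  take <- function(k) { out <- i + seq_len(k); i <<- i + k; out }
  agg_rows <- take(n_aggressive)
  registry$stage[agg_rows] <- rep_len(c(3, 4), n_aggressive)
  registry$gleason[agg_rows] <- rep_len(7:10, n_aggressive)
  take(n_retained - n_aggressive)            # controls keep stage 2 / gleason 5
  registry$address_type[take(n_po_box)] <- "po_box"
  sg <- take(n_missing_stage_grade)
  registry$stage[sg] <- NA_real_             # half also lose gleason
  registry$gleason[sg[seq_len(n_missing_stage_grade %/% 2)]] <- NA_real_
  registry$age_dx[take(n_missing_age)] <- NA_real_
  registry$year_dx[take(n_missing_year)] <- NA_real_
  if (n_other_race > 0L) registry$race[take(n_other_race)] <- "other"

  # exposure matrix: row pattern 1..n_tracts gives distinct values (modal
  # fraction 1/n <= 0.95); failing variables are overwritten
  n_miss_cells <- floor(n_tracts * 0.10) + 1L  # strictly > 10% missing
  vals <- matrix(rep(seq_len(n_tracts), n_variables), n_tracts)
  if (n_fail_missing > 0L) {
    vals[seq_len(n_miss_cells), seq_len(n_fail_missing)] <- NA_real_
  }
  if (n_fail_modal > 0L) {
    vals[, n_fail_missing + seq_len(n_fail_modal)] <- 7  # constant: modal 100%
  }
  exposures <- exposure_table(vals, tract_keys,
                              sprintf("c%05d", seq_len(n_variables)))
  list(registry = registry, exposures = exposures, geography = geo)
}
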