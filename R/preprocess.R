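#' Registry exclusion cascade
#'
#' Applies the cohort-definition rules in a fixed order with first-match-wins
#' attribution, so per-rule exclusion counts are disjoint and sum exactly:
#' (1) restrict to the specified race group; (2) drop P.O. Box addresses;
#' (3) drop cases missing tumor stage or Gleason grade; (4) drop cases missing
#' age at diagnosis; (5) drop cases missing year of diagnosis.
#'
#' @param records Registry `data.frame` from [read_registry()].
#' @param race_restriction Race value to retain, or `NULL` to skip rule (1).
#' @return A list with `records` (retained rows) and `log`, an
#'   `exclusion_log`: a `data.frame` of `(rule, n_excluded)` plus attributes
#'   `n_input`, `n_output`, and `excluded_ids` (list of case-id vectors).
#' @export
filter_registry <- function(records, race_restriction = NULL) {
  n_input <- nrow(records)
  race_rule <- if (is.null(race_restriction)) {
    function(d) rep(FALSE, nrow(d))
  } else {
    function(d) is.na(d$race) | d$race != race_restriction
  }
  rules <- list(
    race        = race_rule,
    po_box      = function(d) !is.na(d$address_type) & d$address_type == "po_box",
    stage_grade = function(d) is.na(d$stage) | is.na(d$gleason),
    age         = function(d) is.na(d$age_dx),
    year        = function(d) is.na(d$year_dx)
  )
  assigned <- rep(NA_character_, n_input)
  for (rn in names(rules)) {
    hit <- rules[[rn]](records) & is.na(assigned)
    assigned[hit] <- rn
  }
  counts <- vapply(names(rules), function(rn) sum(assigned == rn, na.rm = TRUE),
                   integer(1))
  excluded_ids <- lapply(names(rules), function(rn)
    records$case_id[!is.na(assigned) & assigned == rn])
  names(excluded_ids) <- names(rules)
  keep <- is.na(assigned)
  log <- data.frame(rule = names(rules), n_excluded = unname(counts),
                    stringsAsFactors = FALSE)
  attr(log, "n_input") <- n_input
  attr(log, "n_output") <- sum(keep)
  attr(log, "excluded_ids") <- excluded_ids
  class(log) <- c("exclusion_log", "data.frame")
  list(records = records[keep, , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %d -> %d cases\n",
              attr(x, "n_input"), attr(x, "n_output")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Label case aggressiveness
#'
#' A case is aggressive when tumor stage is 3 or 4 AND Gleason grade is 7 or
#' higher; all other stage/grade combinations are non-aggressive (controls).
#' Stage and grade must be non-missing (guaranteed after [filter_registry()]).
#'
#' @param records Registry `data.frame` (or any data.frame with numeric
#'   `stage` and `gleason` columns).
#' @return Character vector, `"aggressive"` or `"non_aggressive"`, one per row.
#' @export
label_outcome <- function(records) {
  if (anyNA(records$stage) || anyNA(records$gleason)) {
    stop("label_outcome requires non-missing stage and gleason; ",
         "run filter_registry first", call. = FALSE)
  }
  ifelse(records$stage >= 3 & records$gleason >= 7,
         "aggressive", "non_aggressive")
}

#' Filter area-level variables by missingness and modal concentration
#'
#' Stage (a) drops variables whose missing fraction is strictly greater than
#' `miss_thresh`; stage (b), evaluated only on stage-(a) survivors, drops
#' variables whose single most frequent non-missing value accounts for
#' strictly more than `modal_thresh` of non-missing entries. Boundary values
#' (exactly 10% missing, exactly 95% modal) are retained.
#'
#' @param exposures An [exposure_table()].
#' @param miss_thresh Missing-fraction threshold (default 0.10).
#' @param modal_thresh Modal-fraction threshold (default 0.95).
#' @return A list with `exposures` (filtered table) and `log`, a
#'   `variable_filter_log` list: `n_input`, `n_excluded_missingness`,
#'   `n_excluded_modal`, `n_retained`, `retained`, `dropped_missingness`,
#'   `dropped_modal`.
#' @export
filter_variables <- function(exposures, miss_thresh = 0.10,
                             modal_thresh = 0.95) {
  stopifnot(inherits(exposures, "exposure_table"))
  m <- length(exposures$variable_ids)
  if (m == 0L) stop("empty exposure table", call. = FALSE)
  miss_frac <- colMeans(exposures$missing_mask)
  drop_miss <- miss_frac > miss_thresh
  modal_frac <- rep(NA_real_, m)
  surv <- which(!drop_miss)
  for (j in surv) {
    v <- exposures$values[!exposures$missing_mask[, j], j]
    if (length(v) == 0L) { modal_frac[j] <- 1; next }
    modal_frac[j] <- max(tabulate(match(v, unique(v)))) / length(v)
  }
  drop_modal <- !drop_miss & modal_frac > modal_thresh
  keep <- !drop_miss & !drop_modal
  log <- structure(list(
    n_input = m,
    n_excluded_missingness = sum(drop_miss),
    n_excluded_modal = sum(drop_modal),
    n_retained = sum(keep),
    retained = exposures$variable_ids[keep],
    dropped_missingness = exposures$variable_ids[drop_miss],
    dropped_modal = exposures$variable_ids[drop_modal]),
    class = "variable_filter_log")
  out <- exposure_table(exposures$values[, keep, drop = FALSE],
                        exposures$tract_keys,
                        exposures$variable_ids[keep],
                        exposures$variable_meta)
  list(exposures = out, log = log)
}

#' @export
print.variable_filter_log <- function(x, ...) {
  cat(sprintf(
    "Variable filter: %d input; %d dropped for missingness, %d for modal concentration; %d retained\n",
    x$n_input, x$n_excluded_missingness, x$n_excluded_modal, x$n_retained))
  invisible(x)
}

#' Z-score exposures across tracts
#'
#' Standardizes each variable over the tracts where it is observed to mean 0
#' and sample standard deviation 1 (denominator n-1), so effect estimates
#' downstream are per standard deviation of the tract-level variable and
#' comparable across variables. Each tract is weighted once, regardless of how
#' many cases it holds. Missing entries stay missing.
#'
#' @param exposures An [exposure_table()].
#' @return A standardized [exposure_table()].
#' @export
zscore <- function(exposures) {
  stopifnot(inherits(exposures, "exposure_table"))
  vals <- exposures$values
  mu <- colMeans(vals, na.rm = TRUE)
  sd <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sd) | sd == 0
  if (any(degenerate)) {
    stop("constant (or all-missing) variable(s) cannot be Z-scored: ",
         paste(utils::head(exposures$variable_ids[degenerate], 10L),
               collapse = ", "),
         "; run filter_variables first", call. = FALSE)
  }
  vals <- sweep(sweep(vals, 2L, mu, "-"), 2L, sd, "/")
  exposure_table(vals, exposures$tract_keys, exposures$variable_ids,
                 exposures$variable_meta)
}
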