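test_that("exclusion cascade attributes each record to its first matching rule", {
  rec <- rbind(
    make_records(3),                                        # clean
    make_records(1, address_type = "po_box", age_dx = NA),  # po_box wins
    make_records(1, stage = NA, year_dx = NA),              # stage_grade wins
    make_records(1, age_dx = NA),
    make_records(1, race = "other"))
  rec$case_id <- sprintf("c%03d", seq_len(nrow(rec)))
  out <- filter_registry(rec, "white")
  counts <- stats::setNames(out$log$n_excluded, out$log$rule)
  expect_equal(counts[["race"]], 1L)
  expect_equal(counts[["po_box"]], 1L)
  expect_equal(counts[["stage_grade"]], 1L)
  expect_equal(counts[["age"]], 1L)
  expect_equal(counts[["year"]], 0L)
  expect_equal(attr(out$log, "n_output"), 3L)
  expect_equal(attr(out$log, "n_input") - sum(out$log$n_excluded),
               attr(out$log, "n_output"))

  # idempotent: second pass excludes nothing
  again <- filter_registry(out$records, "white")
  expect_equal(sum(again$log$n_excluded), 0L)
  expect_identical(again$records, out$records)

  # empty input is legal
  nothing <- filter_registry(rec[0, ], "white")
  expect_equal(attr(nothing$log, "n_output"), 0L)
  expect_true(all(nothing$log$n_excluded == 0L))
})

test_that("aggressiveness requires both high stage and high grade", {
  rec <- make_records(4, stage = c(3, 4, 2, 3), gleason = c(7, 6, 9, 10))
  expect_equal(label_outcome(rec),
               c("aggressive", "non_aggressive", "non_aggressive",
                 "aggressive"))
  expect_error(label_outcome(make_records(1, stage = NA)), "non-missing")

  # labeling partitions any filtered cohort
  cfg <- sim_config(n_county_rows = 2L, n_county_cols = 2L,
                    tracts_per_county = 2L, n_variables = 2L,
                    blocks = integer(0), planted_effects = numeric(0),
                    cases_per_tract = 10, seed = 5L)
  reg <- make_registry(cfg)
  kept <- filter_registry(reg, "white")$records
  lab <- label_outcome(kept)
  expect_equal(sum(lab == "aggressive") + sum(lab == "non_aggressive"),
               nrow(kept))
})

test_that("variable filters use strict thresholds and disjoint stages", {
  # 10 tracts: v_miss 20% missing; v_edge exactly 10% missing (retained);
  # v_const constant (modal 100%); v_ok distinct values
  vals <- cbind(v_miss = c(NA, NA, 3:10),
                v_edge = c(NA, 2:10),
                v_const = rep(7, 10),
                v_ok = 1:10)
  ex <- exposure_table(vals, sprintf("t%02d", 1:10), colnames(vals))
  out <- filter_variables(ex)
  expect_equal(sort(out$log$retained), c("v_edge", "v_ok"))
  expect_equal(out$log$n_excluded_missingness, 1L)
  expect_equal(out$log$n_excluded_modal, 1L)
  expect_equal(out$log$n_retained,
               out$log$n_input - out$log$n_excluded_missingness -
                 out$log$n_excluded_modal)
})

test_that("scaled-down exact-count fixture reproduces its cascade spec", {
  fx <- make_exact_count_fixture(
    n_total = 1000L, n_po_box = 10L, n_missing_stage_grade = 40L,
    n_missing_age = 2L, n_missing_year = 3L, n_aggressive = 80L,
    n_variables = 300L, n_fail_missing = 90L, n_fail_modal = 25L,
    n_other_race = 7L)
  out <- filter_registry(fx$registry, "white")
  counts <- stats::setNames(out$log$n_excluded, out$log$rule)
  expect_equal(unname(counts[c("race", "po_box", "stage_grade", "age",
                               "year")]),
               c(7L, 10L, 40L, 2L, 3L))
  expect_equal(attr(out$log, "n_output"), 945L)
  expect_equal(sum(label_outcome(out$records) == "aggressive"), 80L)
  fv <- filter_variables(fx$exposures)
  expect_equal(fv$log$n_excluded_missingness, 90L)
  expect_equal(fv$log$n_excluded_modal, 25L)
  expect_equal(fv$log$n_retained, 185L)
  # fixture satisfies downstream preconditions: linkage + zscore
  zx <- zscore(fv$exposures)
  expect_s3_class(link_by_key(cbind(out$records,
                                    outcome = label_outcome(out$records)),
                              zx, fx$geography),
                  "linked_dataset")
})

test_that("zscore standardizes each variable over observed tracts", {
  ex <- exposure_table(cbind(a = c(1, 2, 3)), c("t1", "t2", "t3"), "a")
  z <- zscore(ex)
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))

  expect_error(zscore(exposure_table(cbind(k = rep(2, 3)),
                                     c("t1", "t2", "t3"), "k")),
               "constant")

  # post-condition on a random table with missingness, against direct
  # recomputation
  set.seed(99)
  vals <- matrix(rnorm(500), 50, 10,
                 dimnames = list(NULL, sprintf("v%02d", 1:10)))
  vals[sample(500, 30)] <- NA
  ex2 <- exposure_table(vals, sprintf("t%02d", 1:50), colnames(vals))
  z2 <- zscore(ex2)
  for (j in 1:10) {
    obs <- z2$values[, j][!is.na(z2$values[, j])]
    expect_equal(mean(obs), 0, tolerance = 1e-12)
    expect_equal(stats::sd(obs), 1, tolerance = 1e-12)
  }
  expect_identical(unname(is.na(z2$values)), unname(is.na(vals)))
})
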