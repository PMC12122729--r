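test_that("cohort spec enforces the one-year-ahead pairing", {
  expect_error(cohort_spec(2017, 2019), "base_year \\+ 1")
  s <- cohort_spec(2017)
  expect_identical(s$performance_year, 2018L)
})

test_that("eligibility applies age, enrollment, decedent and exclusion rules", {
  spec <- cohort_spec(2017)
  ok <- make_beneficiaries("ok", birth_year = 1952L)          # 65 at baseline
  too_young <- make_beneficiaries("young", birth_year = 1953L) # 64 at baseline
  partc <- make_beneficiaries("pc", part_c = TRUE)
  esrd <- make_beneficiaries("es", esrd = TRUE)
  dual <- make_beneficiaries("du", dual = TRUE)

  ## died June of the performance year, enrolled every month while living
  dec <- make_beneficiaries("dec", death_date = "2018-06-15")
  dec$part_a_months[dec$year == 2018] <- 6L
  dec$part_b_months[dec$year == 2018] <- 6L
  dec$part_a_months[dec$year == 2019] <- 0L
  dec$part_b_months[dec$year == 2019] <- 0L

  ## died June of the performance year but dropped Part B in March
  dec_gap <- make_beneficiaries("decgap", death_date = "2018-06-15")
  dec_gap$part_a_months[dec_gap$year == 2018] <- 6L
  dec_gap$part_b_months[dec_gap$year == 2018] <- 3L

  ## died in the base year: no performance-year outcome exists
  dec_base <- make_beneficiaries("decbase", death_date = "2017-09-15")
  dec_base$part_a_months[dec_base$year == 2017] <- 9L
  dec_base$part_b_months[dec_base$year == 2017] <- 9L
  dec_base$part_a_months[dec_base$year >= 2018] <- 0L
  dec_base$part_b_months[dec_base$year >= 2018] <- 0L

  ## partial enrollment without death
  gap <- make_beneficiaries("gap")
  gap$part_b_months[gap$year == 2017] <- 11L

  all_b <- rbind(ok, too_young, partc, esrd, dual, dec, dec_gap, dec_base, gap)
  expect_identical(apply_eligibility(all_b, spec), c("dec", "du", "ok"))

  ## eligibility is monotone in enrollment: restoring gap's months adds it
  gap_full <- gap; gap_full$part_b_months <- 12L
  more <- rbind(ok, dual, dec, gap_full)
  expect_true("gap" %in% apply_eligibility(more, spec))
})

test_that("ids lacking rows for both years are excluded with a warning", {
  spec <- cohort_spec(2017)
  b <- rbind(make_beneficiaries("full"),
             make_beneficiaries("short", years = 2017L))
  expect_warning(out <- apply_eligibility(b, spec), "lack rows")
  expect_identical(out, "full")
})

test_that("the parity split is an exhaustive, seed-deterministic partition", {
  ids <- sprintf("id%05d", 1:100000)
  a <- split_train_study(ids, split_seed = 42L)
  b <- split_train_study(sample(ids), split_seed = 42L)  # order-insensitive
  expect_identical(a, b)
  expect_setequal(a$beneficiary_id, ids)
  expect_true(all(a$arm %in% c("training", "study")))

  ## training fraction within 3 binomial SE of 1/2
  frac <- mean(a$arm == "training")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(ids)))

  c2 <- split_train_study(ids, split_seed = 43L)
  expect_false(identical(a$arm, c2$arm))
  expect_error(split_train_study(character(), 1L), "empty")
})

test_that("arm assignment is independent of utilization", {
  run_pop <- generate_population(default_generator_params(20000L, seed = 21L))
  ids <- unique(run_pop$beneficiaries$beneficiary_id)
  arms <- split_train_study(ids, split_seed = 22L)
  y <- count_admissions(run_pop$claims, arms$beneficiary_id, 2018L)
  r <- cor(as.numeric(arms$arm == "training"), y)
  expect_lt(abs(r), 3 / sqrt(length(ids)))
})

test_that("admission counts sum inpatient claims of the requested year only", {
  cl <- rbind(
    make_claims("a", 2018L, "inpatient", admissions = 1L),
    make_claims("a", 2018L, "inpatient", admissions = 1L),
    make_claims("a", 2018L, "inpatient", admissions = 1L),
    make_claims("a", 2017L, "inpatient", admissions = 1L),   # out of year
    make_claims("b", 2018L, "outpatient", codes = "D001A"),  # not an admission
    make_claims("c", 2018L, "inpatient", admissions = 1L)
  )
  y <- count_admissions(cl, c("a", "b", "c", "d"), 2018L)
  expect_identical(y, c(a = 3L, b = 0L, c = 1L, d = 0L))
})

test_that("admission counts match a hand count on a mixed fixture", {
  set.seed(13)
  ids <- paste0("p", 1:10)
  rows <- lapply(ids, function(id) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    make_claims(rep(id, k), sample(2017:2019, k, replace = TRUE),
                "inpatient", admissions = 1L)
  })
  cl <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                         list(make_claims("p1", 2018L, "carrier", codes = "X"))))
  hand <- vapply(ids, function(id) {
    sum(cl$admission_count[cl$beneficiary_id == id & cl$service_year == 2018 &
                             cl$setting == "inpatient"])
  }, numeric(1))
  expect_identical(count_admissions(cl, ids, 2018L),
                   setNames(as.integer(hand), ids))
})
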