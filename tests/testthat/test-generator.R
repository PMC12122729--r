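test_that("parameter validation rejects malformed inputs", {
  expect_error(generator_params(0), "positive integer")
  expect_error(generator_params(10, n_categories = 3,
                                category_prevalences = c(0.1, 0.2)),
               "length")
  expect_error(generator_params(10, n_categories = 2,
                                category_prevalences = c(0.1, 1.2),
                                category_effects = c(1, 1)),
               "prevalences")
  expect_error(generator_params(10, n_categories = 2,
                                category_prevalences = c(0.1, 0.2),
                                category_effects = c(1, -1)),
               "positive")
  expect_error(generator_params(10, frailty_shape = 0), "frailty_shape")
})

test_that("with no effects and no frailty, counts are Poisson at the base rate", {
  ## closed form: P(0 admissions) = exp(-0.1) ~ 0.9048
  cells <- default_demographic_cells()
  cells$base_rate <- 0.1
  p <- generator_params(
    40000L, n_categories = 5L,
    category_prevalences = rep(0.05, 5), category_effects = rep(1, 5),
    demographic_cells = cells, frailty_shape = Inf,
    death_rate = 0, persistence = 1, seed = 314L
  )
  pop <- generate_population(p, default_mapping_table(5L, n_rules = 2L))
  y <- count_admissions(pop$claims, unique(pop$beneficiaries$beneficiary_id),
                        2018L)
  zero_frac <- mean(y == 0)
  se <- sqrt(exp(-0.1) * (1 - exp(-0.1)) / length(y))
  expect_lt(abs(zero_frac - exp(-0.1)), 4 * se)
  expect_lt(abs(mean(y) - 0.1), 4 * sqrt(0.1 / length(y)))
})

test_that("generation is byte-identical given the same params and seed", {
  p <- generator_params(500L, seed = 99L)
  a <- generate_population(p)
  b <- generate_population(p)
  expect_identical(a$beneficiaries, b$beneficiaries)
  expect_identical(a$claims, b$claims)
  ## and the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_population(p)); after <- runif(1)
  expect_identical(before, after)

  c2 <- generate_population(generator_params(500L, seed = 100L))
  expect_false(identical(a$claims, c2$claims))
})

test_that("unit-mean frailty leaves the mean count at its frailty-free value", {
  base <- 0.25
  cells <- default_demographic_cells(); cells$base_rate <- base
  mk <- function(shape, seed) generator_params(
    60000L, n_categories = 5L,
    category_prevalences = rep(0.05, 5), category_effects = rep(1, 5),
    demographic_cells = cells, frailty_shape = shape,
    death_rate = 0, seed = seed
  )
  map5 <- default_mapping_table(5L, n_rules = 2L)
  pop <- generate_population(mk(0.8, 2024L), map5)
  ids <- unique(pop$beneficiaries$beneficiary_id)
  y <- count_admissions(pop$claims, ids, 2018L)
  ## analytic frailty-free mean is the base rate; 3 MC standard errors,
  ## with Var(y) = mu + mu^2/shape for the gamma-Poisson mixture
  se <- sqrt((base + base^2 / 0.8) / length(y))
  expect_lt(abs(mean(y) - base), 3 * se)

  ## finite frailty shape implies strict overdispersion at this n
  expect_gt(var(y), mean(y))
  pop0 <- generate_population(mk(Inf, 2025L), map5)
  y0 <- count_admissions(pop0$claims, ids, 2018L)
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.05)
})

test_that("claims-derived profiles recover the drawn categories exactly", {
  p <- generator_params(800L, seed = 5L)
  tab <- default_mapping_table()
  pop <- generate_population(p, tab)
  ids <- unique(pop$beneficiaries$beneficiary_id)
  for (yr in c(2017L, 2018L)) {
    prof <- build_condition_profiles(pop$claims, pop$beneficiaries, ids, yr, tab)
    ## reconstruct the drawn sets straight from the emitted diagnosis rows
    diag <- pop$claims[pop$claims$setting != "inpatient" &
                         pop$claims$service_year == yr, ]
    lookup <- setNames(tab$code_to_cc$category, tab$code_to_cc$code)
    drawn <- tapply(unname(lookup[diag$diagnosis_codes]), diag$beneficiary_id,
                    function(x) paste(sort(unique(x)), collapse = ";"))
    drawn <- setNames(as.character(drawn), names(drawn))
    got <- setNames(prof$hcc_flags, prof$beneficiary_id)
    expect_identical(got[names(drawn)], drawn)
    expect_true(all(got[setdiff(ids, names(drawn))] == ""))
  }
})

test_that("beneficiary and claim tables satisfy their schema invariants", {
  p <- generator_params(3000L, death_rate = 0.15, seed = 8L)
  pop <- generate_population(p)
  b <- pop$beneficiaries; cl <- pop$claims

  expect_true(all(b$part_a_months >= 0 & b$part_a_months <= 12))
  expect_identical(b$part_a_months, b$part_b_months)
  ## admission_count = 1 iff inpatient setting
  expect_true(all(cl$admission_count[cl$setting == "inpatient"] == 1L))
  expect_true(all(cl$admission_count[cl$setting != "inpatient"] == 0L))

  ## no enrollment or claims after the death year
  dead <- b[!is.na(b$death_date), ]
  dyear <- as.integer(substr(dead$death_date, 1, 4))
  expect_true(all(dead$part_a_months[dead$year > dyear] == 0L))
  death_by_id <- tapply(dyear, dead$beneficiary_id, max)
  cl_dead <- cl[cl$beneficiary_id %in% names(death_by_id), ]
  expect_true(all(cl_dead$service_year <=
                    death_by_id[cl_dead$beneficiary_id]))

  ## drawn category sets respect the dominance rules (post-hierarchy draw)
  tab <- default_mapping_table()
  prof <- build_condition_profiles(cl, b, unique(b$beneficiary_id), 2017L, tab)
  flags <- strsplit(prof$hcc_flags[nzchar(prof$hcc_flags)], ";")
  viol <- vapply(flags, function(f) {
    any(tab$hierarchy$dominant %in% f & tab$hierarchy$subordinate %in% f)
  }, logical(1))
  expect_false(any(viol))
})

test_that("the latent rate cap bounds extreme admission counts", {
  run <- small_default_run()
  ## Poisson(12) essentially never exceeds ~30 in 10^4 draws
  expect_lt(max(run$observed), 40)
})
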