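## tiny deterministic fixtures shared across test files

## three-category table with a single rule: C1 dominates C2
tiny_mapping <- function() {
  mapping_table(
    data.frame(code = c("A1", "A2", "B1", "B2", "X1"),
               category = c("C1", "C1", "C2", "C2", "C3")),
    data.frame(dominant = "C1", subordinate = "C2")
  )
}

## three-level dominance chain C1 -> C2 -> C3 over five categories
chain_mapping <- function() {
  mapping_table(
    data.frame(code = paste0("K", 1:5), category = paste0("C", 1:5)),
    data.frame(dominant = c("C1", "C2"), subordinate = c("C2", "C3"))
  )
}

## beneficiary table: one row per (id, year), defaults fully enrolled
make_beneficiaries <- function(ids, years = 2017:2019, sex = "F",
                               birth_year = 1940L, death_date = NA_character_,
                               months = 12L, part_c = FALSE, esrd = FALSE,
                               dual = FALSE) {
  grid <- expand.grid(beneficiary_id = ids, year = years,
                      stringsAsFactors = FALSE)
  data.frame(
    beneficiary_id = grid$beneficiary_id,
    sex = rep_len(sex, nrow(grid)),
    birth_year = rep_len(birth_year, nrow(grid)),
    death_date = rep_len(death_date, nrow(grid)),
    year = grid$year,
    part_a_months = rep_len(months, nrow(grid)),
    part_b_months = rep_len(months, nrow(grid)),
    part_c_any = rep_len(part_c, nrow(grid)),
    esrd = rep_len(esrd, nrow(grid)),
    dual_buyin = rep_len(dual, nrow(grid))
  )
}

make_claims <- function(ids, years, settings, codes = "", admissions = 0L) {
  data.frame(
    beneficiary_id = ids,
    service_year = years,
    setting = settings,
    diagnosis_codes = codes,
    admission_count = admissions
  )
}

## small calibrated-run cache so several test files can share one pipeline run
small_default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_study(default_generator_params(20000L, seed = 11L))
    }
    cache
  }
})
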