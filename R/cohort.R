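#' Cohort specification: base/performance year pairing and filters
#'
#' A base year supplies the diagnoses (predictors); the following
#' performance year supplies the admission counts (outcome). Eligibility
#' follows standard actuarial cohort construction for fee-for-service
#' risk-model calibration: aged `min_age`+ at the start of the base year,
#' continuously enrolled in Parts A and B across both years, with decedents
#' retained when they die in the performance year while fully enrolled up to
#' death; any Medicare Advantage (Part C) enrollment or an ESRD flag
#' excludes (Part C claims are unobservable in FFS data; ESRD beneficiaries
#' are risk-adjusted under a distinct model). Dual-eligible (state buy-in)
#' beneficiaries are retained.
#'
#' @param base_year calendar year of the predictors.
#' @param performance_year calendar year of the outcome; must equal
#'   `base_year + 1`.
#' @param min_age minimum age at January 1 of the base year (default 65).
#' @param include_decedents keep performance-year decedents fully enrolled
#'   while living (default TRUE).
#' @param exclude_part_c,exclude_esrd apply the respective exclusions
#'   (default TRUE).
#' @param split_seed seed for the randomized training/study split.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(base_year, performance_year = base_year + 1L,
                        min_age = 65L, include_decedents = TRUE,
                        exclude_part_c = TRUE, exclude_esrd = TRUE,
                        split_seed = 1L) {
  if (performance_year != base_year + 1L) {
    stop("performance_year must be base_year + 1", call. = FALSE)
  }
  structure(
    list(base_year = as.integer(base_year),
         performance_year = as.integer(performance_year),
         min_age = as.integer(min_age),
         include_decedents = isTRUE(include_decedents),
         exclude_part_c = isTRUE(exclude_part_c),
         exclude_esrd = isTRUE(exclude_esrd),
         split_seed = as.integer(split_seed)),
    class = "cohort_spec"
  )
}

#' Apply eligibility filters for a base/performance year pairing
#'
#' Implements the rules documented in [cohort_spec()]. An id lacking
#' beneficiary rows for either year is excluded with a warning. Eligibility
#' is monotone in enrollment: adding enrolled months never removes an
#' eligible id.
#'
#' @param beneficiaries beneficiary table, one row per (beneficiary, year)
#'   (schema of [generate_population()]).
#' @param spec a [cohort_spec()].
#' @return Sorted character vector of eligible beneficiary ids.
#' @export
apply_eligibility <- function(beneficiaries, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- data.table::as.data.table(beneficiaries)
  yrs <- c(spec$base_year, spec$performance_year)
  b <- b[year %in% yrs]

  n_years <- b[, .N, by = beneficiary_id]
  incomplete <- n_years[N < 2L, beneficiary_id]
  if (length(incomplete)) {
    warning(sprintf("%d id(s) lack rows for both years; excluded",
                    length(incomplete)), call. = FALSE)
    b <- b[!beneficiary_id %in% incomplete]
  }
  if (!nrow(b)) return(character())

  w <- data.table::dcast(b, beneficiary_id + sex + birth_year + death_date +
                           part_c_any + esrd ~ year,
                         value.var = c("part_a_months", "part_b_months"))
  a_base <- w[[paste0("part_a_months_", spec$base_year)]]
  b_base <- w[[paste0("part_b_months_", spec$base_year)]]
  a_perf <- w[[paste0("part_a_months_", spec$performance_year)]]
  b_perf <- w[[paste0("part_b_months_", spec$performance_year)]]

  keep <- (spec$base_year - w$birth_year) >= spec$min_age
  if (spec$exclude_part_c) keep <- keep & !w$part_c_any
  if (spec$exclude_esrd) keep <- keep & !w$esrd

  death_year <- suppressWarnings(as.integer(substr(w$death_date, 1L, 4L)))
  death_month <- suppressWarnings(as.integer(substr(w$death_date, 6L, 7L)))
  survivor <- is.na(death_year) | death_year > spec$performance_year
  full_both <- a_base == 12L & b_base == 12L & a_perf == 12L & b_perf == 12L

  enrolled <- (survivor & full_both)
  if (spec$include_decedents) {
    ## died in the performance year, enrolled every month while living
    dec <- !is.na(death_year) & death_year == spec$performance_year &
      a_base == 12L & b_base == 12L &
      a_perf == death_month & b_perf == death_month
    enrolled <- enrolled | dec
  }
  sort(w$beneficiary_id[keep & enrolled])
}

#' Randomized training/study split by integer parity
#'
#' Every id is independently assigned a pseudo-random integer; even parity
#' goes to the training arm, odd to the study arm. Ids are sorted before
#' assignment so the labels depend only on the id set and the seed, not on
#' input order.
#'
#' @param ids character vector of eligible beneficiary ids.
#' @param split_seed integer seed.
#' @return data.table with columns `beneficiary_id` and `arm`
#'   (`"training"` or `"study"`), sorted by id.
#' @export
split_train_study <- function(ids, split_seed) {
  ids <- sort(unique(as.character(ids)))
  if (!length(ids)) stop("empty id set", call. = FALSE)
  draw <- with_seed(split_seed, sample.int(.Machine$integer.max, length(ids),
                                           replace = TRUE))
  data.table::data.table(
    beneficiary_id = ids,
    arm = c("training", "study")[1L + draw %% 2L]
  )
}

#' Performance-year admission counts per beneficiary
#'
#' Sums `admission_count` over inpatient claims of the given year; ids with
#' no inpatient claims that year get 0.
#'
#' @param claims claims table.
#' @param ids beneficiary ids defining the output order.
#' @param year service year to count.
#' @return Integer vector of counts, named by and aligned with `ids`.
#' @export
count_admissions <- function(claims, ids, year) {
  cl <- data.table::as.data.table(claims)
  ids <- as.character(ids)
  agg <- cl[setting == "inpatient" & service_year == year &
              beneficiary_id %in% ids,
            .(n_admissions = sum(admission_count)), by = beneficiary_id]
  out <- setNames(integer(length(ids)), ids)
  out[agg$beneficiary_id] <- as.integer(agg$n_admissions)
  out
}
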