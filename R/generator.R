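#' Parameters of the synthetic claims generator
#'
#' The generator emulates a Medicare-like fee-for-service population:
#' beneficiaries aged 65+, yearly Part A/B enrollment spans with deaths and
#' exclusion flags (Part C, ESRD), base-year diagnosis codes that induce
#' binary condition categories, and performance-year inpatient admission
#' counts. The data-generating process for the latent annual admission rate
#' of beneficiary `i` in year `t` is multiplicative:
#'
#' \deqn{\lambda_{it} = b(\mathrm{cell}_{it}) \prod_k e_k^{z_{ikt}} \varepsilon_i}
#'
#' where `b(cell)` is a demographic base rate (admissions/person-year),
#' `e_k > 0` are per-category rate effects, `z_{ikt}` indicates that
#' condition category `k` is active for `i` in year `t`, and
#' `\varepsilon_i ~ Gamma(shape, rate = shape)` is a unit-mean individual
#' frailty inducing overdispersion. Admission counts are Poisson with mean
#' `\lambda_{it}` times the fraction of the year the beneficiary is alive.
#' Category activity evolves as a stationary two-state Markov chain: an
#' active category stays active the next year with probability
#' `persistence`, and incidence among inactives is set so the marginal
#' prevalence is constant across years. Active sets are kept consistent with
#' the mapping table's dominance rules, so profiles recovered from emitted
#' claims reproduce the drawn categories exactly.
#'
#' The counts are deliberately only weakly predictable from base-year
#' categories: a linear model fitted downstream is misspecified for this
#' multiplicative process, and the frailty and year-to-year category drift
#' are unobservable to it, which together reproduce the low individual-level
#' R-squared characteristic of claims-based utilization models.
#'
#' @param n_beneficiaries number of beneficiaries to simulate.
#' @param n_categories number of condition categories (default 79).
#' @param category_prevalences marginal activity probabilities, one per
#'   category, each in (0, 1). Default: log-spaced 0.005 to 0.20.
#' @param category_effects multiplicative rate effects, one per category,
#'   all positive. Default: log-spaced and assigned so rarer categories have
#'   larger effects (the calibrated exponent `effect_gamma` is applied to a
#'   1.1--3.0 ladder).
#' @param demographic_cells data.frame with columns `cell` and `base_rate`
#'   (annual admissions/person-year for a condition-free beneficiary of unit
#'   frailty). Default: [default_demographic_cells()].
#' @param frailty_shape shape of the unit-mean gamma frailty; smaller values
#'   mean more overdispersion. `Inf` switches frailty off.
#' @param rate_cap ceiling on the latent annual admission rate
#'   (admissions/person-year). Multiplicative stacking of many strong
#'   categories would otherwise produce physically impossible rates
#'   (hundreds of admissions a year); a dozen admissions/person-year is
#'   about the plausible maximum given typical inpatient lengths of stay.
#'   `Inf` disables the cap.
#' @param persistence probability that an active category remains active in
#'   the following year.
#' @param death_rate annual death probability (deaths are uniform in-year;
#'   decedents retain enrollment while living).
#' @param exclusion_rates named vector with elements `part_c` and `esrd`:
#'   probabilities of carrying each exclusion flag.
#' @param dual_rate probability of a state buy-in (dual-eligible) indicator;
#'   duals are *not* excluded downstream.
#' @param years ordered calendar years covered (default 2017:2019).
#' @param seed integer seed; the generator is deterministic given
#'   `params` + `seed`.
#' @return An object of class `generator_params` (a validated list).
#' @seealso [generate_population()], [default_generator_params()]
#' @export
generator_params <- function(n_beneficiaries,
                             n_categories = 79L,
                             category_prevalences = logspace(0.005, 0.20, n_categories),
                             category_effects = rev(logspace(1.1, 3.0, n_categories)),
                             demographic_cells = default_demographic_cells(),
                             frailty_shape = 1,
                             rate_cap = 12,
                             persistence = 0.7,
                             death_rate = 0.04,
                             exclusion_rates = c(part_c = 0.10, esrd = 0.01),
                             dual_rate = 0.20,
                             years = 2017:2019,
                             seed = 1L) {
  stop_if_not_scalar_count(n_beneficiaries, "n_beneficiaries")
  stop_if_not_scalar_count(n_categories, "n_categories")
  if (length(category_prevalences) != n_categories ||
      length(category_effects) != n_categories) {
    stop("prevalence/effect vectors must have length `n_categories`",
         call. = FALSE)
  }
  if (any(category_prevalences <= 0 | category_prevalences >= 1)) {
    stop("category prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (any(category_effects <= 0)) {
    stop("category effects must be strictly positive", call. = FALSE)
  }
  demographic_cells <- as.data.frame(demographic_cells)
  if (!all(c("cell", "base_rate") %in% names(demographic_cells)) ||
      any(demographic_cells$base_rate <= 0)) {
    stop("demographic_cells needs columns `cell`, `base_rate` (> 0)",
         call. = FALSE)
  }
  if (!(frailty_shape > 0)) stop("frailty_shape must be > 0", call. = FALSE)
  if (!(rate_cap > 0)) stop("rate_cap must be > 0", call. = FALSE)
  stopifnot(persistence >= 0, persistence <= 1,
            death_rate >= 0, death_rate < 1,
            all(exclusion_rates >= 0), all(exclusion_rates <= 1),
            dual_rate >= 0, dual_rate <= 1,
            length(years) >= 2L, !is.unsorted(years))
  structure(
    list(n_beneficiaries = as.integer(n_beneficiaries),
         n_categories = as.integer(n_categories),
         category_prevalences = as.numeric(category_prevalences),
         category_effects = as.numeric(category_effects),
         demographic_cells = demographic_cells,
         frailty_shape = frailty_shape,
         rate_cap = rate_cap,
         persistence = persistence,
         death_rate = death_rate,
         exclusion_rates = exclusion_rates,
         dual_rate = dual_rate,
         years = as.integer(years),
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_params> n=%d, %d categories, frailty shape %.3g,\n",
    "  persistence %.2f, death rate %.3f, years %d-%d, seed %d\n"),
    x$n_beneficiaries, x$n_categories, x$frailty_shape, x$persistence,
    x$death_rate, min(x$years), max(x$years), x$seed))
  invisible(x)
}

#' Default demographic cells and base admission rates
#'
#' Twelve (age band, sex) cells: 5-year bands from 65 to 90+, crossed with
#' sex. Base rates rise with age and are slightly higher for men, a shape
#' typical of Medicare inpatient utilization; `scale` multiplies all of them
#' and is the knob the calibration uses to hit the marginal admission rate.
#'
#' @param scale multiplier applied to every base rate.
#' @return data.frame with columns `cell` and `base_rate`.
#' @export
default_demographic_cells <- function(scale = 1) {
  shape <- c(`65_69` = 0.10, `70_74` = 0.12, `75_79` = 0.15,
             `80_84` = 0.19, `85_89` = 0.24, `90plus` = 0.30)
  cells <- data.frame(
    cell = c(paste0("F_", names(shape)), paste0("M_", names(shape))),
    base_rate = scale * c(shape, 1.1 * shape),
    row.names = NULL
  )
  cells[order(cells$cell), , drop = FALSE]
}

#' Generate a synthetic beneficiary population and its claims
#'
#' Simulates the process described in [generator_params()] and emits two
#' tables. The beneficiary table has one row per (beneficiary, year) with
#' enrollment months prorated to the month of death. The claims table has
#' one outpatient/carrier claim per active (beneficiary, year, category) —
#' carrying a diagnosis code that maps back to exactly that category — and
#' one inpatient claim per admission (`admission_count = 1`,
#' no diagnosis codes).
#'
#' @param params a [generator_params()] object.
#' @param mapping a [mapping_table()] with at least `params$n_categories`
#'   categories; its dominance rules are enforced on the drawn category sets
#'   so that claims-derived profiles round-trip exactly.
#' @return list with elements `beneficiaries` and `claims` (data.tables; see
#'   Details for columns) and `params` (the input, echoed).
#' @examples
#' pop <- generate_population(generator_params(200, seed = 42))
#' head(pop$beneficiaries)
#' @export
generate_population <- function(params, mapping = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(mapping)) mapping <- default_mapping_table(params$n_categories)
  stopifnot(inherits(mapping, "mapping_table"))
  if (length(mapping$category_ids) < params$n_categories) {
    stop("mapping table has fewer categories than `n_categories`",
         call. = FALSE)
  }
  with_seed(params$seed, generate_population_impl(params, mapping))
}

generate_population_impl <- function(params, mapping) {
  n <- params$n_beneficiaries
  years <- params$years
  K <- params$n_categories
  cats <- mapping$category_ids[seq_len(K)]
  q <- params$category_prevalences
  log_e <- log(params$category_effects)
  p <- params$persistence

  ids <- sprintf("B%07d", seq_len(n))
  sex <- c("F", "M")[1L + (runif(n) < 0.45)]
  age0 <- sample(65:100, n, replace = TRUE, prob = exp(-0.075 * (0:35)))
  birth_year <- years[1L] - age0

  ## frailty: unit-mean gamma; Inf shape means no frailty
  frailty <- if (is.finite(params$frailty_shape)) {
    rgamma(n, shape = params$frailty_shape, rate = params$frailty_shape)
  } else rep(1, n)

  ## deaths: annual hazard, month uniform in-year
  death_year <- rep(NA_integer_, n)
  death_month <- rep(NA_integer_, n)
  for (yr in years) {
    at_risk <- is.na(death_year)
    dies <- at_risk & (runif(n) < params$death_rate)
    death_year[dies] <- yr
    death_month[dies] <- sample.int(12L, sum(dies), replace = TRUE)
  }

  part_c <- runif(n) < params$exclusion_rates[["part_c"]]
  esrd <- runif(n) < params$exclusion_rates[["esrd"]]
  dual <- runif(n) < params$dual_rate

  ## per-category code assignment (deterministic: person index cycles codes)
  codes_by_cat <- split(mapping$code_to_cc$code,
                        factor(mapping$code_to_cc$category, levels = cats))
  codes_flat <- unlist(codes_by_cat, use.names = FALSE)
  codes_len <- lengths(codes_by_cat)
  codes_off <- cumsum(c(0L, codes_len[-K]))
  ## dominance rules as index pairs into 1..K
  rules <- mapping$hierarchy[dominant %in% cats & subordinate %in% cats]
  dom_idx <- match(rules$dominant, cats)
  sub_idx <- match(rules$subordinate, cats)

  base_rates <- setNames(params$demographic_cells$base_rate,
                         params$demographic_cells$cell)

  bene_rows <- vector("list", length(years))
  claim_rows <- vector("list", length(years) * 2L)
  z_prev <- NULL
  incidence <- q * (1 - p) / (1 - q)  # keeps marginal prevalence stationary

  for (ti in seq_along(years)) {
    yr <- years[ti]
    ## enrollment months this year (0 once dead, prorated in death year)
    months <- rep(12L, n)
    months[!is.na(death_year) & death_year < yr] <- 0L
    dy <- !is.na(death_year) & death_year == yr
    months[dy] <- death_month[dy]
    exposure <- months / 12

    ## category activity: fresh draw in the first year, Markov chain after
    z <- matrix(FALSE, n, K)
    for (k in seq_len(K)) {
      r <- runif(n)
      z[, k] <- if (is.null(z_prev)) r < q[k] else {
        (z_prev[, k] & r < p) | (!z_prev[, k] & r < incidence[k])
      }
    }
    z[exposure == 0, ] <- FALSE
    ## enforce dominance so claims-derived profiles round-trip exactly;
    ## fixture rules are two-level, one pass suffices (dominants never removed)
    for (j in seq_along(dom_idx)) {
      z[z[, dom_idx[j]], sub_idx[j]] <- FALSE
    }

    ## latent rate and admission counts
    cell <- demographic_cell(pmax(yr - birth_year, 65L), sex)
    log_lambda <- log(base_rates[cell]) + log(frailty)
    for (k in seq_len(K)) log_lambda[z[, k]] <- log_lambda[z[, k]] + log_e[k]
    counts <- rpois(n, pmin(exp(log_lambda), params$rate_cap) * exposure)

    ## diagnosis claims: one outpatient/carrier claim per active category
    act <- which(z, arr.ind = TRUE)
    if (nrow(act)) {
      i <- act[, 1L]; k <- act[, 2L]
      code <- codes_flat[codes_off[k] + 1L + (i %% codes_len[k])]
      claim_rows[[2L * ti - 1L]] <- data.table::data.table(
        beneficiary_id = ids[i],
        service_year = yr,
        setting = c("outpatient", "carrier")[1L + (i + k) %% 2L],
        diagnosis_codes = code,
        admission_count = 0L
      )
    }
    ## inpatient claims: one per admission
    adm <- which(counts > 0L)
    if (length(adm)) {
      claim_rows[[2L * ti]] <- data.table::data.table(
        beneficiary_id = rep(ids[adm], counts[adm]),
        service_year = yr,
        setting = "inpatient",
        diagnosis_codes = "",
        admission_count = 1L
      )
    }

    bene_rows[[ti]] <- data.table::data.table(
      beneficiary_id = ids,
      sex = sex,
      birth_year = birth_year,
      death_date = data.table::fifelse(
        is.na(death_year), NA_character_,
        sprintf("%04d-%02d-15", death_year, death_month)),
      year = yr,
      part_a_months = months,
      part_b_months = months,
      part_c_any = part_c,
      esrd = esrd,
      dual_buyin = dual
    )
    z_prev <- z
  }

  beneficiaries <- data.table::rbindlist(bene_rows)
  claims <- data.table::rbindlist(claim_rows[!vapply(claim_rows, is.null, logical(1))])
  data.table::setorder(beneficiaries, beneficiary_id, year)
  data.table::setorder(claims, beneficiary_id, service_year, setting,
                       diagnosis_codes)
  list(beneficiaries = beneficiaries, claims = claims, params = params)
}

#' Write / read a generated population as CSV
#'
#' `beneficiaries.csv` and `claims.csv` in `dir`, matching the schemas
#' produced by [generate_population()].
#'
#' @param population list with `beneficiaries` and `claims` tables.
#' @param dir output (input) directory.
#' @return `write_population()` invisibly returns `dir`; `read_population()`
#'   returns a list of the two tables.
#' @export
write_population <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(population$beneficiaries, file.path(dir, "beneficiaries.csv"))
  data.table::fwrite(population$claims, file.path(dir, "claims.csv"))
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  list(
    beneficiaries = data.table::fread(file.path(dir, "beneficiaries.csv"),
                                      na.strings = ""),
    claims = data.table::fread(file.path(dir, "claims.csv"),
                               colClasses = list(character = "diagnosis_codes"),
                               na.strings = NULL)
  )
}
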