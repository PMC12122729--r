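#' Assign expected-utilization quintiles
#'
#' Study-arm members are stably sorted by (expected value ascending,
#' beneficiary id ascending) and cut into five blocks whose sizes differ by
#' at most one (exactly `n/5` each when `n` is divisible by 5; the lower
#' quintiles absorb any remainder). Quintile 5 is the highest expected
#' utilization. The id tie-break makes the assignment deterministic.
#'
#' @param expected numeric vector of expected utilization.
#' @param ids beneficiary ids aligned with `expected`; defaults to
#'   `names(expected)`.
#' @return Integer vector of quintile labels in 1..5, aligned with the
#'   input order and named by id.
#' @export
assign_quintiles <- function(expected, ids = names(expected)) {
  n <- length(expected)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(expected))) stop("expected values must be finite",
                                      call. = FALSE)
  ids <- as.character(ids)
  ord <- order(expected, ids)
  ## block sizes differ by at most 1; the lowest quintiles absorb a remainder
  sizes <- rep.int(n %/% 5L, 5L)
  r <- n %% 5L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  labels <- integer(n)
  labels[ord] <- rep.int(1:5, sizes)
  setNames(labels, ids)
}

#' Per-quintile calibration summary
#'
#' For each quintile: size, mean expected and observed admissions, the
#' predictive ratio (mean expected / mean observed; group-level calibration
#' is 1.0), a 95% half-width for the mean observed
#' (`1.96 * sd / sqrt(n)`), and empirical bounds containing 99% of
#' individual outcomes (0.5th and 99.5th percentiles, nearest-rank). A
#' quintile whose mean observed is 0 gets `NA` as predictive ratio rather
#' than infinity.
#'
#' @param assignment quintile labels from [assign_quintiles()].
#' @param expected,observed numeric vectors aligned with `assignment`.
#' @return data.table with one row per quintile: `quintile`, `n`,
#'   `mean_expected`, `mean_observed`, `predictive_ratio`, `ci_half_width`,
#'   `lower_99`, `upper_99`.
#' @export
quintile_summary <- function(assignment, expected, observed) {
  stopifnot(length(assignment) == length(expected),
            length(assignment) == length(observed))
  out <- lapply(sort(unique(assignment)), function(qt) {
    e <- expected[assignment == qt]
    o <- observed[assignment == qt]
    mo <- mean(o)
    bounds <- quantile(o, c(0.005, 0.995), type = 1, names = FALSE)
    data.table::data.table(
      quintile = qt,
      n = length(o),
      mean_expected = mean(e),
      mean_observed = mo,
      predictive_ratio = if (mo == 0) NA_real_ else mean(e) / mo,
      ci_half_width = 1.96 * sd(o) / sqrt(length(o)),
      lower_99 = bounds[1L],
      upper_99 = bounds[2L]
    )
  })
  data.table::rbindlist(out)
}

#' Individual-level coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed on the
#' study arm. This is the standard individual-level measure used to
#' characterise claims-based risk models; values near 0.12 are typical for
#' one-year-ahead utilization. Constant observed values make the statistic
#' undefined and return `NA` with a warning.
#'
#' @param observed,expected aligned numeric vectors, `length >= 2`.
#' @return A single numeric value (possibly negative), or `NA` if undefined.
#' @export
r_squared <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("observed values are constant; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((observed - expected)^2) / sst
}
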