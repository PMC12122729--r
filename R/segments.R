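segment_labels <- c("top20", "top40", "top60", "top80", "all100")

#' Cumulative risk segments from quintile labels
#'
#' The five progressively narrower cumulative risk segments: `top20` is
#' quintile 5 (highest expected utilization), `top40` unions quintiles 4-5,
#' and so on down to `all100`, the whole study arm. Segments are nested by
#' construction.
#'
#' @param assignment integer quintile labels from [assign_quintiles()].
#' @return Named list of logical membership vectors (one per segment, each
#'   aligned with `assignment`), ordered `top20` to `all100`.
#' @export
cumulative_segments <- function(assignment) {
  stopifnot(all(assignment %in% 1:5))
  out <- lapply(4:0, function(th) assignment > th)
  names(out) <- segment_labels
  out
}

#' Segment-level utilization summary
#'
#' For each cumulative risk segment: member count, expected and actual
#' admission totals and rates, the capture fraction (share of the whole
#' population's actual admissions falling in the segment), the zero
#' fraction (share of members with no admissions), the distinct
#' "any admission" probability, and a count histogram. Rates are
#' admissions per beneficiary expressed as a percent — a count rate, not a
#' probability, so values can exceed 100 in extreme segments; the
#' `pct_any_admission` column is the probability reading and is reported
#' alongside to avoid conflating the two. Histograms are capped at count 15
#' with an overflow bin for reporting; the full tail is retained in the
#' `histograms` attribute.
#'
#' @param memberships named list of logical vectors from
#'   [cumulative_segments()].
#' @param observed integer admission counts aligned with the membership
#'   vectors.
#' @param expected expected utilization aligned likewise.
#' @param histogram_cap counts above this go into an overflow bin in the
#'   reported histogram (default 15).
#' @return data.table with one row per segment (`segment`, `n`,
#'   `expected_total`, `expected_rate_pct`, `actual_total`,
#'   `actual_rate_pct`, `capture_fraction`, `zero_fraction`,
#'   `pct_any_admission`), with attribute `histograms`: a named list of
#'   full count tables.
#' @export
segment_summary <- function(memberships, observed, expected,
                            histogram_cap = 15L) {
  stopifnot(is.list(memberships), length(observed) == length(expected))
  population_actual <- sum(observed)
  hists <- list()
  rows <- lapply(names(memberships), function(lab) {
    m <- memberships[[lab]]
    if (!any(m)) stop(sprintf("segment '%s' is empty", lab), call. = FALSE)
    o <- observed[m]
    e <- expected[m]
    tab <- table(factor(o, levels = 0:max(o, histogram_cap)))
    hists[[lab]] <<- tab
    data.table::data.table(
      segment = lab,
      n = length(o),
      expected_total = sum(e),
      expected_rate_pct = 100 * sum(e) / length(e),
      actual_total = sum(o),
      actual_rate_pct = 100 * sum(o) / length(o),
      capture_fraction = if (population_actual == 0) NA_real_ else
        sum(o) / population_actual,
      zero_fraction = mean(o == 0),
      pct_any_admission = 100 * mean(o > 0)
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "histograms", hists)
  out
}

## reported histogram: counts 0..cap plus an overflow bin
capped_histogram <- function(tab, cap = 15L) {
  counts <- as.integer(tab)
  vals <- as.integer(names(tab))
  keep <- vals <= cap
  h <- setNames(as.list(counts[keep]), vals[keep])
  overflow <- sum(counts[!keep])
  h[[paste0(">", cap)]] <- overflow
  h
}

#' Write the machine-readable run report
#'
#' A single JSON report containing the quintile table, segment table (with
#' capped histograms), the study-arm R-squared, and run metadata (seeds,
#' parameter echo, package version, timestamp). Key order is stable, so two
#' runs with identical seeds produce byte-identical reports apart from the
#' timestamp. Companion CSVs of the two tables and of the histograms are
#' written alongside when `csv_dir` is given.
#'
#' @param quintiles data.table from [quintile_summary()].
#' @param segments data.table from [segment_summary()].
#' @param r2 study-arm R-squared.
#' @param metadata named list echoed verbatim into the report (seeds,
#'   generator parameters, cohort sizes, ...).
#' @param path output path of the JSON report.
#' @param csv_dir optional directory for `quintile_summary.csv`,
#'   `segments.csv` and `histograms.csv`.
#' @param histogram_cap reporting cap for histograms (default 15).
#' @return Invisibly, `path`.
#' @export
write_report <- function(quintiles, segments, r2, metadata = list(), path,
                         csv_dir = NULL, histogram_cap = 15L) {
  hists <- attr(segments, "histograms")
  report <- list(
    package = "riskstrata",
    version = as.character(utils::packageVersion("riskstrata")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    metadata = metadata,
    r_squared = r2,
    quintiles = as.data.frame(quintiles),
    segments = as.data.frame(segments),
    histograms = lapply(hists, capped_histogram, cap = histogram_cap)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(csv_dir)) {
    if (!dir.exists(csv_dir)) dir.create(csv_dir, recursive = TRUE)
    data.table::fwrite(quintiles, file.path(csv_dir, "quintile_summary.csv"))
    data.table::fwrite(segments, file.path(csv_dir, "segments.csv"))
    hl <- data.table::rbindlist(lapply(names(hists), function(lab) {
      data.table::data.table(segment = lab,
                             count = as.integer(names(hists[[lab]])),
                             n = as.integer(hists[[lab]]))
    }))
    data.table::fwrite(hl, file.path(csv_dir, "histograms.csv"))
  }
  invisible(path)
}

#' Read a run report written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return The report as a named list; the two tables are data.frames.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
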