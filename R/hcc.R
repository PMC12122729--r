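#' Map diagnosis codes to raw condition categories
#'
#' Looks up each code in the mapping table and returns the set (no
#' duplicates) of condition categories triggered. Codes absent from the table
#' are ignored, mirroring how unmapped diagnoses simply contribute nothing to
#' a risk profile.
#'
#' @param codes character vector of diagnosis codes (may contain duplicates).
#' @param table a [mapping_table()].
#' @return Character vector of category ids, sorted, without duplicates.
#' @export
map_to_categories <- function(codes, table) {
  stopifnot(inherits(table, "mapping_table"))
  if (length(codes) == 0L) return(character())
  idx <- match(unique(as.character(codes)), table$code_to_cc$code)
  sort(unique(table$code_to_cc$category[idx[!is.na(idx)]]))
}

#' Apply hierarchy (dominance) rules to a raw category set
#'
#' Iteratively removes every category that is subordinate to a category
#' present in the set, until a fixed point is reached. The result is
#' independent of rule order, is a subset of the input, and applying the
#' operation twice equals applying it once.
#'
#' @param categories character vector of category ids.
#' @param table a [mapping_table()] (its rules were validated acyclic at
#'   construction).
#' @return Character vector: the post-hierarchy category set, sorted.
#' @export
apply_hierarchy <- function(categories, table) {
  stopifnot(inherits(table, "mapping_table"))
  cats <- sort(unique(as.character(categories)))
  rules <- table$hierarchy
  if (!nrow(rules) || !length(cats)) return(cats)
  repeat {
    drop <- rules$subordinate[rules$dominant %in% cats & rules$subordinate %in% cats]
    if (!length(drop)) break
    cats <- setdiff(cats, drop)
  }
  cats
}

#' Demographic cell assignment
#'
#' Assigns one (age band, sex) cell id, e.g. `"F_65_69"` or `"M_90plus"`.
#' Bands are closed on both ends; the top band is open above. Age is the age
#' at the start of the base year; beneficiaries younger than the lowest band
#' are a cohort-filter violation and raise an error.
#'
#' @param age integer vector of ages at the start of the base year.
#' @param sex character vector, `"F"` or `"M"`, recycled against `age`.
#' @param bands integer vector of band lower edges (default CMS-style 5-year
#'   bands from 65, topping out at 90+).
#' @return Character vector of cell ids.
#' @export
demographic_cell <- function(age, sex, bands = c(65L, 70L, 75L, 80L, 85L, 90L)) {
  if (any(age < bands[1L], na.rm = TRUE)) {
    stop(sprintf("age below %d: the cohort filter should have removed these",
                 bands[1L]), call. = FALSE)
  }
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)
  labs <- band_labels(bands)
  band <- labs[findInterval(age, bands)]
  paste(sex, band, sep = "_")
}

band_labels <- function(bands) {
  k <- length(bands)
  c(paste(bands[-k], c(bands[-1L] - 1L), sep = "_"), paste0(bands[k], "plus"))
}

#' All demographic cell ids for a band configuration
#'
#' Cell ids in canonical (lexicographic) order: all female cells by ascending
#' band, then all male cells. This is the fixed demographic block of the
#' design-matrix column order.
#'
#' @inheritParams demographic_cell
#' @return Character vector of cell ids.
#' @export
demographic_cell_ids <- function(bands = c(65L, 70L, 75L, 80L, 85L, 90L)) {
  sort(as.vector(outer(c("F", "M"), band_labels(bands), paste, sep = "_")))
}

#' Build base-year condition profiles from claims
#'
#' Converts the base-year diagnosis codes of each cohort member into a
#' post-hierarchy condition-category profile plus a demographic cell.
#' Diagnoses are taken from inpatient, outpatient, and carrier claims of the
#' base year only. Unmapped codes are ignored; members with no mappable
#' diagnosis get an empty flag set (their profile is demographic-only).
#'
#' @param claims claims table (see [generate_population()] for the schema);
#'   `diagnosis_codes` holds semicolon-joined code strings.
#' @param beneficiaries beneficiary table, used for sex and birth year.
#' @param ids character vector of cohort member ids to profile.
#' @param base_year calendar year whose diagnoses form the profile.
#' @param table a [mapping_table()].
#' @param bands age-band edges passed to [demographic_cell()].
#' @return data.table with columns `beneficiary_id`, `base_year`,
#'   `demographic_cell`, `hcc_flags` (semicolon-joined post-hierarchy
#'   category ids, `""` when empty), one row per id, sorted by id.
#' @export
build_condition_profiles <- function(claims, beneficiaries, ids, base_year,
                                     table = default_mapping_table(),
                                     bands = c(65L, 70L, 75L, 80L, 85L, 90L)) {
  stopifnot(inherits(table, "mapping_table"))
  claims <- data.table::as.data.table(claims)
  beneficiaries <- data.table::as.data.table(beneficiaries)
  ids <- sort(unique(as.character(ids)))

  cl <- claims[beneficiary_id %in% ids & service_year == base_year &
                 setting %in% c("inpatient", "outpatient", "carrier") &
                 nzchar(diagnosis_codes)]
  flags <- if (nrow(cl)) {
    long <- cl[, .(code = unlist(strsplit(diagnosis_codes, ";", fixed = TRUE))),
               by = beneficiary_id]
    long <- merge(long, table$code_to_cc, by = "code", allow.cartesian = TRUE)
    long <- unique(long[, .(beneficiary_id, category)])
    apply_hierarchy_bulk(long, table)
  } else {
    data.table::data.table(beneficiary_id = character(), category = character())
  }
  flag_str <- flags[order(beneficiary_id, category),
                    .(hcc_flags = paste(category, collapse = ";")),
                    by = beneficiary_id]

  demo <- unique(beneficiaries[beneficiary_id %in% ids,
                               .(beneficiary_id, sex, birth_year)])
  prof <- data.table::data.table(beneficiary_id = ids)
  prof <- merge(prof, demo, by = "beneficiary_id", all.x = TRUE)
  prof[, `:=`(base_year = base_year,
              demographic_cell = demographic_cell(base_year - birth_year, sex,
                                                  bands = bands))]
  prof <- merge(prof, flag_str, by = "beneficiary_id", all.x = TRUE)
  prof[is.na(hcc_flags), hcc_flags := ""]
  data.table::setorder(prof, beneficiary_id)
  prof[, .(beneficiary_id, base_year, demographic_cell, hcc_flags)]
}

## vectorised fixed-point hierarchy application on a long (id, category) table
apply_hierarchy_bulk <- function(long, table) {
  rules <- table$hierarchy
  if (!nrow(rules) || !nrow(long)) return(long)
  repeat {
    dom <- merge(long, rules, by.x = "category", by.y = "dominant",
                 allow.cartesian = TRUE)[, .(beneficiary_id, category = subordinate)]
    before <- nrow(long)
    long <- long[!dom, on = c("beneficiary_id", "category")]
    if (nrow(long) == before) break
  }
  long
}
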