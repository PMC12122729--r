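#' Diagnosis-code to condition-category mapping tables
#'
#' A `mapping_table` holds the two pieces needed to turn raw diagnosis codes
#' into a post-hierarchy condition-category profile: a code-to-category map
#' and a set of dominance rules. In hierarchical condition category (HCC)
#' systems a more severe ("dominant") category zeroes out related milder
#' ("subordinate") categories when both are triggered by a beneficiary's
#' diagnoses. The licensed CMS mapping files are not shipped; a synthetic
#' fixture table ([default_mapping_table()]) is used by default, and real
#' tables can be loaded from CSV with [read_mapping_table()].
#'
#' @param code_to_cc data.frame with columns `code` (diagnosis code string)
#'   and `category` (category id string).
#' @param hierarchy data.frame with columns `dominant` and `subordinate`
#'   (category ids); may have zero rows. When a dominant category is present
#'   in a profile, all of its subordinates are removed.
#' @param category_ids ordered character vector of all category ids. Defaults
#'   to the sorted categories appearing in `code_to_cc`.
#'
#' @return An object of class `mapping_table`: a list with elements
#'   `code_to_cc` (data.table), `hierarchy` (data.table) and `category_ids`.
#' @examples
#' tab <- mapping_table(
#'   data.frame(code = c("A1", "A2", "B1"), category = c("C1", "C1", "C2")),
#'   data.frame(dominant = "C1", subordinate = "C2")
#' )
#' map_to_categories(c("A1", "B1"), tab)
#' @export
mapping_table <- function(code_to_cc, hierarchy = NULL, category_ids = NULL) {
  code_to_cc <- data.table::as.data.table(code_to_cc)
  if (!all(c("code", "category") %in% names(code_to_cc))) {
    stop("`code_to_cc` needs columns `code` and `category`", call. = FALSE)
  }
  code_to_cc <- code_to_cc[, .(code = as.character(code),
                               category = as.character(category))]
  if (anyDuplicated(code_to_cc$code)) {
    stop("each diagnosis code may map to at most one category", call. = FALSE)
  }
  if (is.null(hierarchy)) {
    hierarchy <- data.table::data.table(dominant = character(),
                                        subordinate = character())
  }
  hierarchy <- data.table::as.data.table(hierarchy)[
    , .(dominant = as.character(dominant), subordinate = as.character(subordinate))]
  category_ids <- as.character(category_ids %||% sort(unique(code_to_cc$category)))

  referenced <- unique(c(hierarchy$dominant, hierarchy$subordinate))
  missing <- setdiff(referenced, category_ids)
  if (length(missing)) {
    stop("hierarchy references unknown categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(hierarchy)) assert_acyclic(hierarchy)

  structure(
    list(code_to_cc = code_to_cc, hierarchy = hierarchy,
         category_ids = category_ids),
    class = "mapping_table"
  )
}

## dominance must be acyclic: no category may (transitively) dominate itself
assert_acyclic <- function(hierarchy) {
  edges <- unique(hierarchy)
  nodes <- unique(c(edges$dominant, edges$subordinate))
  ## Kahn's algorithm; leftover nodes imply a cycle
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$subordinate)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    out <- edges$subordinate[edges$dominant == v]
    for (w in out) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    stop("hierarchy rules contain a dominance cycle", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d codes -> %d categories, %d hierarchy rules\n",
              nrow(x$code_to_cc), length(x$category_ids), nrow(x$hierarchy)))
  invisible(x)
}

#' Synthetic fixture mapping table
#'
#' Builds a deterministic synthetic mapping table: `n_categories` condition
#' categories (ids `CC001`, `CC002`, ...) with 2--5 diagnosis codes each, and
#' `n_rules` two-level dominance rules in which category `i` dominates
#' category `i + n_rules`. It is a stand-in feature space with the same shape
#' as a real HCC mapping (many-to-one codes, acyclic dominance), not a
#' clinical code set.
#'
#' @param n_categories number of condition categories (default 79).
#' @param n_rules number of two-level hierarchy rules (default 12; must
#'   satisfy `2 * n_rules <= n_categories`).
#' @return A [mapping_table()].
#' @export
default_mapping_table <- function(n_categories = 79L, n_rules = 12L) {
  stop_if_not_scalar_count(n_categories, "n_categories")
  if (2L * n_rules > n_categories) {
    stop("need 2 * n_rules <= n_categories for disjoint two-level rules",
         call. = FALSE)
  }
  category_ids <- sprintf("CC%03d", seq_len(n_categories))
  ## 2..5 codes per category, cycling, so the table is reproducible without RNG
  n_codes <- 2L + (seq_len(n_categories) - 1L) %% 4L
  code_to_cc <- data.table::data.table(
    code = unlist(lapply(seq_len(n_categories), function(j) {
      sprintf("D%03d%s", j, LETTERS[seq_len(n_codes[j])])
    })),
    category = rep(category_ids, n_codes)
  )
  hierarchy <- data.table::data.table(
    dominant = category_ids[seq_len(n_rules)],
    subordinate = category_ids[n_rules + seq_len(n_rules)]
  )
  mapping_table(code_to_cc, hierarchy, category_ids)
}

#' Read a mapping table from CSV files
#'
#' `mapping_csv` must have columns `code,category`; `hierarchy_csv` (optional)
#' must have columns `dominant,subordinate`. This is the hook through which a
#' licensed user can supply real CMS-HCC mapping files.
#'
#' @param mapping_csv path to the code-to-category CSV.
#' @param hierarchy_csv optional path to the dominance-rule CSV.
#' @return A [mapping_table()].
#' @export
read_mapping_table <- function(mapping_csv, hierarchy_csv = NULL) {
  codes <- data.table::fread(mapping_csv, colClasses = "character")
  hier <- if (!is.null(hierarchy_csv)) {
    data.table::fread(hierarchy_csv, colClasses = "character")
  }
  mapping_table(codes, hier)
}

#' Write a mapping table to CSV files
#'
#' @param table a [mapping_table()].
#' @param mapping_csv,hierarchy_csv output paths.
#' @return Invisibly, the paths written.
#' @export
write_mapping_table <- function(table, mapping_csv, hierarchy_csv) {
  stopifnot(inherits(table, "mapping_table"))
  data.table::fwrite(table$code_to_cc, mapping_csv)
  data.table::fwrite(table$hierarchy, hierarchy_csv)
  invisible(c(mapping_csv, hierarchy_csv))
}
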