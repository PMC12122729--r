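#' Design-matrix column specification
#'
#' The fixed column order shared by the training and study design matrices:
#' all demographic cells first (lexicographic), then all condition-category
#' ids (lexicographic). The demographic cells are exhaustive and mutually
#' exclusive, so their block forms a partition of unity across rows and
#' plays the role of an intercept, mirroring how CMS-style risk models carry
#' demographic terms; no separate intercept column is used.
#'
#' @param table a [mapping_table()] supplying the category ids.
#' @param bands age-band lower edges (see [demographic_cell()]).
#' @return Character vector of column ids.
#' @export
design_columns <- function(table = default_mapping_table(),
                           bands = c(65L, 70L, 75L, 80L, 85L, 90L)) {
  c(demographic_cell_ids(bands), sort(table$category_ids))
}

#' Build the 0/1 design matrix from condition profiles
#'
#' One row per beneficiary (sorted by id for determinism), one column per
#' configured column id. Each row has exactly one 1 in the demographic
#' block, plus a 1 for every post-hierarchy category flag.
#'
#' @param profiles profile table from [build_condition_profiles()].
#' @param columns character vector of column ids, from [design_columns()];
#'   must cover every cell and category appearing in `profiles`.
#' @return A sparse `dgCMatrix` with beneficiary ids as rownames and column
#'   ids as colnames.
#' @export
build_design_matrix <- function(profiles, columns) {
  prof <- data.table::as.data.table(profiles)
  data.table::setorder(prof, beneficiary_id)
  n <- nrow(prof)
  col_index <- setNames(seq_along(columns), columns)

  ci_demo <- col_index[prof$demographic_cell]
  if (anyNA(ci_demo)) {
    bad <- unique(prof$demographic_cell[is.na(ci_demo)])
    stop("unknown demographic cell(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  flag_list <- strsplit(prof$hcc_flags, ";", fixed = TRUE)
  n_flags <- lengths(flag_list)
  flat <- unlist(flag_list, use.names = FALSE)
  ci_flag <- col_index[flat]
  if (anyNA(ci_flag)) {
    bad <- unique(flat[is.na(ci_flag)])
    stop("unknown category id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- Matrix::sparseMatrix(
    i = c(seq_len(n), rep(seq_len(n), n_flags)),
    j = c(ci_demo, ci_flag),
    x = 1,
    dims = c(n, length(columns)),
    dimnames = list(prof$beneficiary_id, columns)
  )
  X
}

#' Least-squares calibration of admission-rate coefficients
#'
#' Solves the heavily overdetermined system `X b ≈ y` in the least-squares
#' sense via the normal equations `(X'X) b = X'y`. When `X'X` is numerically
#' singular (e.g. a category absent from the training arm), the
#' minimum-norm solution is returned via the eigen-pseudoinverse of `X'X`
#' instead of failing; all-zero columns then get coefficient 0 and are
#' reported in a warning. The returned solution always satisfies the
#' residual-orthogonality contract
#' `max|X'(y - Xb)| <= 1e-6 * max|X'y|`.
#'
#' @param X design matrix (dense or sparse) with column names.
#' @param y numeric outcome vector, `length(y) == nrow(X)`.
#' @return Named numeric vector of coefficients, one per column of `X`.
#' @export
fit_least_squares <- function(X, y) {
  if (nrow(X) != length(y)) {
    stop(sprintf("dimension mismatch: %d rows vs %d outcomes", nrow(X),
                 length(y)), call. = FALSE)
  }
  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, y))

  zero_cols <- which(Matrix::colSums(X != 0) == 0)
  if (length(zero_cols)) {
    warning("all-zero column(s): ",
            paste(colnames(X)[zero_cols], collapse = ", "),
            " (coefficient 0 under the minimum-norm convention)",
            call. = FALSE)
  }

  b <- tryCatch(drop(solve(XtX, Xty)), error = function(e) NULL)
  if (is.null(b) || !residual_orthogonal(XtX, Xty, b)) {
    b <- drop(pinv_sym(XtX) %*% Xty)
  }
  if (!residual_orthogonal(XtX, Xty, b)) {
    stop("least-squares solve failed the residual-orthogonality check",
         call. = FALSE)
  }
  setNames(as.numeric(b), colnames(X))
}

residual_orthogonal <- function(XtX, Xty, b, tol = 1e-6) {
  max(abs(Xty - XtX %*% b)) <= tol * max(abs(Xty), 1e-300)
}

## Moore-Penrose pseudoinverse of a symmetric PSD matrix via eigendecomposition
pinv_sym <- function(S, tol = NULL) {
  e <- eigen(S, symmetric = TRUE)
  tol <- tol %||% (max(dim(S)) * .Machine$double.eps * max(abs(e$values), 0))
  pos <- e$values > tol
  if (!any(pos)) return(matrix(0, nrow(S), ncol(S)))
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / e$values[pos])
}

#' Expected performance-year utilization
#'
#' The linear prediction `X_s b_t`: study-arm design matrix times
#' training-arm coefficients. Column names must match the training order
#' exactly (they are compared, not assumed). Predictions are not clipped;
#' small negative expectations can occur and only affect ranking.
#'
#' @param X study-arm design matrix with column names.
#' @param coefficients named coefficient vector from [fit_least_squares()].
#' @return Numeric vector of expected admission counts, named by row
#'   (beneficiary) id.
#' @export
predict_utilization <- function(X, coefficients) {
  if (ncol(X) != length(coefficients) ||
      !identical(colnames(X), names(coefficients))) {
    stop("design-matrix columns do not match the coefficient vector",
         call. = FALSE)
  }
  setNames(as.numeric(X %*% coefficients), rownames(X))
}
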