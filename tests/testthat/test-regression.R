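## handmade 5-profile fixture over a 2-category table
fixture_profiles <- function() {
  data.frame(
    beneficiary_id = paste0("b", 1:5),
    base_year = 2017L,
    demographic_cell = c("F_65_69", "F_65_69", "M_70_74", "M_90plus", "F_85_89"),
    hcc_flags = c("", "CC001", "CC001;CC002", "CC002", "")
  )
}

test_that("design matrix equals its hand-written counterpart", {
  tab <- mapping_table(data.frame(code = c("A", "B"),
                                  category = c("CC001", "CC002")))
  cols <- design_columns(tab)
  X <- build_design_matrix(fixture_profiles(), cols)
  expect_identical(dim(X), c(5L, 14L))
  expect_identical(rownames(X), paste0("b", 1:5))

  hand <- matrix(0, 5, 14, dimnames = list(paste0("b", 1:5), cols))
  hand["b1", "F_65_69"] <- 1; hand["b2", "F_65_69"] <- 1
  hand["b3", "M_70_74"] <- 1; hand["b4", "M_90plus"] <- 1
  hand["b5", "F_85_89"] <- 1
  hand["b2", "CC001"] <- 1; hand["b3", c("CC001", "CC002")] <- 1
  hand["b4", "CC002"] <- 1
  expect_equal(as.matrix(X), hand)

  ## each row's demographic block sums to exactly 1
  demo <- demographic_cell_ids()
  expect_true(all(Matrix::rowSums(X[, demo]) == 1))
})

test_that("unknown categories and cells are reported by name", {
  tab <- mapping_table(data.frame(code = "A", category = "CC001"))
  prof <- fixture_profiles()
  expect_error(build_design_matrix(prof, design_columns(tab)), "CC002")
  prof2 <- fixture_profiles()
  prof2$demographic_cell[1] <- "F_17_19"
  expect_error(build_design_matrix(prof2, design_columns(tab)), "F_17_19")
})

test_that("least squares solves trivial systems exactly", {
  I5 <- diag(5); colnames(I5) <- paste0("c", 1:5)
  y <- c(3, -1, 0, 2.5, 7)
  expect_equal(unname(fit_least_squares(I5, y)), y)

  set.seed(1)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("c", 1:4)))
  b0 <- c(1, -2, 0.5, 4)
  expect_equal(unname(fit_least_squares(X, X %*% b0)), b0, tolerance = 1e-8)
})

test_that("least squares matches an independent pseudoinverse oracle", {
  set.seed(202)
  for (i in 1:20) {
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("c", 1:4)))
    y <- rnorm(50)
    b <- fit_least_squares(X, y)
    oracle <- drop(MASS::ginv(X) %*% y)
    expect_equal(unname(b), oracle, tolerance = 1e-8)
    ## residual orthogonality contract
    expect_lte(max(abs(t(X) %*% (y - X %*% b))),
               1e-6 * max(abs(t(X) %*% y)))
  }
})

test_that("rank deficiency falls back to the minimum-norm solution", {
  set.seed(3)
  A <- matrix(rnorm(60), 20, 3)
  X <- cbind(A, A[, 3])   # duplicated column -> singular X'X
  colnames(X) <- paste0("c", 1:4)
  y <- rnorm(20)
  b <- fit_least_squares(X, y)
  oracle <- drop(MASS::ginv(X) %*% y)
  expect_equal(unname(b), oracle, tolerance = 1e-8)
  expect_lte(max(abs(t(X) %*% (y - X %*% b))), 1e-6 * max(abs(t(X) %*% y)))

  ## an all-zero column warns and gets coefficient 0
  Z <- cbind(A, 0); colnames(Z) <- paste0("c", 1:4)
  expect_warning(bz <- fit_least_squares(Z, y), "all-zero")
  expect_equal(unname(bz[4]), 0, tolerance = 1e-10)

  expect_error(fit_least_squares(A, rnorm(5)), "dimension mismatch")
})

test_that("prediction is the plain matrix-vector product with order checking", {
  tab <- mapping_table(data.frame(code = c("A", "B"),
                                  category = c("CC001", "CC002")))
  cols <- design_columns(tab)
  X <- build_design_matrix(fixture_profiles(), cols)

  b0 <- setNames(rep(0, ncol(X)), cols)
  expect_identical(unname(predict_utilization(X, b0)), rep(0, 5))

  b <- setNames(seq_len(ncol(X)) / 10, cols)
  hand <- as.numeric(as.matrix(X) %*% b)
  expect_equal(unname(predict_utilization(X, b)), hand)
  ## a unit row (no flags) predicts exactly its cell coefficient
  expect_equal(predict_utilization(X, b)[["b1"]], b[["F_65_69"]])

  expect_error(predict_utilization(X, rev(b)), "do not match")
  expect_error(predict_utilization(X, b[-1]), "do not match")
})

test_that("fitted training mean equals the observed mean via the demographic partition", {
  run <- small_default_run()
  p <- run$params
  mapping <- default_mapping_table(p$n_categories)
  pop <- generate_population(p, mapping)
  arms <- split_train_study(unique(pop$beneficiaries$beneficiary_id),
                            run$split_seed)
  elig <- apply_eligibility(pop$beneficiaries, cohort_spec(2017L))
  train_ids <- intersect(arms$beneficiary_id[arms$arm == "training"], elig)
  prof <- build_condition_profiles(pop$claims, pop$beneficiaries, train_ids,
                                   2017L, mapping)
  X <- build_design_matrix(prof, design_columns(mapping))
  y <- count_admissions(pop$claims, rownames(X), 2018L)
  b <- suppressWarnings(fit_least_squares(X, y))
  expect_equal(mean(as.numeric(X %*% b)), mean(y), tolerance = 1e-8)

  ## the least-squares fit beats any perturbed coefficient vector
  sse <- sum((y - as.numeric(X %*% b))^2)
  set.seed(77)
  for (i in 1:100) {
    bp <- b + rnorm(length(b), sd = 0.01)
    expect_lte(sse, sum((y - as.numeric(X %*% bp))^2))
  }
})
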