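# LOD imputation, missingness filter, logistic fitting, stepwise AIC,
# consensus CV, threshold choice, exhaustive search.

mat_of <- function(vals, cohort = "training") abundance_matrix(vals, cohort)

test_that("LOD imputation uses the per-cohort observed minimum", {
  vals <- matrix(c(5, 7, NA), 3, 1, dimnames = list(paste0("S", 1:3), "PX"))
  m <- impute_lod(mat_of(vals))
  expect_equal(unname(m$values[, "PX"]), c(5, 7, 5))

  # no missing cells: identity
  full <- matrix(1:6, 3, 2, dimnames = list(paste0("S", 1:3), c("PA", "PB")))
  expect_equal(impute_lod(mat_of(full))$values, full)

  # two cohorts impute with their own minima
  vals2 <- matrix(c(5, NA, 2, NA), 4, 1, dimnames = list(paste0("S", 1:4), "PX"))
  m2 <- impute_lod(mat_of(vals2, c("training", "training", "validation", "validation")))
  expect_equal(unname(m2$values[, "PX"]), c(5, 5, 2, 2))

  # observed cells never change; imputed minima equal observed minima
  g <- small_cohort()
  mm <- filter_missing_proteins(summarize_protein_abundance(g$records))
  imp <- impute_lod(mm)
  obs <- !is.na(mm$values)
  expect_equal(imp$values[obs], mm$values[obs])
  expect_equal(apply(imp$values, 2, min),
               apply(mm$values, 2, min, na.rm = TRUE))
  expect_false(any(missing_mask(imp)))

  # a protein entirely missing in one cohort cannot be imputed
  vals3 <- matrix(c(1, 2, NA, NA), 4, 1, dimnames = list(paste0("S", 1:4), "PX"))
  expect_error(impute_lod(mat_of(vals3, rep(c("a", "b"), each = 2))), "PX")
})

test_that("missingness filter is strict at 40%", {
  vals <- matrix(rnorm(300), 100, 3,
                 dimnames = list(sprintf("S%03d", 1:100), c("P41", "P40", "P00")))
  vals[1:41, "P41"] <- NA
  vals[1:40, "P40"] <- NA
  out <- filter_missing_proteins(mat_of(vals))
  expect_identical(attr(out, "removed"), "P41")
  expect_identical(colnames(out$values), c("P40", "P00"))
})

test_that("logistic fit matches closed forms and flags separation", {
  y <- rep(c(0, 1), each = 10)
  f <- fit_logistic(NULL, y)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(f$aic, -2 * 20 * log(0.5) + 2, tolerance = 1e-8)
  expect_false(f$separation)

  # perfectly separable toy data raises the separation flag
  x <- matrix(c(1:10, 21:30), ncol = 1, dimnames = list(NULL, "PX"))
  fs <- fit_logistic(x, y)
  expect_true(fs$separation)

  expect_error(fit_logistic(NULL, rep(1, 5)), "both classes")
})

test_that("logistic fit matches a likelihood grid-search oracle", {
  set.seed(12)
  x <- rnorm(20)
  y <- rbinom(20, 1, plogis(-0.5 + 1.2 * x))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  f <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "PX")), y)
  oracle <- logit_grid_oracle(x, y)
  expect_lt(max(abs(unname(f$coefficients) - oracle)), 1e-3)
})

test_that("stepwise selection minimizes AIC with monotone accepted moves", {
  set.seed(21)
  n <- 400
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("P", 1:10)))
  y <- rbinom(n, 1, plogis(1.5 * x[, "P3"]))
  out <- stepwise_select(x, y)
  expect_true("P3" %in% out$selected)
  expect_true(all(diff(out$aic_trace) < 0))

  # zero candidates: intercept-only model
  empty <- stepwise_select(x[, 0, drop = FALSE], y)
  expect_length(empty$selected, 0)
})

test_that("stepwise recovers a planted predictor across seeds", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("P", 1:10)))
    y <- rbinom(n, 1, plogis(1.2 * x[, "P1"]))
    "P1" %in% stepwise_select(x, y)$selected
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("threshold choice maximizes training accuracy", {
  expect_equal(choose_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1)), 0.5)
  # perfectly inverted scores: a sentinel wins with majority-class accuracy
  inv <- choose_threshold(c(0.9, 0.6, 0.4, 0.1), c(0, 0, 1, 1))
  expect_true(inv %in% c(0, 1))
  acc <- mean((c(0.9, 0.6, 0.4, 0.1) >= inv) == c(0, 0, 1, 1))
  expect_equal(acc, 0.5)
  # constant probabilities: sentinel, majority-class accuracy
  expect_equal(choose_threshold(rep(0.3, 5), c(1, 1, 1, 0, 1)), 0)
  # exhaustive-candidate oracle on random data
  set.seed(5)
  for (i in 1:20) {
    p <- runif(15); l <- rbinom(15, 1, 0.5)
    if (length(unique(l)) < 2) next
    t_star <- choose_threshold(p, l)
    acc_star <- mean((p >= t_star) == l)
    grid <- seq(0, 1, by = 0.001)
    expect_gte(acc_star + 1e-12, max(vapply(grid, function(t) mean((p >= t) == l), 0)))
  }
})

test_that("consensus CV assigns stratified folds and is order-invariant", {
  set.seed(2)
  n <- 200
  vals <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(sprintf("S%03d", 1:n), paste0("P", 1:8)))
  is_case <- rep(c(TRUE, FALSE), each = 100)
  vals[is_case, "P2"] <- vals[is_case, "P2"] + 1.2
  fold <- srmsig:::assign_folds(rownames(vals), is_case, 10, seed = 1)
  expect_equal(as.vector(table(fold)), rep(20L, 10))
  for (f in 1:10) {
    expect_equal(sum(is_case[fold[rownames(vals)] == f]), 10L)
  }

  cv <- consensus_cv(mat_of(vals), is_case, seed = 77)
  expect_true("P2" %in% cv$model$protein_ids)
  expect_true(all(cv$report$fold_auc > 0.5, na.rm = TRUE))
  # same seed, permuted subject order: identical consensus and threshold
  perm <- sample(n)
  cv2 <- consensus_cv(mat_of(vals[perm, ]), is_case[perm], seed = 77)
  expect_identical(cv2$model$protein_ids, cv$model$protein_ids)
  expect_equal(cv2$model$coefficients, cv$model$coefficients)
  expect_equal(cv2$model$threshold, cv$model$threshold)
})

test_that("an empty consensus is an explicit no-signature result", {
  set.seed(9)
  vals <- matrix(rnorm(100 * 6), 100, 6,
                 dimnames = list(sprintf("S%03d", 1:100), paste0("P", 1:6)))
  cv <- consensus_cv(mat_of(vals), rep(c(TRUE, FALSE), 50), seed = 5)
  expect_length(cv$model$protein_ids, 0)
  expect_true(isTRUE(cv$model$no_stable_signature))
})

test_that("probability prediction is the inverse-logit linear predictor", {
  m0 <- srmsig:::new_signature_model("PX", 0, intercept = 0)
  vals <- matrix(c(-2, 0, 2), 3, 1, dimnames = list(paste0("S", 1:3), "PX"))
  expect_equal(unname(predict_probability(m0, vals)), rep(0.5, 3))

  m1 <- srmsig:::new_signature_model("PX", 2, intercept = -1)
  expect_equal(unname(predict_probability(m1, vals))[2], plogis(-1))
  expect_equal(unname(predict_probability(m1, matrix(1, 1, 1,
    dimnames = list("s", "PX")))), 1 / (1 + exp(-1)))
  # monotone in a positively weighted protein
  p <- unname(predict_probability(m1, vals))
  expect_true(all(diff(p) > 0))
  expect_error(predict_probability(m1, vals[, 0, drop = FALSE]), "PX")
})

test_that("exhaustive search enumerates all subsets and ranks by median AUC", {
  set.seed(14)
  n <- 60
  vals <- matrix(rnorm(n * 3), n, 3, dimnames = list(sprintf("S%02d", 1:n), paste0("P", 1:3)))
  is_case <- rep(c(TRUE, FALSE), each = n / 2)
  res <- exhaustive_search(mat_of(vals), is_case, max_size = 2, B = 10, seed = 2)
  expect_equal(res$n_models, 6)
  expect_equal(nrow(res$models), 6)
  expect_true(all(diff(res$models$median_auc) <= 0))

  vals5 <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("S%02d", 1:n), paste0("P", 1:5)))
  res5 <- exhaustive_search(mat_of(vals5), is_case, max_size = 5, B = 5, seed = 2)
  expect_equal(res5$n_models, 31)

  # refusal above the pool cap names the model count
  big <- matrix(rnorm(n * 16), n, 16,
                dimnames = list(sprintf("S%02d", 1:n), paste0("P", 1:16)))
  expect_error(exhaustive_search(mat_of(big), is_case), "restrict the candidate pool")
})

test_that("a dominant planted marker tops the exhaustive protein ranking", {
  set.seed(33)
  n <- 120
  vals <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("S%03d", 1:n), paste0("P", 1:6)))
  is_case <- rep(c(TRUE, FALSE), each = n / 2)
  vals[is_case, "P4"] <- vals[is_case, "P4"] + 2
  res <- exhaustive_search(mat_of(vals), is_case, max_size = 3, B = 30, seed = 4)
  expect_equal(names(res$protein_frequency)[1], "P4")
  expect_true(grepl("P4", res$models$proteins[1]))
})

test_that("exhaustive search is seed-deterministic", {
  set.seed(3)
  vals <- matrix(rnorm(40 * 4), 40, 4,
                 dimnames = list(sprintf("S%02d", 1:40), paste0("P", 1:4)))
  is_case <- rep(c(TRUE, FALSE), 20)
  a <- exhaustive_search(mat_of(vals), is_case, max_size = 2, B = 20, seed = 9)
  b <- exhaustive_search(mat_of(vals), is_case, max_size = 2, B = 20, seed = 9)
  expect_identical(a$models, b$models)
})
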