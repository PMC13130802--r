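test_that("accuracy metrics match hand-computed oracles", {
  # R^2 = 1 - SSE/TSS on y = (1,2,3), yhat = (1,2,4): 1 - 1/2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0.0)   # mean predictor
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")

  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(mae(c(0, 0), c(3, 4)), 3.5)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(mae(1:5, 1:5), 0)
})

test_that("RMSE is never smaller than MAE", {
  withr::with_seed(31, {
    for (i in 1:25) {
      y <- rnorm(sample(3:30, 1))
      yhat <- y + rnorm(length(y), 0, runif(1, 0.1, 3))
      expect_gte(rmse(y, yhat), mae(y, yhat) - 1e-12)
    }
  })
})

test_that("data splitting follows the ceiling convention and is seed-stable", {
  d729 <- tibble::tibble(x = seq_len(729))
  s <- split_data(d729, fraction = 0.75, seed = 126)
  expect_equal(nrow(s$train), 547)
  expect_equal(nrow(s$test), 182)

  d58 <- tibble::tibble(x = seq_len(58))
  s58 <- split_data(d58, fraction = 0.75, seed = 117)
  expect_equal(nrow(s58$train), 44)
  expect_equal(nrow(s58$test), 14)

  d4 <- tibble::tibble(x = 1:4)
  s4 <- split_data(d4, fraction = 0.75, seed = 1)
  expect_equal(nrow(s4$train), 3)
  expect_equal(nrow(s4$test), 1)

  expect_identical(split_data(d58, seed = 5), split_data(d58, seed = 5))
  expect_false(identical(split_data(d58, seed = 5), split_data(d58, seed = 6)))
  expect_equal(intersect(split_data(d58, seed = 5)$train$x,
                         split_data(d58, seed = 5)$test$x), integer(0))
  expect_error(split_data(d58, fraction = 1.2), "fraction")
})

test_that("spot-check recovers a linear signal and reproduces itself under one seed", {
  d <- linear_dataset()
  cl <- classify_variables(d, roles = linear_roles)
  sp <- split_data(d, seed = 11)
  algs <- c("PLS", "ElasticNet", "kNN")
  sc1 <- spot_check(sp$train, sp$test, cl, algorithms = algs,
                    cv = cv_control(k = 5, repeats = 2), seed = 126)
  sc2 <- spot_check(sp$train, sp$test, cl, algorithms = algs,
                    cv = cv_control(k = 5, repeats = 2), seed = 126)
  expect_identical(tidy(sc1), tidy(sc2))

  tb <- tidy(sc1)
  expect_gt(max(tb$test_r2[tb$algorithm %in% c("PLS", "ElasticNet")]), 0.9)

  # stored test predictions regenerate the reported metrics exactly
  m <- select_best(sc1, "y")
  expect_equal(r_squared(m$test_predictions$actual,
                         m$test_predictions$predicted), m$test$r2)
  expect_equal(rmse(m$test_predictions$actual,
                    m$test_predictions$predicted), m$test$rmse)
})

test_that("a pure-noise response yields near-zero test accuracy, not spurious fit", {
  withr::with_seed(42, {
    d <- tibble::tibble(x1 = runif(150), x2 = runif(150), y = rnorm(150))
  })
  cl <- classify_variables(d, roles = c(x1 = "B", x2 = "B", y = "D"))
  sp <- split_data(d, seed = 2)
  sc <- spot_check(sp$train, sp$test, cl,
                   algorithms = c("ElasticNet", "kNN"),
                   cv = cv_control(k = 5, repeats = 1), seed = 3)
  expect_lt(max(tidy(sc)$test_r2), 0.3)
})

test_that("algorithm failures are recorded without aborting the spot-check", {
  d <- linear_dataset(n = 60)
  d$flat <- 1.0   # constant response: R^2 undefined -> learner entry fails
  cl <- classify_variables(d, roles = c(linear_roles, flat = "D"))
  sp <- split_data(d, seed = 4)
  sc <- spot_check(sp$train, sp$test, cl, algorithms = c("ElasticNet"),
                   cv = cv_control(k = 3, repeats = 1), seed = 5)
  tb <- tidy(sc)
  expect_true(tb$failed[tb$response == "flat"])
  expect_false(tb$failed[tb$response == "y"])
  expect_error(select_best(sc, "flat"), "no successful model")
})

test_that("non-varying predictors are removed before training", {
  d <- linear_dataset(n = 80)
  d$const <- 7
  cl <- classify_variables(d, roles = c(linear_roles, const = "B"))
  sp <- split_data(d, seed = 8)
  sc <- spot_check(sp$train, sp$test, cl, algorithms = "ElasticNet",
                   cv = cv_control(k = 3, repeats = 1), seed = 8)
  expect_true("const" %in% sc$dropped_predictors)
  expect_false("const" %in% sc$predictors)
})

test_that("feature importance concentrates on the informative predictor", {
  d <- linear_dataset(n = 150, noise_sd = 0.1)
  cl <- classify_variables(d, roles = linear_roles)
  sp <- split_data(d, seed = 21)
  sc <- spot_check(sp$train, sp$test, cl, algorithms = c("RF", "ElasticNet"),
                   cv = cv_control(k = 3, repeats = 1), seed = 21)
  for (alg in c("RF", "ElasticNet")) {
    res <- sc$results[[paste0("y.", alg)]]
    fi <- feature_importance(res)
    expect_equal(fi$predictor[1], "x1")
    expect_equal(fi$importance[1], 100)
    expect_true(all(fi$importance[-1] < 40))
  }
})

test_that("best-model selection ranks by test R2, then RMSE, then MAE, then name", {
  fake <- function(alg, r2, rm, ma) {
    structure(list(algorithm = alg, response = "y", failed = FALSE,
                   test = list(r2 = r2, rmse = rm, mae = ma)),
              class = "model_result")
  }
  mk <- function(...) {
    structure(list(results = list(...), responses = "y"),
              class = "spot_check")
  }
  sc <- mk(a = fake("A", 0.91, 1, 1), b = fake("B", 0.88, 0.5, 0.5))
  expect_equal(select_best(sc, "y")$algorithm, "A")

  sc2 <- mk(a = fake("A", 0.90, 0.56, 1), b = fake("B", 0.90, 0.52, 1))
  expect_equal(select_best(sc2, "y")$algorithm, "B")

  sc3 <- mk(a = fake("A", 0.9, 0.5, 0.7), b = fake("B", 0.9, 0.5, 0.6))
  expect_equal(select_best(sc3, "y")$algorithm, "B")

  sc4 <- mk(a = fake("Z", 0.9, 0.5, 0.6))
  expect_equal(select_best(sc4, "y")$algorithm, "Z")
})

test_that("LOOCV engages for small training sets and the explicit config overrides it", {
  d <- linear_dataset(n = 40)
  cl <- classify_variables(d, roles = linear_roles)
  sp <- split_data(d, fraction = 0.75, seed = 3)   # 30 train rows < 50
  sc <- spot_check(sp$train, sp$test, cl, algorithms = "ElasticNet",
                   cv = cv_control(k = 5, repeats = 3), seed = 3)
  r <- sc$results[["y.ElasticNet"]]
  # LOOCV pools all holdouts into one metric set: sd is NA
  expect_true(is.na(r$cv$r2_sd))
  sc2 <- spot_check(sp$train, sp$test, cl, algorithms = "ElasticNet",
                    cv = cv_control(k = 4, repeats = 2, loocv = FALSE),
                    seed = 3)
  expect_false(is.na(sc2$results[["y.ElasticNet"]]$cv$r2_sd))
})
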