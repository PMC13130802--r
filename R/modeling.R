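#' Split data into training and test sets
#'
#' Seeded simple random partition. The training set receives
#' `ceiling(n * fraction)` rows, so 729 rows at the default 75% give
#' 547 training and 182 test observations, and 58 rows give 44/14.
#' Cross-validation inside [spot_check()] stands in for a separate
#' validation set.
#'
#' @param data A data frame.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A list with `train` and `test` tibbles.
#' @examples
#' s <- split_data(data.frame(x = 1:8, y = rnorm(8)), seed = 1)
#' nrow(s$train)  # 6
#' @export
split_data <- function(data, fraction = 0.75, seed = NULL) {
  n <- nrow(data)
  stopifnot(n >= 4L)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- as.integer(ceiling(n * fraction))
  idx <- with_seed(seed, sample.int(n, n_train))
  data <- tibble::as_tibble(data)
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Cross-validation settings
#'
#' Repeated k-fold cross-validation (default fivefold with 3 repetitions)
#' used for hyperparameter grid search. For small training sets
#' (`n < 50`) leave-one-out cross-validation is used instead, unless
#' `loocv` is set to `TRUE`/`FALSE` explicitly — use cases with their own
#' stated fold configuration override the rule.
#'
#' @param k Number of folds (>= 2).
#' @param repeats Number of repetitions (>= 1).
#' @param loocv `"auto"` (LOOCV when n < 50), or a logical to force.
#' @return A `cv_control` list.
#' @export
cv_control <- function(k = 5L, repeats = 3L, loocv = "auto") {
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 loocv = loocv),
            class = "cv_control")
}

# fold assignments: list over repeats of integer fold id per row
make_folds <- function(n, cv) {
  use_loocv <- identical(cv$loocv, TRUE) ||
    (identical(cv$loocv, "auto") && n < 50L)
  if (use_loocv) {
    return(list(seq_len(n)))
  }
  k <- min(cv$k, n)
  lapply(seq_len(cv$repeats), function(r) {
    rep_len(seq_len(k), n)[sample.int(n)]
  })
}

# grid search one (response, algorithm) by repeated k-fold CV; returns the
# winning parameter row plus per-fold metrics for it
cv_grid_search <- function(x, y, algorithm, grid, folds, base_seed) {
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fold_r2 <- fold_rmse <- fold_mae <- numeric(0)
    loocv <- length(folds) == 1L && length(unique(folds[[1]])) == length(y)
    if (loocv) {
      # LOOCV: single-observation holdouts; metrics pooled over all n
      preds <- rep(NA_real_, length(y))
      for (i in seq_along(y)) {
        set.seed(base_seed + 7L * i)
        m <- fit_learner(algorithm, x[-i, , drop = FALSE], y[-i], params)
        preds[i] <- predict(m, as.data.frame(x[i, , drop = FALSE]))
      }
      fold_r2 <- r_squared(y, preds)
      fold_rmse <- rmse(y, preds)
      fold_mae <- mae(y, preds)
    } else {
      for (r in seq_along(folds)) {
        fid <- folds[[r]]
        for (f in sort(unique(fid))) {
          tr <- fid != f
          set.seed(base_seed + 131L * r + 7L * f)
          m <- fit_learner(algorithm, x[tr, , drop = FALSE], y[tr], params)
          ph <- predict(m, as.data.frame(x[!tr, , drop = FALSE]))
          if (stats::var(y[!tr]) > 0) fold_r2 <- c(fold_r2, r_squared(y[!tr], ph))
          fold_rmse <- c(fold_rmse, rmse(y[!tr], ph))
          fold_mae <- c(fold_mae, mae(y[!tr], ph))
        }
      }
    }
    results[[g]] <- list(params = params, rmse = mean(fold_rmse),
                         fold_r2 = fold_r2, fold_rmse = fold_rmse,
                         fold_mae = fold_mae)
  }
  best <- which.min(vapply(results, `[[`, numeric(1), "rmse"))
  results[[best]]
}

#' Automated regression spot-check
#'
#' Trains the full algorithm roster for every response, tuning each by
#' repeated k-fold cross-validation (LOOCV below 50 training rows) on the
#' training set, refitting the winning settings on the full training set
#' and scoring once on the held-out test set. Non-varying predictors are
#' removed before training. All randomness derives from the single
#' `seed`, so a rerun with the same data and configuration reproduces the
#' metrics table bit for bit. An algorithm that errors on a response is
#' recorded as failed and the run continues.
#'
#' The stacked ensemble (`"ESR"`) is excluded from the default roster, as
#' is standard for the spot-check; request it explicitly via
#' `algorithms`. Center-scale preprocessing of predictors is not applied
#' to the data passed to tree learners (scale-invariant); learners that
#' need scaling do it internally and undo it at prediction time.
#'
#' @param train,test Data frames from [split_data()] (already
#'   integer-encoded for Type-C columns).
#' @param classification A `variable_roles` table.
#' @param responses Response columns to model; default all Type-D columns.
#' @param algorithms Algorithm ids among PLS, ElasticNet, RF, GBT, ESR,
#'   MARS, kNN, SVM, ANN.
#' @param cv A [cv_control()].
#' @param seed Integer ML seed.
#' @param grids Optional replacement for [default_grids()].
#' @return A `spot_check` object; see [tidy.spot_check()],
#'   [select_best()], [feature_importance()].
#' @export
spot_check <- function(train, test, classification, responses = NULL,
                       algorithms = setdiff(ALGORITHMS, "ESR"),
                       cv = cv_control(), seed = 1L, grids = NULL) {
  validate_roles(classification)
  stopifnot(all(algorithms %in% ALGORITHMS))
  if (is.null(responses)) responses <- roles_of(classification, "D")
  predictors <- intersect(roles_of(classification, c("B", "C")), names(train))
  if (!all(vapply(train[predictors], is.numeric, logical(1)))) {
    stop("non-numeric predictor present; run encode_categoricals() first",
         call. = FALSE)
  }
  # removal of non-varying predictors
  varying <- predictors[vapply(predictors, function(p) {
    v <- stats::var(train[[p]])
    is.finite(v) && v > 0
  }, logical(1))]
  dropped <- setdiff(predictors, varying)

  xtr <- as.matrix(train[, varying, drop = FALSE])
  xte <- as.matrix(test[, varying, drop = FALSE])
  storage.mode(xtr) <- storage.mode(xte) <- "double"
  if (is.null(grids)) grids <- default_grids(ncol(xtr), nrow(xtr))

  folds <- with_seed(seed, make_folds(nrow(xtr), cv))

  results <- list()
  for (ri in seq_along(responses)) {
    resp <- responses[[ri]]
    ytr <- train[[resp]]
    yte <- test[[resp]]
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[[ai]]
      base_seed <- seed + 10000L * ri + 100L * ai
      entry <- tryCatch({
        cvres <- cv_grid_search(xtr, ytr, alg, grids[[alg]], folds, base_seed)
        set.seed(base_seed + 1L)
        model <- fit_learner(alg, xtr, ytr, cvres$params)
        pred_tr <- predict(model, as.data.frame(xtr))
        pred_te <- predict(model, as.data.frame(xte))
        set.seed(base_seed + 2L)
        imp <- normalize_importance(learner_importance(model, xtr, ytr))
        structure(list(
          algorithm = alg, response = resp, params = cvres$params,
          cv = list(r2_mean = mean(cvres$fold_r2), r2_sd = stats::sd(cvres$fold_r2),
                    rmse_mean = mean(cvres$fold_rmse), rmse_sd = stats::sd(cvres$fold_rmse),
                    mae_mean = mean(cvres$fold_mae), mae_sd = stats::sd(cvres$fold_mae)),
          train = list(r2 = r_squared(ytr, pred_tr), rmse = rmse(ytr, pred_tr),
                       mae = mae(ytr, pred_tr)),
          test = list(r2 = r_squared(yte, pred_te), rmse = rmse(yte, pred_te),
                      mae = mae(yte, pred_te)),
          test_predictions = tibble::tibble(actual = yte, predicted = pred_te),
          importance = imp, model = model, failed = FALSE, error = NA_character_
        ), class = "model_result")
      }, error = function(e) {
        structure(list(algorithm = alg, response = resp, failed = TRUE,
                       error = conditionMessage(e)),
                  class = "model_result")
      })
      results[[paste(resp, alg, sep = ".")]] <- entry
    }
  }
  structure(list(results = results, responses = responses,
                 algorithms = algorithms, predictors = varying,
                 dropped_predictors = dropped, cv = cv, seed = seed,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "spot_check")
}

#' @export
print.spot_check <- function(x, ...) {
  cat(sprintf("# Regression spot-check: %d response(s) x %d algorithm(s), %d/%d train/test rows\n",
              length(x$responses), length(x$algorithms), x$n_train, x$n_test))
  print(tidy(x))
  invisible(x)
}

#' Tidy a spot-check into a metrics table
#'
#' @param x A `spot_check` object.
#' @param ... Unused.
#' @return One row per (response, algorithm): cross-validation mean and sd,
#'   train and test R-squared, RMSE and MAE, plus a `failed` flag.
#' @export
tidy.spot_check <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    if (r$failed) {
      return(tibble::tibble(response = r$response, algorithm = r$algorithm,
                            failed = TRUE))
    }
    tibble::tibble(
      response = r$response, algorithm = r$algorithm,
      cv_r2 = r$cv$r2_mean, cv_r2_sd = r$cv$r2_sd,
      train_r2 = r$train$r2, test_r2 = r$test$r2,
      cv_rmse = r$cv$rmse_mean, train_rmse = r$train$rmse,
      test_rmse = r$test$rmse, test_mae = r$test$mae, failed = FALSE
    )
  })
}

#' @export
glance.spot_check <- function(x, ...) {
  tb <- tidy(x)
  ok <- tb[!tb$failed, , drop = FALSE]
  tibble::tibble(
    n_models = nrow(tb), n_failed = sum(tb$failed),
    n_train = x$n_train, n_test = x$n_test,
    best_test_r2 = if (nrow(ok)) max(ok$test_r2) else NA_real_,
    seed = x$seed
  )
}

#' Select the best model for a response
#'
#' Purely data-driven selection on the unseen test set: the highest test
#' R-squared wins, ties broken by lower test RMSE, then lower test MAE,
#' then algorithm name.
#'
#' @param x A `spot_check` object.
#' @param response Response column name.
#' @return The winning `model_result`.
#' @export
select_best <- function(x, response) {
  stopifnot(inherits(x, "spot_check"))
  cand <- purrr::keep(x$results, ~ identical(.x$response, response) && !.x$failed)
  if (length(cand) == 0L) {
    stop("no successful model for response '", response, "'", call. = FALSE)
  }
  ord <- order(-vapply(cand, function(r) r$test$r2, numeric(1)),
               vapply(cand, function(r) r$test$rmse, numeric(1)),
               vapply(cand, function(r) r$test$mae, numeric(1)),
               vapply(cand, function(r) r$algorithm, character(1)))
  cand[[ord[1L]]]
}

#' Ranked feature importance of one fitted model
#'
#' Tree ensembles report impurity-based importance, linear models absolute
#' standardized coefficients, all other algorithms permutation importance
#' on the training data; scores are scaled so the strongest predictor
#' reads 100.
#'
#' @param model_result A `model_result` from [spot_check()].
#' @return A tibble `(predictor, importance)` sorted by decreasing score.
#' @export
feature_importance <- function(model_result) {
  stopifnot(inherits(model_result, "model_result"))
  if (model_result$failed) stop("model fit failed; no importance available",
                                call. = FALSE)
  imp <- sort(model_result$importance, decreasing = TRUE)
  tibble::tibble(predictor = names(imp), importance = unname(imp))
}

#' @export
print.model_result <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<model %s / %s: FAILED (%s)>\n", x$algorithm, x$response, x$error))
  } else {
    cat(sprintf("<model %s / %s: test R2 %.3f, RMSE %.3g, MAE %.3g>\n",
                x$algorithm, x$response, x$test$r2, x$test$rmse, x$test$mae))
  }
  invisible(x)
}

#' @export
predict.model_result <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' @export
glance.model_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, response = x$response,
                 cv_r2 = x$cv$r2_mean, train_r2 = x$train$r2,
                 test_r2 = x$test$r2, test_rmse = x$test$rmse,
                 test_mae = x$test$mae)
}

#' Plot spot-check performance
#'
#' Grouped bars of cross-validation, train and test R-squared per
#' algorithm, one facet per response.
#'
#' @param object A `spot_check` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spot_check <- function(object, ...) {
  tb <- tidy(object)
  tb <- tb[!tb$failed, , drop = FALSE]
  long <- tidyr::pivot_longer(
    tb[, c("response", "algorithm", "cv_r2", "train_r2", "test_r2")],
    cols = c("cv_r2", "train_r2", "test_r2"),
    names_to = "partition", values_to = "r2")
  ggplot2::ggplot(long, ggplot2::aes(.data$algorithm, .data$r2,
                                     fill = .data$partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
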