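#' Define one optimization objective
#'
#' Couples a response to a trained surrogate model, an optimization
#' direction and the observed extremes of that response in the ML
#' dataset. Raw model predictions are min-max normalized against
#' `[y_min, y_max]`, direction-corrected (minimization objectives are
#' reflected as `1 - normalized`) and summed into the cumulative fitness
#' that ranges from 0 (worst) to the number of objectives (best).
#'
#' @param response Response column name.
#' @param direction `"maximize"` or `"minimize"`.
#' @param model A fitted `model_result` (or any object with a `predict`
#'   method taking `newdata`).
#' @param y_min,y_max Observed minimum and maximum of the response in the
#'   ML dataset (`y_max > y_min`).
#' @return An `objective_spec`.
#' @export
objective_spec <- function(response, direction = c("maximize", "minimize"),
                           model = NULL, y_min, y_max) {
  direction <- match.arg(direction)
  if (!(is.numeric(y_min) && is.numeric(y_max) && y_max > y_min)) {
    stop("objective '", response, "': y_max must exceed y_min", call. = FALSE)
  }
  structure(list(response = response, direction = direction, model = model,
                 y_min = y_min, y_max = y_max),
            class = "objective_spec")
}

#' Build objective specs from selected models and the ML dataset
#'
#' @param models Named list mapping response name to a fitted model
#'   (e.g. the output of [select_best()] per response).
#' @param data The ML dataset the models were trained on; supplies the
#'   observed `y_min`/`y_max` per response.
#' @param directions Named character vector, `"maximize"` (default) or
#'   `"minimize"` per response.
#' @return A list of `objective_spec`s.
#' @export
objectives_from_models <- function(models, data, directions = NULL) {
  purrr::imap(models, function(m, resp) {
    dir <- if (!is.null(directions) && resp %in% names(directions)) {
      directions[[resp]]
    } else "maximize"
    objective_spec(resp, dir, model = m,
                   y_min = min(data[[resp]], na.rm = TRUE),
                   y_max = max(data[[resp]], na.rm = TRUE))
  })
}

#' Fitness normalization and aggregation
#'
#' `normalize_fitness()` rescales a raw prediction to
#' `(raw - y_min) / (y_max - y_min)`, clipped into `[0, 1]` when the
#' surrogate extrapolates beyond the observed range.
#' `direction_correct()` leaves maximization objectives unchanged and
#' reflects minimization objectives as `1 - normalized`.
#' `cumulative_fitness()` sums the corrected components, giving a value
#' in `[0, n]` for `n` objectives.
#'
#' @param raw Raw predicted value(s).
#' @param spec An `objective_spec`.
#' @return Numeric of the same length as the input.
#' @examples
#' sp <- objective_spec("y", "minimize", y_min = 0, y_max = 100)
#' normalize_fitness(50, sp)          # 0.5
#' direction_correct(0.3, "minimize") # 0.7
#' cumulative_fitness(c(1, 1, 1, 1))  # 4
#' @export
normalize_fitness <- function(raw, spec) {
  z <- (raw - spec$y_min) / (spec$y_max - spec$y_min)
  pmin(1, pmax(0, z))
}

#' @rdname normalize_fitness
#' @param normalized Normalized fitness value(s) in `[0, 1]`.
#' @param direction `"maximize"` or `"minimize"`.
#' @export
direction_correct <- function(normalized, direction) {
  if (direction == "minimize") 1 - normalized else normalized
}

#' @rdname normalize_fitness
#' @param corrected Vector of direction-corrected components in `[0, 1]`.
#' @export
cumulative_fitness <- function(corrected) sum(corrected)

#' Extract decision-variable bounds from the ML dataset
#'
#' Continuous (Type B) predictors receive bounds
#' `[min - p * range, max + p * range]` with `p` the extrapolation
#' fraction (default 0, i.e. stay inside the training data); expanded
#' lower bounds are floored at 0 for non-negative quantities such as
#' media component concentrations (flagged per variable). Integer-coded
#' categorical (Type C) predictors receive the integer range of their
#' codes. Constant predictors are excluded with a warning.
#'
#' @param data The (encoded) ML dataset.
#' @param classification A `variable_roles` table.
#' @param extrapolation Per-side range expansion fraction, `>= 0`.
#' @param nonnegative Floor expanded lower bounds at zero for variables
#'   observed non-negative (default `TRUE`).
#' @return A `decision_space` tibble: `variable`, `kind`, `lower`,
#'   `upper`, `n_levels`, `floored`.
#' @export
extract_bounds <- function(data, classification, extrapolation = 0,
                           nonnegative = TRUE) {
  stopifnot(extrapolation >= 0)
  bcols <- intersect(roles_of(classification, "B"), names(data))
  ccols <- intersect(roles_of(classification, "C"), names(data))
  rows <- list()
  for (col in bcols) {
    x <- data[[col]]
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (hi <= lo) {
      warning("constant predictor '", col, "' excluded from the decision space")
      next
    }
    r <- hi - lo
    lower <- lo - extrapolation * r
    upper <- hi + extrapolation * r
    floored <- FALSE
    if (nonnegative && lo >= 0 && lower < 0) {
      lower <- 0
      floored <- TRUE
    }
    rows[[col]] <- tibble::tibble(variable = col, kind = "continuous",
                                  lower = lower, upper = upper,
                                  n_levels = NA_integer_, floored = floored)
  }
  for (col in ccols) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      stop("categorical predictor '", col, "' is not integer-encoded; ",
           "run encode_categoricals() first", call. = FALSE)
    }
    L <- max(x, na.rm = TRUE) + 1L
    if (L < 2L) {
      warning("constant predictor '", col, "' excluded from the decision space")
      next
    }
    rows[[col]] <- tibble::tibble(variable = col, kind = "categorical",
                                  lower = 0, upper = L - 1,
                                  n_levels = as.integer(L), floored = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no usable decision variables", call. = FALSE)
  class(out) <- c("decision_space", class(out))
  out
}

#' Constraint rules with penalty weights
#'
#' `constraint_single()` bounds one variable
#' (e.g. auxin concentration <= 2), `constraint_sum()` bounds the sum of
#' a variable set (e.g. total growth regulators <= 5). A candidate's
#' penalty is `weight * max(0, violation)` summed over rules and is
#' subtracted from its (cumulative) fitness; for dominance sorting,
#' feasible candidates dominate infeasible ones and smaller violations
#' dominate larger ones.
#'
#' @param variable,variables Decision-variable name(s).
#' @param bound Bound value in actual units.
#' @param sense `"<="` or `">="`.
#' @param weight Non-negative penalty weight (default 1).
#' @return A `constraint_rule`.
#' @export
constraint_single <- function(variable, bound, sense = c("<=", ">="),
                              weight = 1) {
  sense <- match.arg(sense)
  stopifnot(weight >= 0)
  structure(list(type = "single_bound", variables = variable, bound = bound,
                 sense = sense, weight = weight),
            class = "constraint_rule")
}

#' @rdname constraint_single
#' @export
constraint_sum <- function(variables, bound, sense = c("<=", ">="),
                           weight = 1) {
  sense <- match.arg(sense)
  stopifnot(weight >= 0, length(variables) >= 1L)
  structure(list(type = "sum_bound", variables = variables, bound = bound,
                 sense = sense, weight = weight),
            class = "constraint_rule")
}

# total weighted penalty per row of the decision matrix (actual units)
penalty_total <- function(X, vars, constraints) {
  if (length(constraints) == 0L) return(rep(0, nrow(X)))
  pen <- rep(0, nrow(X))
  for (cn in constraints) {
    missing_vars <- setdiff(cn$variables, vars)
    if (length(missing_vars)) {
      stop("constraint references unknown variable(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    val <- rowSums(X[, match(cn$variables, vars), drop = FALSE])
    viol <- if (cn$sense == "<=") pmax(0, val - cn$bound)
            else pmax(0, cn$bound - val)
    pen <- pen + cn$weight * viol
  }
  pen
}

# round half-up and clip categorical coordinates
round_categoricals <- function(X, space) {
  cat_idx <- which(space$kind == "categorical")
  for (j in cat_idx) {
    X[, j] <- pmin(space$upper[j], pmax(space$lower[j], floor(X[, j] + 0.5)))
  }
  X
}

#' Surrogate optimization problem
#'
#' Bundles objective specs, the decision space and constraint rules into
#' the evaluation function used by the optimizers. Each candidate is
#' processed as: round categorical coordinates half-up to the nearest
#' valid code, predict every objective with its surrogate model, apply
#' min-max normalization, direction correction and cumulation, and
#' subtract the weighted constraint penalty. An internal prediction cache
#' (keyed on the rounded decision vector) skips re-evaluating candidates
#' regenerated in later generations; disable it with `cache = FALSE`
#' when exact evaluation accounting is required.
#'
#' @param objectives List of [objective_spec()]s (each with a model).
#' @param space A `decision_space` from [extract_bounds()].
#' @param constraints List of `constraint_rule`s.
#' @param cache Enable the prediction cache (default `TRUE`).
#' @return An `optimization_problem`.
#' @export
surrogate_problem <- function(objectives, space, constraints = list(),
                              cache = TRUE) {
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  stopifnot(length(objectives) >= 1L,
            all(vapply(objectives, inherits, logical(1), "objective_spec")))
  for (ob in objectives) {
    if (is.null(ob$model)) stop("objective '", ob$response, "' has no model",
                                call. = FALSE)
  }
  vars <- space$variable
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$hits <- 0L
  env$cache <- new.env(parent = emptyenv())

  eval_fn <- function(X) {
    X <- matrix(X, ncol = length(vars))
    X <- round_categoricals(X, space)
    n <- nrow(X)
    keys <- apply(X, 1, function(r) paste(format(r, digits = 15), collapse = "|"))
    m <- length(objectives)
    raw <- matrix(NA_real_, n, m)
    cached <- logical(n)
    if (cache) {
      for (i in seq_len(n)) {
        hit <- get0(keys[i], envir = env$cache, inherits = FALSE)
        if (!is.null(hit)) {
          raw[i, ] <- hit
          cached[i] <- TRUE
        }
      }
    }
    todo <- which(!cached)
    env$hits <- env$hits + sum(cached)
    if (length(todo)) {
      nd <- tibble::as_tibble(as.data.frame(X[todo, , drop = FALSE]))
      names(nd) <- vars
      for (k in seq_len(m)) {
        raw[todo, k] <- tryCatch(
          as.numeric(predict(objectives[[k]]$model, nd)),
          error = function(e) {
            warning("surrogate prediction failed (", conditionMessage(e),
                    "); candidates assigned worst fitness")
            rep(objectives[[k]]$y_min, length(todo))
          })
      }
      env$count <- env$count + length(todo)
      if (cache) {
        for (i in todo) assign(keys[i], raw[i, ], envir = env$cache)
      }
    }
    corrected <- vapply(seq_len(m), function(k) {
      direction_correct(normalize_fitness(raw[, k], objectives[[k]]),
                        objectives[[k]]$direction)
    }, numeric(n))
    corrected <- matrix(corrected, nrow = n)
    pen <- penalty_total(X, vars, constraints)
    list(X = X, raw = raw, corrected = corrected,
         cumulative = rowSums(corrected), penalty = pen,
         F = 1 - corrected)     # internal minimization scale
  }

  structure(list(
    kind = "surrogate", eval = eval_fn, vars = vars, space = space,
    objectives = objectives, constraints = constraints,
    n_obj = length(objectives),
    lower = space$lower, upper = space$upper,
    responses = vapply(objectives, `[[`, character(1), "response"),
    counter = function() env$count, cache_hits = function() env$hits,
    reset = function() { env$count <- 0L; env$hits <- 0L
                         env$cache <- new.env(parent = emptyenv()) }
  ), class = "optimization_problem")
}

#' Direct (non-surrogate) optimization problem
#'
#' Wraps an analytic vector-valued function for benchmark studies
#' (e.g. ZDT2) and for exact evaluation accounting: the counter
#' increments by one per candidate row evaluated, with no cache.
#' Objectives are minimized internally.
#'
#' @param fn Function taking an `n x d` matrix and returning an
#'   `n x n_obj` matrix of objective values (minimization orientation).
#' @param lower,upper Bound vectors of length `d`.
#' @param n_obj Number of objectives.
#' @return An `optimization_problem`.
#' @export
direct_problem <- function(fn, lower, upper, n_obj = 1L) {
  stopifnot(length(lower) == length(upper), all(upper > lower), n_obj >= 1L)
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  d <- length(lower)
  vars <- paste0("x", seq_len(d))
  eval_fn <- function(X) {
    X <- matrix(X, ncol = d)
    F <- fn(X)
    F <- matrix(F, nrow = nrow(X))
    env$count <- env$count + nrow(X)
    list(X = X, raw = F, corrected = NULL, cumulative = rep(NA_real_, nrow(X)),
         penalty = rep(0, nrow(X)), F = F)
  }
  structure(list(
    kind = "direct", eval = eval_fn, vars = vars, space = NULL,
    objectives = NULL, constraints = list(), n_obj = as.integer(n_obj),
    lower = lower, upper = upper, responses = paste0("f", seq_len(n_obj)),
    counter = function() env$count, cache_hits = function() 0L,
    reset = function() env$count <- 0L
  ), class = "optimization_problem")
}

#' Evaluate a single candidate
#'
#' Runs one decision vector through the full evaluation pipeline of a
#' problem — categorical rounding, surrogate prediction, normalization,
#' direction correction, cumulative fitness and penalty — and returns
#' the solution record as a one-row tibble.
#'
#' @param x Decision vector (continuous values and raw categorical
#'   coordinates; rounding is applied here).
#' @param problem An `optimization_problem`.
#' @return A tibble with the (rounded) decision values, per-objective raw
#'   predictions and corrected fitness, `cumulative` and `penalty`.
#' @export
evaluate_candidate <- function(x, problem) {
  ev <- problem$eval(matrix(x, nrow = 1L))
  solution_records(ev, problem)
}

# subset / concatenate stored eval() results without re-evaluating
ev_subset <- function(ev, idx) {
  list(X = ev$X[idx, , drop = FALSE], raw = ev$raw[idx, , drop = FALSE],
       corrected = if (is.null(ev$corrected)) NULL else
         ev$corrected[idx, , drop = FALSE],
       cumulative = ev$cumulative[idx], penalty = ev$penalty[idx],
       F = ev$F[idx, , drop = FALSE])
}

ev_rbind <- function(ev1, ev2) {
  list(X = rbind(ev1$X, ev2$X), raw = rbind(ev1$raw, ev2$raw),
       corrected = if (is.null(ev1$corrected)) NULL else
         rbind(ev1$corrected, ev2$corrected),
       cumulative = c(ev1$cumulative, ev2$cumulative),
       penalty = c(ev1$penalty, ev2$penalty), F = rbind(ev1$F, ev2$F))
}

# assemble the solutions tibble from an eval() result
solution_records <- function(ev, problem, generation = NA_integer_) {
  dec <- tibble::as_tibble(as.data.frame(ev$X))
  names(dec) <- problem$vars
  m <- problem$n_obj
  for (k in seq_len(m)) {
    dec[[paste0("pred_", problem$responses[k])]] <- ev$raw[, k]
  }
  if (!is.null(ev$corrected)) {
    for (k in seq_len(m)) {
      dec[[paste0("fitness_", problem$responses[k])]] <- ev$corrected[, k]
    }
  }
  dec$cumulative <- ev$cumulative
  dec$penalty <- ev$penalty
  if (!all(is.na(generation))) dec$generation <- generation
  attr(dec, "decision_vars") <- problem$vars
  dec
}
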