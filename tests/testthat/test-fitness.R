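# a transparent "model" for tests: predicts a fixed linear function
test_that("min-max normalization, direction correction and cumulation follow the stated forms", {
  sp <- objective_spec("y", "maximize", y_min = 0, y_max = 100)
  expect_equal(normalize_fitness(0, sp), 0)
  expect_equal(normalize_fitness(100, sp), 1)
  expect_equal(normalize_fitness(50, sp), 0.5)
  # predictions beyond the observed range are clipped into [0, 1]
  expect_equal(normalize_fitness(130, sp), 1)
  expect_equal(normalize_fitness(-10, sp), 0)
  expect_error(objective_spec("y", "maximize", y_min = 5, y_max = 5),
               "y_max must exceed y_min")

  expect_equal(direction_correct(0.3, "minimize"), 0.7)
  expect_equal(direction_correct(0.3, "maximize"), 0.3)
  expect_equal(direction_correct(direction_correct(0.42, "minimize"),
                                 "minimize"), 0.42)

  expect_equal(cumulative_fitness(c(1, 1, 1, 1)), 4)
  expect_equal(cumulative_fitness(c(0, 0, 0)), 0)
  expect_equal(cumulative_fitness(c(0.5, 0.5)), 1.0)
})

test_that("decision-space bounds come from the data with optional extrapolation", {
  d <- tibble::tibble(a = c(2, 3, 4), b = c(0, 2, 4), g = c(0L, 1L, 2L),
                      y = c(1, 5, 9))
  cl <- classify_variables(d, roles = c(a = "B", b = "B", g = "C", y = "D"))
  s0 <- extract_bounds(d, cl, extrapolation = 0)
  expect_equal(s0$lower[s0$variable == "a"], 2)
  expect_equal(s0$upper[s0$variable == "a"], 4)

  s5 <- extract_bounds(d, cl, extrapolation = 0.5)
  expect_equal(s5$lower[s5$variable == "a"], 1)   # 2 - 0.5 * 2
  expect_equal(s5$upper[s5$variable == "a"], 5)
  # non-negative floor engages for b: 0 - 0.5 * 4 -> 0, flagged
  expect_equal(s5$lower[s5$variable == "b"], 0)
  expect_true(s5$floored[s5$variable == "b"])
  # categorical integer bounds [0, L-1]
  expect_equal(s5$lower[s5$variable == "g"], 0)
  expect_equal(s5$upper[s5$variable == "g"], 2)

  d$const <- 3
  cl2 <- classify_variables(d, roles = c(a = "B", const = "B", y = "D"))
  expect_warning(extract_bounds(d, cl2), "constant predictor")
})

test_that("candidate evaluation rounds categoricals, applies Eqs and consults the cache", {
  space <- tibble::tibble(variable = c("x", "g"),
                          kind = c("continuous", "categorical"),
                          lower = c(0, 0), upper = c(10, 2),
                          n_levels = c(NA, 3L), floored = FALSE)
  class(space) <- c("decision_space", class(space))
  obj <- objective_spec("y", "maximize",
                        model = lookup_model(function(nd) nd$x + 10 * nd$g),
                        y_min = 0, y_max = 30)
  prob <- surrogate_problem(obj, space, cache = TRUE)

  rec <- evaluate_candidate(c(4, 1.4), prob)
  expect_equal(rec$g, 1)                 # 1.4 rounds half-up to level 1
  expect_equal(rec$pred_y, 14)           # model saw the rounded code
  expect_equal(rec$fitness_y, 14 / 30)
  expect_equal(rec$cumulative, 14 / 30)

  rec2 <- evaluate_candidate(c(4, 1.5), prob)   # half-up: 1.5 -> 2
  expect_equal(rec2$g, 2)

  n0 <- prob$counter()
  again <- evaluate_candidate(c(4, 1.4), prob)
  expect_equal(prob$counter(), n0)       # cache hit: counter unchanged
  expect_gte(prob$cache_hits(), 1)
  expect_equal(again$pred_y, rec$pred_y)
})

test_that("sum-bound constraint penalties are weight times violation", {
  space <- tibble::tibble(variable = c("bap", "iba"), kind = "continuous",
                          lower = 0, upper = 10, n_levels = NA_integer_,
                          floored = FALSE)
  class(space) <- c("decision_space", class(space))
  obj <- objective_spec("y", "maximize",
                        model = lookup_model(function(nd) nd$bap),
                        y_min = 0, y_max = 10)
  # total growth regulators <= 5, weight 2
  prob <- surrogate_problem(obj, space,
                            constraints = list(constraint_sum(c("bap", "iba"),
                                                              5, "<=", 2)))
  rec <- evaluate_candidate(c(4, 2), prob)   # sum 6 -> violation 1 -> penalty 2
  expect_equal(rec$penalty, 2.0)
  ok <- evaluate_candidate(c(2, 2), prob)
  expect_equal(ok$penalty, 0)

  single <- surrogate_problem(obj, space,
                              constraints = list(constraint_single("iba", 2,
                                                                   "<=", 1.5)))
  rec2 <- evaluate_candidate(c(1, 3.5), single)
  expect_equal(rec2$penalty, 1.5 * 1.5)
  expect_error(
    surrogate_problem(obj, space,
                      constraints = list(constraint_single("nope", 1)))$eval(
                        matrix(c(1, 1), 1)),
    "unknown variable")
})

test_that("the Eq. 4-6 pipeline maps best-observed rows to n and all-worst rows to 0", {
  withr::with_seed(5, {
    d <- tibble::tibble(x = runif(30, 0, 10))
    d$y1 <- d$x + rnorm(30, 0, 0.1)
    d$y2 <- 10 - d$x + rnorm(30, 0, 0.1)
  })
  o1 <- objective_spec("y1", "maximize", model = lookup_model(function(nd) nd$x),
                       y_min = min(d$y1), y_max = max(d$y1))
  o2 <- objective_spec("y2", "minimize", model = lookup_model(function(nd) nd$x),
                       y_min = min(d$y2), y_max = max(d$y2))
  # best conceivable candidate: maximal y1 prediction, minimal y2 prediction
  corrected_best <- c(direction_correct(normalize_fitness(max(d$y1), o1), "maximize"),
                      direction_correct(normalize_fitness(min(d$y2), o2), "minimize"))
  expect_equal(cumulative_fitness(corrected_best), 2)
  corrected_worst <- c(direction_correct(normalize_fitness(min(d$y1), o1), "maximize"),
                       direction_correct(normalize_fitness(max(d$y2), o2), "minimize"))
  expect_equal(cumulative_fitness(corrected_worst), 0)
})
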