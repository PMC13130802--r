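#' Evolutionary-algorithm configuration
#'
#' Defaults follow the workflow's standard settings: crossover
#' probability 0.7 with simulated binary crossover (SBX) distribution
#' index 15, per-individual mutation probability 0.2 with polynomial
#' mutation index 25 (per-gene rate `1/d` once an individual mutates).
#' SMS-EMOA is steady-state and requires `lambda = 1`.
#'
#' @param algorithm One of `"GA"`, `"PSO"`, `"NSGA2"`, `"SMSEMOA"`.
#' @param mu Population size (>= 2).
#' @param lambda Offspring per generation; defaults to `mu` (forced to 1
#'   for SMS-EMOA).
#' @param generations Number of generations (>= 1).
#' @param p_crossover,p_mutation Crossover / per-individual mutation
#'   probabilities.
#' @param eta_sbx,eta_mutation SBX and polynomial-mutation distribution
#'   indices.
#' @param seed Integer EA seed; a run is exactly reproducible given the
#'   same configuration and seed.
#' @return An `ea_control` list.
#' @export
ea_control <- function(algorithm = c("GA", "PSO", "NSGA2", "SMSEMOA"),
                       mu = 50L, lambda = NULL, generations = 100L,
                       p_crossover = 0.7, p_mutation = 0.2,
                       eta_sbx = 15, eta_mutation = 25, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(lambda)) lambda <- if (algorithm == "SMSEMOA") 1L else mu
  if (algorithm == "SMSEMOA" && lambda != 1L) {
    stop("SMS-EMOA is steady-state: lambda must be 1", call. = FALSE)
  }
  stopifnot(mu >= 2L, generations >= 1L, lambda >= 1L)
  structure(list(algorithm = algorithm, mu = as.integer(mu),
                 lambda = as.integer(lambda),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta_sbx = eta_sbx, eta_mutation = eta_mutation, seed = seed),
            class = "ea_control")
}

# ---- variation operators ----------------------------------------------------

init_population <- function(mu, lower, upper) {
  d <- length(lower)
  matrix(stats::runif(mu * d, rep(lower, each = mu), rep(upper, each = mu)),
         nrow = mu)
}

# simulated binary crossover on one parent pair -> two children
sbx_pair <- function(p1, p2, lower, upper, eta) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(upper, pmax(lower, c1)), pmin(upper, pmax(lower, c2)))
}

# polynomial mutation: with prob p_ind per individual, each gene mutates
# at rate 1/d
poly_mutate <- function(x, lower, upper, eta, p_ind, p_gene = NULL) {
  if (stats::runif(1) > p_ind) return(x)
  d <- length(x)
  if (is.null(p_gene)) p_gene <- 1 / d
  hit <- stats::runif(d) < p_gene
  if (!any(hit)) return(x)
  range <- upper - lower
  u <- stats::runif(sum(hit))
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[hit] <- x[hit] + delta * range[hit]
  pmin(upper, pmax(lower, x))
}

# binary tournament: smaller comparator wins (ties -> random of the two)
tournament_pick <- function(n, comparator) {
  i <- sample.int(n, 1L)
  j <- sample.int(n, 1L)
  better <- comparator(i, j)
  if (is.na(better)) if (stats::runif(1) < 0.5) i else j
  else if (better) i else j
}

# produce `lambda` offspring from population X using `comparator(i, j)`
# (TRUE if i better, NA if tied)
make_offspring <- function(X, lambda, lower, upper, control, comparator) {
  d <- ncol(X)
  n <- nrow(X)
  out <- matrix(NA_real_, lambda, d)
  k <- 0L
  while (k < lambda) {
    i <- tournament_pick(n, comparator)
    j <- tournament_pick(n, comparator)
    p1 <- X[i, ]
    p2 <- X[j, ]
    if (stats::runif(1) < control$p_crossover) {
      ch <- sbx_pair(p1, p2, lower, upper, control$eta_sbx)
    } else {
      ch <- list(p1, p2)
    }
    for (c in ch) {
      if (k >= lambda) break
      k <- k + 1L
      out[k, ] <- poly_mutate(c, lower, upper, control$eta_mutation,
                              control$p_mutation)
    }
  }
  out
}

new_ea_result <- function(problem, control, solutions, best, history) {
  structure(list(algorithm = control$algorithm, solutions = solutions,
                 best = best, history = history,
                 evaluations = problem$counter(),
                 cache_hits = problem$cache_hits(),
                 control = control, problem_kind = problem$kind),
            class = "ea_result")
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("# %s run: %d generation(s), %d evaluation(s), %d cache hit(s)\n",
              x$algorithm, x$control$generations, x$evaluations, x$cache_hits))
  cat(sprintf("  %d solution(s) returned\n", nrow(x$solutions)))
  invisible(x)
}

#' @export
tidy.ea_result <- function(x, ...) x$solutions

#' @export
glance.ea_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, mu = x$control$mu,
                 lambda = x$control$lambda,
                 generations = x$control$generations,
                 evaluations = x$evaluations, cache_hits = x$cache_hits,
                 n_solutions = nrow(x$solutions),
                 best_cumulative = if ("cumulative" %in% names(x$solutions))
                   suppressWarnings(max(x$solutions$cumulative, na.rm = TRUE))
                 else NA_real_)
}

#' Plot optimizer convergence
#'
#' Best (and, for single-objective runs, mean) fitness per generation.
#'
#' @param object An `ea_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_result <- function(object, ...) {
  h <- object$history
  value_cols <- setdiff(names(h), "generation")
  long <- tidyr::pivot_longer(h[, c("generation", value_cols)],
                              cols = dplyr::all_of(value_cols),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("%s convergence", object$algorithm)) +
    ggplot2::theme_minimal()
}

# internal single-objective fitness on the minimization scale:
# direct problems minimize F + penalty; surrogate problems maximize the
# raw prediction (direction-aware), penalty subtracted from the objective
so_internal <- function(ev, problem) {
  if (problem$kind == "direct") {
    ev$F[, 1] + ev$penalty
  } else {
    dir <- problem$objectives[[1]]$direction
    raw <- ev$raw[, 1]
    if (dir == "maximize") -(raw - ev$penalty) else raw + ev$penalty
  }
}

# user-facing fitness scale (higher reported as 'best' for maximize)
so_reported <- function(ev, problem) {
  if (problem$kind == "direct") ev$F[, 1] + ev$penalty
  else {
    dir <- problem$objectives[[1]]$direction
    if (dir == "maximize") ev$raw[, 1] - ev$penalty else ev$raw[, 1] + ev$penalty
  }
}

check_single_objective <- function(problem, algorithm) {
  if (problem$n_obj != 1L) {
    stop(algorithm, " handles exactly one objective; use run_nsga2() or ",
         "run_smsemoa() for multi-objective problems", call. = FALSE)
  }
}

#' Single-objective genetic algorithm
#'
#' Generational GA with binary tournament selection, simulated binary
#' crossover, polynomial mutation and elitism of one: the best individual
#' found so far always survives, so the best fitness trace is monotone.
#' Surrogate predictions serve directly as fitness; penalties are
#' subtracted from the objective.
#'
#' @param problem An `optimization_problem` with one objective.
#' @param control An [ea_control()] with `algorithm = "GA"`.
#' @return An `ea_result`: `best` (one-row solution record), `solutions`
#'   (final population), `history` (best/mean per generation),
#'   `evaluations`, `cache_hits`.
#' @export
run_ga <- function(problem, control = ea_control("GA")) {
  check_single_objective(problem, "GA")
  if (!is.null(control$seed)) set.seed(control$seed)
  problem$reset()
  lower <- problem$lower
  upper <- problem$upper
  X <- init_population(control$mu, lower, upper)
  ev <- problem$eval(X)
  fit <- so_internal(ev, problem)
  history <- vector("list", control$generations)
  best_i <- which.min(fit)
  best <- list(ev = ev_subset(ev, best_i), fit = fit[best_i])
  for (g in seq_len(control$generations)) {
    cmp <- function(i, j) {
      if (fit[i] == fit[j]) return(NA)
      fit[i] < fit[j]
    }
    O <- make_offspring(ev$X, control$lambda, lower, upper, control, cmp)
    evo <- problem$eval(O)
    # elitism of 1: best-so-far individual joins the offspring pool
    # (with lambda < mu the parents survive too, plus-selection style)
    pool <- if (control$lambda >= control$mu) ev_rbind(evo, best$ev)
            else ev_rbind(evo, ev)
    pool_f <- so_internal(pool, problem)
    ord <- order(pool_f)[seq_len(control$mu)]
    ev <- ev_subset(pool, ord)
    fit <- pool_f[ord]
    if (fit[1] < best$fit) {
      best <- list(ev = ev_subset(ev, 1L), fit = fit[1])
    }
    rep_fit <- so_reported(ev, problem)
    history[[g]] <- tibble::tibble(
      generation = g,
      best = if (problem$kind == "direct") min(rep_fit) else max(rep_fit),
      mean = mean(rep_fit))
  }
  best_record <- solution_records(best$ev, problem)
  solutions <- solution_records(ev, problem)
  new_ea_result(problem, control, solutions, best_record,
                dplyr::bind_rows(history))
}

#' Single-objective particle swarm optimization
#'
#' Global-best PSO with constriction-style coefficients
#' (`w = 0.729`, `c1 = c2 = 1.49445`), velocity clamped to half the
#' variable range, and reflecting bounds. Deterministic under the EA
#' seed.
#'
#' @inheritParams run_ga
#' @return An `ea_result`; `history` holds the global-best and swarm-mean
#'   fitness per iteration.
#' @export
run_pso <- function(problem, control = ea_control("PSO")) {
  check_single_objective(problem, "PSO")
  if (!is.null(control$seed)) set.seed(control$seed)
  problem$reset()
  w <- 0.729; c1 <- 1.49445; c2 <- 1.49445
  lower <- problem$lower
  upper <- problem$upper
  d <- length(lower)
  vmax <- 0.5 * (upper - lower)
  X <- init_population(control$mu, lower, upper)
  V <- matrix(0, control$mu, d)
  ev <- problem$eval(X)
  X <- ev$X
  fit <- so_internal(ev, problem)
  pbest_X <- X
  pbest_f <- fit
  pbest_ev <- ev
  g_i <- which.min(fit)
  gbest_x <- X[g_i, ]
  gbest_f <- fit[g_i]
  gbest_ev <- ev_subset(ev, g_i)
  history <- vector("list", control$generations)
  for (g in seq_len(control$generations)) {
    r1 <- matrix(stats::runif(control$mu * d), control$mu)
    r2 <- matrix(stats::runif(control$mu * d), control$mu)
    V <- w * V + c1 * r1 * (pbest_X - X) +
      c2 * r2 * (matrix(gbest_x, control$mu, d, byrow = TRUE) - X)
    V <- pmin(matrix(vmax, control$mu, d, byrow = TRUE),
              pmax(-matrix(vmax, control$mu, d, byrow = TRUE), V))
    X <- X + V
    # reflect at the bounds, reversing the velocity component
    for (j in seq_len(d)) {
      lo <- X[, j] < lower[j]
      hi <- X[, j] > upper[j]
      X[lo, j] <- pmin(upper[j], 2 * lower[j] - X[lo, j])
      X[hi, j] <- pmax(lower[j], 2 * upper[j] - X[hi, j])
      V[lo | hi, j] <- -V[lo | hi, j]
    }
    ev <- problem$eval(X)
    fit <- so_internal(ev, problem)
    rep_f <- so_reported(ev, problem)
    improved <- which(fit < pbest_f)
    pbest_X[improved, ] <- ev$X[improved, , drop = FALSE]
    pbest_f[improved] <- fit[improved]
    for (i in improved) {
      pbest_ev <- within_ev_replace(pbest_ev, i, ev)
    }
    if (min(fit) < gbest_f) {
      g_i <- which.min(fit)
      gbest_x <- ev$X[g_i, ]
      gbest_f <- fit[g_i]
      gbest_ev <- ev_subset(ev, g_i)
    }
    history[[g]] <- tibble::tibble(generation = g,
                                   best = so_reported(gbest_ev, problem),
                                   mean = mean(rep_f))
  }
  best_record <- solution_records(gbest_ev, problem)
  solutions <- solution_records(pbest_ev, problem)
  new_ea_result(problem, control, solutions, best_record,
                dplyr::bind_rows(history))
}

# replace row i of a stored eval record with row i of another
within_ev_replace <- function(target, i, source) {
  target$X[i, ] <- source$X[i, ]
  target$raw[i, ] <- source$raw[i, ]
  if (!is.null(target$corrected)) target$corrected[i, ] <- source$corrected[i, ]
  target$cumulative[i] <- source$cumulative[i]
  target$penalty[i] <- source$penalty[i]
  target$F[i, ] <- source$F[i, ]
  target
}
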