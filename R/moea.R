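# Multi-objective machinery. Internally every objective is minimized
# (surrogate problems expose F = 1 - corrected fitness, so the ideal
# point is the origin); constraint handling uses constrained domination:
# a feasible candidate dominates an infeasible one, and between two
# infeasible candidates the smaller total violation wins.

# n x n logical matrix: D[i, j] = candidate i dominates candidate j
domination_matrix <- function(F, penalty = NULL) {
  n <- nrow(F)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(F))) {
    fk <- F[, k]
    le <- le & outer(fk, fk, "<=")
    lt <- lt | outer(fk, fk, "<")
  }
  D <- le & lt
  if (!is.null(penalty) && any(penalty > 0)) {
    pl <- outer(penalty, penalty, "<")
    pe <- outer(penalty, penalty, "==")
    D <- pl | (pe & D)
  }
  D
}

# fast non-dominated sorting; returns integer rank per row (1 = best)
nds_rank <- function(F, penalty = NULL) {
  D <- domination_matrix(F, penalty)
  n <- nrow(F)
  n_dom <- colSums(D)
  rank <- integer(n)
  r <- 0L
  remaining <- n
  while (remaining > 0L) {
    r <- r + 1L
    front <- which(rank == 0L & n_dom == 0L)
    rank[front] <- r
    remaining <- remaining - length(front)
    if (remaining > 0L) {
      n_dom <- n_dom - colSums(D[front, , drop = FALSE])
      n_dom[rank > 0L] <- Inf
    }
  }
  rank
}

# crowding distance within one front (rows of F); boundary points get Inf
crowding_distance <- function(F) {
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  dist <- rep(0, n)
  for (k in seq_len(ncol(F))) {
    ord <- order(F[, k])
    rng <- F[ord[n], k] - F[ord[1], k]
    dist[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      dist[ord[2:(n - 1L)]] <- dist[ord[2:(n - 1L)]] +
        (F[ord[3:n], k] - F[ord[1:(n - 2L)], k]) / rng
    }
  }
  dist
}

#' Exact hypervolume of a point set
#'
#' Lebesgue measure of the region dominated by `points` (minimization
#' orientation) and bounded by `reference`, computed exactly by the
#' dimension-sweep (slicing) recursion. Points that do not strictly
#' dominate the reference contribute nothing and raise a warning.
#'
#' @param points Numeric matrix, one row per point, columns = objectives.
#' @param reference Reference point, length `ncol(points)`.
#' @return The hypervolume as a single number.
#' @examples
#' hypervolume(rbind(c(0, 0)), c(1, 1))              # 1
#' hypervolume(rbind(c(0, .5), c(.5, 0)), c(1, 1))   # 0.75
#' @export
hypervolume <- function(points, reference) {
  points <- matrix(points, ncol = length(reference))
  ok <- apply(points, 1, function(p) all(p < reference))
  if (!all(ok)) {
    warning(sum(!ok), " point(s) do not dominate the reference; they contribute 0")
    points <- points[ok, , drop = FALSE]
  }
  if (nrow(points) == 0L) return(0)
  hv_recurse(points, reference)
}

hv_recurse <- function(P, ref) {
  m <- ncol(P)
  if (m == 1L) return(max(0, ref - min(P)))
  if (m == 2L) return(hv_2d(P, ref))
  ord <- order(P[, m])
  P <- P[ord, , drop = FALSE]
  z <- c(P[, m], ref[m])
  total <- 0
  for (i in seq_len(nrow(P))) {
    depth <- z[i + 1L] - z[i]
    if (depth > 0) {
      total <- total + depth * hv_recurse(P[seq_len(i), -m, drop = FALSE],
                                          ref[-m])
    }
  }
  total
}

# 2-d sweep: sort by f1 ascending, accumulate staircase area
hv_2d <- function(P, ref) {
  P <- P[order(P[, 1], P[, 2]), , drop = FALSE]
  total <- 0
  best2 <- ref[2]
  x <- c(P[, 1], ref[1])
  for (i in seq_len(nrow(P))) {
    if (P[i, 2] < best2) {
      total <- total + (ref[1] - P[i, 1]) * (best2 - P[i, 2])
      best2 <- P[i, 2]
    }
  }
  total
}

# exclusive hypervolume contribution of each row (points beyond the
# reference or duplicated get 0)
hv_contributions <- function(P, ref) {
  n <- nrow(P)
  if (n == 1L) return(hypervolume_safe(P, ref))
  # the fast staircase formula assumes a mutually non-dominated set
  if (ncol(P) == 2L && !any(domination_matrix(P)) && !anyDuplicated(P)) {
    return(hv_contributions_2d(P, ref))
  }
  total <- hypervolume_safe(P, ref)
  vapply(seq_len(n), function(i) {
    total - hypervolume_safe(P[-i, , drop = FALSE], ref)
  }, numeric(1))
}

hypervolume_safe <- function(P, ref) {
  ok <- apply(P, 1, function(p) all(p < ref))
  P <- P[ok, , drop = FALSE]
  if (nrow(P) == 0L) return(0)
  hv_recurse(P, ref)
}

hv_contributions_2d <- function(P, ref) {
  n <- nrow(P)
  contrib <- rep(0, n)
  ok <- P[, 1] < ref[1] & P[, 2] < ref[2]
  idx <- which(ok)
  if (length(idx) == 0L) return(contrib)
  Q <- P[idx, , drop = FALSE]
  ord <- order(Q[, 1], Q[, 2])
  Q <- Q[ord, , drop = FALSE]
  # walk the staircase: only points strictly improving f2 are on the front
  front <- logical(nrow(Q))
  best2 <- Inf
  for (i in seq_len(nrow(Q))) {
    if (Q[i, 2] < best2) {
      front[i] <- TRUE
      best2 <- Q[i, 2]
    }
  }
  fidx <- which(front)
  f1 <- Q[fidx, 1]
  f2 <- Q[fidx, 2]
  right <- c(f1[-1], ref[1])
  above <- c(ref[2], f2[-length(f2)])
  contrib[idx[ord[fidx]]] <- (right - f1) * (above - f2)
  contrib
}

moea_history_row <- function(g, ev, problem) {
  row <- tibble::tibble(generation = g)
  if (problem$kind == "surrogate") {
    row$best_cumulative <- max(ev$cumulative - ev$penalty)
    for (k in seq_len(problem$n_obj)) {
      row[[paste0("best_", problem$responses[k])]] <- max(ev$corrected[, k])
    }
  } else {
    for (k in seq_len(problem$n_obj)) {
      row[[paste0("best_", problem$responses[k])]] <- min(ev$F[, k])
    }
  }
  row
}

check_multi_objective <- function(problem, algorithm) {
  if (problem$n_obj < 2L) {
    stop(algorithm, " requires >= 2 objectives; use run_ga() or run_pso() ",
         "for single-objective problems", call. = FALSE)
  }
}

#' NSGA-II multi-objective optimization
#'
#' Elitist genetic algorithm using fast non-dominated sorting and
#' crowding-distance truncation: each generation `lambda` offspring are
#' produced by binary tournament on (rank, crowding), SBX and polynomial
#' mutation; parents and offspring are merged and the best `mu` survive.
#' Total surrogate evaluations equal `mu + lambda * generations` when the
#' prediction cache is disabled. Returns the final non-dominated set.
#'
#' @param problem An `optimization_problem` with at least two objectives.
#' @param control An [ea_control()] with `algorithm = "NSGA2"`.
#' @return An `ea_result` whose `solutions` are the final Pareto set and
#'   whose `history` tracks the per-generation best cumulative fitness
#'   and per-objective bests.
#' @export
run_nsga2 <- function(problem, control = ea_control("NSGA2")) {
  check_multi_objective(problem, "NSGA-II")
  if (!is.null(control$seed)) set.seed(control$seed)
  problem$reset()
  lower <- problem$lower
  upper <- problem$upper
  ev <- problem$eval(init_population(control$mu, lower, upper))
  rank <- nds_rank(ev$F, ev$penalty)
  crowd <- rep(0, control$mu)
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(ev$F[idx, , drop = FALSE])
  }
  history <- vector("list", control$generations)
  for (g in seq_len(control$generations)) {
    cmp <- function(i, j) {
      if (rank[i] != rank[j]) return(rank[i] < rank[j])
      if (crowd[i] == crowd[j]) return(NA)
      crowd[i] > crowd[j]
    }
    O <- make_offspring(ev$X, control$lambda, lower, upper, control, cmp)
    evo <- problem$eval(O)
    pool <- ev_rbind(ev, evo)
    pr <- nds_rank(pool$F, pool$penalty)
    sel <- integer(0)
    r <- 1L
    crowd_sel <- numeric(0)
    while (length(sel) < control$mu) {
      front <- which(pr == r)
      cd <- crowding_distance(pool$F[front, , drop = FALSE])
      if (length(sel) + length(front) <= control$mu) {
        sel <- c(sel, front)
        crowd_sel <- c(crowd_sel, cd)
      } else {
        need <- control$mu - length(sel)
        keep <- order(cd, decreasing = TRUE)[seq_len(need)]
        sel <- c(sel, front[keep])
        crowd_sel <- c(crowd_sel, cd[keep])
      }
      r <- r + 1L
    }
    ev <- ev_subset(pool, sel)
    rank <- pr[sel]
    crowd <- crowd_sel
    history[[g]] <- moea_history_row(g, ev, problem)
  }
  pareto <- ev_subset(ev, which(rank == 1L))
  solutions <- solution_records(pareto, problem)
  new_ea_result(problem, control, solutions, best = NULL,
                dplyr::bind_rows(history))
}

#' SMS-EMOA multi-objective optimization
#'
#' Steady-state hypervolume-based algorithm: each generation one
#' offspring is created, the merged population is non-dominated sorted
#' and the member of the worst front with the smallest exclusive
#' hypervolume contribution is discarded. For surrogate problems the
#' reference point sits 10% beyond the worst corrected fitness in every
#' objective (1.1 per dimension on the internal minimization scale); for
#' direct problems it is re-derived each generation as the population
#' maximum plus a 10% range buffer, unless `ref_point` is supplied.
#'
#' @inheritParams run_nsga2
#' @param ref_point Optional fixed hypervolume reference point on the
#'   internal minimization scale.
#' @return An `ea_result`; `solutions` are the final non-dominated set.
#' @export
run_smsemoa <- function(problem, control = ea_control("SMSEMOA"),
                        ref_point = NULL) {
  check_multi_objective(problem, "SMS-EMOA")
  if (control$lambda != 1L) stop("SMS-EMOA requires lambda = 1", call. = FALSE)
  if (problem$n_obj > 4L) {
    warning("exact hypervolume with more than 4 objectives is expensive; proceeding")
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  problem$reset()
  lower <- problem$lower
  upper <- problem$upper
  ev <- problem$eval(init_population(control$mu, lower, upper))
  fixed_ref <- if (!is.null(ref_point)) {
    ref_point
  } else if (problem$kind == "surrogate") {
    rep(1.1, problem$n_obj)   # worst corrected fitness 1, plus 10% buffer
  } else NULL
  rank <- nds_rank(ev$F, ev$penalty)
  history <- vector("list", control$generations)
  for (g in seq_len(control$generations)) {
    cmp <- function(i, j) {
      if (rank[i] == rank[j]) return(NA)
      rank[i] < rank[j]
    }
    O <- make_offspring(ev$X, 1L, lower, upper, control, cmp)
    evo <- problem$eval(O)
    pool <- ev_rbind(ev, evo)
    pr <- nds_rank(pool$F, pool$penalty)
    worst <- which(pr == max(pr))
    if (length(worst) == 1L) {
      drop_i <- worst
    } else {
      ref <- if (!is.null(fixed_ref)) fixed_ref else {
        apply(pool$F, 2, max) + 0.1 * pmax(apply(pool$F, 2, max) -
                                             apply(pool$F, 2, min), 1e-12)
      }
      contrib <- hv_contributions(pool$F[worst, , drop = FALSE], ref)
      drop_i <- worst[which.min(contrib)]
    }
    keep <- setdiff(seq_len(control$mu + 1L), drop_i)
    ev <- ev_subset(pool, keep)
    rank <- pr[keep]
    rank <- match(rank, sort(unique(rank)))   # re-compact front indices
    history[[g]] <- moea_history_row(g, ev, problem)
  }
  pareto <- ev_subset(ev, which(rank == 1L))
  solutions <- solution_records(pareto, problem)
  new_ea_result(problem, control, solutions, best = NULL,
                dplyr::bind_rows(history))
}

#' Plot a 2-objective Pareto front
#'
#' @param result An `ea_result` from [run_nsga2()] or [run_smsemoa()].
#' @param objectives Which two response names to plot; defaults to the
#'   first two prediction columns.
#' @return A ggplot object.
#' @export
plot_pareto <- function(result, objectives = NULL) {
  sol <- result$solutions
  pred_cols <- grep("^pred_", names(sol), value = TRUE)
  if (is.null(objectives)) objectives <- pred_cols[1:2]
  else objectives <- paste0("pred_", objectives)
  ggplot2::ggplot(sol, ggplot2::aes(.data[[objectives[1]]],
                                    .data[[objectives[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = if ("cumulative" %in% names(sol))
      .data$cumulative else NULL)) +
    ggplot2::labs(colour = "cumulative", title = "Non-dominated solutions") +
    ggplot2::theme_minimal()
}
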