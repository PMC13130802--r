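#' Distance-based solution filtering
#'
#' Reduces a solution set to `k` diverse representatives by greedy
#' farthest-point (max-min) selection in the min-max-scaled decision
#' space, seeded at the solution with the best cumulative fitness.
#' Duplicated decision vectors collapse onto one representative.
#'
#' @param solutions Solutions tibble from an `ea_result` (or any data
#'   frame carrying the decision variables and a `cumulative` column).
#' @param k Number of representatives to keep; `k >= nrow(solutions)`
#'   returns the input unchanged.
#' @param vars Decision-variable columns; defaults to the
#'   `"decision_vars"` attribute set by the optimizers.
#' @return The filtered tibble.
#' @export
filter_solutions <- function(solutions, k, vars = NULL) {
  stopifnot(nrow(solutions) >= 1L, k >= 1L)
  if (is.null(vars)) vars <- attr(solutions, "decision_vars")
  if (is.null(vars)) stop("decision variables unknown; pass `vars`", call. = FALSE)
  n <- nrow(solutions)
  if (k >= n) return(solutions)
  X <- as.matrix(solutions[, vars, drop = FALSE])
  # min-max scale each decision axis
  for (j in seq_len(ncol(X))) {
    r <- range(X[, j])
    X[, j] <- if (r[2] > r[1]) (X[, j] - r[1]) / (r[2] - r[1]) else 0
  }
  start <- if ("cumulative" %in% names(solutions) &&
               !all(is.na(solutions$cumulative))) {
    which.max(solutions$cumulative - if ("penalty" %in% names(solutions))
      solutions$penalty else 0)
  } else 1L
  sel <- start
  d2min <- colSums((t(X) - X[start, ])^2)
  while (length(sel) < k) {
    cand <- which.max(d2min)
    if (d2min[cand] <= 0) break    # only duplicates left
    sel <- c(sel, cand)
    d2min <- pmin(d2min, colSums((t(X) - X[cand, ])^2))
  }
  solutions[sort(sel), , drop = FALSE]
}

#' Sequential objective-priority filtering
#'
#' Steps through objectives in the given priority order, at each step
#' retaining the top `keep_fraction` of the remaining solutions by that
#' objective (ties at the cutoff are kept). Use it to shortlist
#' multi-objective solutions response by response.
#'
#' @param solutions Solutions tibble.
#' @param priorities Character vector of column names to filter by, in
#'   order (e.g. `c("pred_PR", "pred_SN")`).
#' @param keep_fraction Fraction retained at each step, in (0, 1].
#' @param directions Optional named vector, `"maximize"` (default) or
#'   `"minimize"` per priority column.
#' @return The filtered tibble.
#' @export
sequential_filter <- function(solutions, priorities, keep_fraction = 0.5,
                              directions = NULL) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  out <- solutions
  for (p in priorities) {
    if (!p %in% names(out)) stop("unknown priority column: ", p, call. = FALSE)
    v <- out[[p]]
    dir <- if (!is.null(directions) && p %in% names(directions))
      directions[[p]] else "maximize"
    if (dir == "minimize") v <- -v
    n_keep <- max(1L, ceiling(keep_fraction * nrow(out)))
    cutoff <- sort(v, decreasing = TRUE)[n_keep]
    out <- out[v >= cutoff, , drop = FALSE]   # ties kept
  }
  out
}
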