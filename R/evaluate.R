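#' Compare original data against optimized solutions
#'
#' Scores the original experimental rows on their observed responses and
#' the optimized solutions on their surrogate predictions, using the
#' identical objective specs (same observed extremes and directions) that
#' drove the optimization. Both groups receive the cumulative normalized
#' fitness in `[0, n]`; higher is better. The two score sources are
#' labelled explicitly so measurements are never conflated with
#' predictions.
#'
#' @param original The original (uploaded) experimental data frame.
#' @param solutions Solutions tibble from an `ea_result` (with `pred_*`
#'   columns), or any data frame holding one column per response.
#' @param objectives List of [objective_spec()]s.
#' @return An `evaluation_report`: `per_objective` summary tibble,
#'   `scores` (per-row cumulative fitness for both groups) and
#'   `improvement` deltas.
#' @export
compare_solutions <- function(original, solutions, objectives) {
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  specs <- purrr::keep(objectives, function(ob) {
    ok <- ob$response %in% names(original)
    if (!ok) warning("response '", ob$response,
                     "' missing from the original data; excluded")
    ok
  })
  if (length(specs) == 0L) stop("no comparable objectives", call. = FALSE)
  n_obj <- length(specs)

  value_of <- function(df, resp) {
    if (resp %in% names(df)) df[[resp]]
    else if (paste0("pred_", resp) %in% names(df)) df[[paste0("pred_", resp)]]
    else stop("solutions lack a column for response '", resp, "'", call. = FALSE)
  }

  corrected <- function(df) {
    vapply(specs, function(ob) {
      direction_correct(normalize_fitness(value_of(df, ob$response), ob),
                        ob$direction)
    }, numeric(nrow(df)))
  }
  co <- matrix(corrected(original), nrow = nrow(original))
  cs <- matrix(corrected(solutions), nrow = nrow(solutions))

  per_objective <- purrr::map_dfr(seq_len(n_obj), function(k) {
    ob <- specs[[k]]
    ov <- value_of(original, ob$response)
    sv <- value_of(solutions, ob$response)
    best <- if (ob$direction == "maximize") max else min
    tibble::tibble(
      response = ob$response, direction = ob$direction,
      original_mean = mean(ov), original_best = best(ov),
      original_sd = stats::sd(ov),
      optimized_mean = mean(sv), optimized_best = best(sv),
      mean_delta = mean(sv) - mean(ov), best_delta = best(sv) - best(ov)
    )
  })

  scores <- dplyr::bind_rows(
    tibble::tibble(group = "original (observed)",
                   cumulative = rowSums(co)),
    tibble::tibble(group = "optimized (predicted)",
                   cumulative = rowSums(cs))
  )
  structure(
    list(per_objective = per_objective, scores = scores,
         n_objectives = n_obj,
         improvement = tibble::tibble(
           mean_cumulative_original = mean(rowSums(co)),
           mean_cumulative_optimized = mean(rowSums(cs)),
           best_cumulative_original = max(rowSums(co)),
           best_cumulative_optimized = max(rowSums(cs))
         )),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("# Original vs optimized, %d objective(s); cumulative fitness in [0, %d]\n",
              x$n_objectives, x$n_objectives))
  print(x$per_objective)
  print(x$improvement)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_objective

#' @export
glance.evaluation_report <- function(x, ...) x$improvement

#' Violin plot of original vs optimized objective values
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object showing the cumulative-fitness distribution of
#'   the original rows against the optimized solutions.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$group, .data$cumulative,
                               fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = NULL, y = "cumulative normalized fitness") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
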