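#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

new_design_table <- function(df, design_type, factors, coded = NULL) {
  out <- as_tibble(df)
  attr(out, "design_type") <- design_type
  attr(out, "factors") <- factors
  attr(out, "coded") <- if (!is.null(coded)) as_tibble(coded) else NULL
  class(out) <- c("design_table", class(out))
  out
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("# Design table: %s, %d runs, %d factors\n",
              attr(x, "design_type"), nrow(x), length(attr(x, "factors"))))
  NextMethod()
}

#' Coded coordinates of a design table
#'
#' Returns the coded-unit companion table (`cube = ±1`, `center = 0`,
#' `axial = ±alpha`) recorded when the design was generated, or `NULL` for
#' grid designs that have no coded representation.
#'
#' @param design A `design_table`.
#' @return A tibble of coded coordinates, or `NULL`.
#' @export
design_coded <- function(design) attr(design, "coded")

#' @rdname design_coded
#' @export
design_factors <- function(design) attr(design, "factors")

rep_rows <- function(df, replicates) {
  if (replicates == 1L) {
    df$replicate <- 1L
    return(df)
  }
  idx <- rep(seq_len(nrow(df)), each = replicates)
  out <- df[idx, , drop = FALSE]
  out$replicate <- rep(seq_len(replicates), times = nrow(df))
  rownames(out) <- NULL
  out
}

# lexicographic full grid: first factor varies slowest
full_grid <- function(factors) {
  lvls <- lapply(factors, `[[`, "levels")
  g <- rev(expand.grid(rev(lvls), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  names(g) <- names(factors)
  g
}

#' Full factorial design
#'
#' Enumerates every combination of the declared factor levels, repeated
#' `replicates` times, in deterministic lexicographic order over the factor
#' order. Three factors at five levels each therefore produce
#' \eqn{5^3 = 125} unique formulations, or 375 experimental units with
#' three replicates.
#'
#' @param factors A `factor_spec` list; every factor (including continuous
#'   ones) must carry an explicit `levels` vector.
#' @param replicates Number of replicates per combination.
#' @return A `design_table` tibble with one row per run, the factor columns
#'   in actual units plus `role` and `replicate`.
#' @examples
#' f <- lapply(c("A", "B"), function(n) factor_spec(n, levels = c(0, 1, 2)))
#' design_ffd(f, replicates = 2)
#' @export
design_ffd <- function(factors, replicates = 1L) {
  factors <- as_factor_specs(factors)
  require_levels(factors, "full factorial")
  stopifnot(replicates >= 1L)
  g <- full_grid(factors)
  g$role <- "corner"
  g <- rep_rows(g, as.integer(replicates))
  new_design_table(g, "FFD", factors)
}

#' Central composite design
#'
#' Builds the rotatable-style CCD of \eqn{2^k} cube points (coded ±1),
#' \eqn{2k} axial points (coded ±alpha on one axis) and
#' \eqn{n_0 = \max(4, 2k)} center points. The default axial distance
#' `alpha = 0.8` keeps every decoded setting inside the declared
#' `[min, max]` range, so no run asks for a physically impossible (e.g.
#' negative) concentration. Coded coordinates are converted to actual
#' units by `actual = midpoint + coded * half-range`.
#'
#' @param factors Continuous `factor_spec` list, `k >= 2`.
#' @param alpha Axial distance in coded units (default 0.8).
#' @param n_center Number of center points; `NULL` applies
#'   \eqn{\max(4, 2k)}.
#' @param replicates Replicates per generated point.
#' @return A `design_table`; the coded companion is available via
#'   [design_coded()].
#' @export
design_ccd <- function(factors, alpha = 0.8, n_center = NULL, replicates = 1L) {
  factors <- as_factor_specs(factors)
  require_continuous(factors, "central composite")
  k <- length(factors)
  if (k < 2L) stop("central composite design requires >= 2 factors", call. = FALSE)
  stopifnot(alpha > 0)
  if (is.null(n_center)) n_center <- max(4L, 2L * k)

  cube <- as.matrix(rev(expand.grid(rev(rep(list(c(-1, 1)), k)))))
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(cube, axial, center)
  colnames(coded) <- names(factors)
  role <- c(rep("cube", nrow(cube)), rep("axial", nrow(axial)),
            rep("center", n_center))

  actual <- coded
  for (i in seq_len(k)) actual[, i] <- coded_to_actual(coded[, i], factors[[i]])
  df <- as.data.frame(actual)
  df$role <- role
  df <- rep_rows(df, as.integer(replicates))
  coded_df <- as.data.frame(coded)[rep(seq_len(nrow(coded)),
                                       each = as.integer(replicates)), ,
                                   drop = FALSE]
  new_design_table(df, "CCD", factors, coded = coded_df)
}

#' Box-Behnken design
#'
#' Three-level response-surface design placing, for every unordered factor
#' pair, four runs at coded (±1, ±1) with all remaining factors at their
#' center, plus center points. No run sets more than two factors to an
#' extreme, so the full corners of the cube — often non-viable culture
#' conditions — are never requested. Requires at least three factors.
#'
#' @inheritParams design_ccd
#' @return A `design_table` with `4 * choose(k, 2) + n_center` runs (before
#'   replication).
#' @export
design_bbd <- function(factors, n_center = NULL, replicates = 1L) {
  factors <- as_factor_specs(factors)
  require_continuous(factors, "Box-Behnken")
  k <- length(factors)
  if (k < 3L) stop("Box-Behnken design requires >= 3 factors", call. = FALSE)
  if (is.null(n_center)) n_center <- max(4L, 2L * k)

  pairs <- utils::combn(k, 2L)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  coded <- matrix(0, 4L * ncol(pairs) + n_center, k)
  r <- 1L
  for (p in seq_len(ncol(pairs))) {
    for (q in 1:4) {
      coded[r, pairs[1L, p]] <- pm[q, 1L]
      coded[r, pairs[2L, p]] <- pm[q, 2L]
      r <- r + 1L
    }
  }
  colnames(coded) <- names(factors)
  role <- c(rep("cube", 4L * ncol(pairs)), rep("center", n_center))

  actual <- coded
  for (i in seq_len(k)) actual[, i] <- coded_to_actual(coded[, i], factors[[i]])
  df <- as.data.frame(actual)
  df$role <- role
  df <- rep_rows(df, as.integer(replicates))
  coded_df <- as.data.frame(coded)[rep(seq_len(nrow(coded)),
                                       each = as.integer(replicates)), ,
                                   drop = FALSE]
  new_design_table(df, "BBD", factors, coded = coded_df)
}

#' Latin hypercube sample
#'
#' Space-filling design: each factor's `[min, max]` range is divided into
#' `n_runs` equal-width intervals and exactly one run falls in each
#' interval, with the interval-to-run assignment permuted independently
#' per factor. With uniform ranges equal width equals equal probability.
#'
#' @param factors Continuous `factor_spec` list.
#' @param n_runs Number of runs (and intervals per factor).
#' @param seed Integer seed; the same seed reproduces the identical table.
#' @return A `design_table` of `n_runs` rows with role `"sample"`.
#' @export
design_lhs <- function(factors, n_runs, seed = NULL) {
  factors <- as_factor_specs(factors)
  require_continuous(factors, "Latin hypercube")
  stopifnot(n_runs >= 1L)
  n <- as.integer(n_runs)
  u <- with_seed(seed, {
    vapply(seq_along(factors), function(i) {
      (sample.int(n) - 1L + stats::runif(n)) / n
    }, numeric(n))
  })
  u <- matrix(u, nrow = n)
  actual <- vapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    f$min + u[, i] * (f$max - f$min)
  }, numeric(n))
  df <- as.data.frame(matrix(actual, nrow = n))
  names(df) <- names(factors)
  df$role <- "sample"
  df$replicate <- 1L
  new_design_table(df, "LHS", factors)
}

# middle level, lower-middle when the level count is even
middle_level <- function(levels) levels[[ceiling((length(levels) + 1L) / 2L) -
                                           (length(levels) %% 2L == 0L)]]

#' Random design over a factor grid
#'
#' For small design spaces (grid size \eqn{G \le 50}) this falls back to
#' the full factorial layout. Larger grids are subsampled to
#' `n = clamp(round(0.30 G), 20, 100)` runs drawn without replacement,
#' after which the \eqn{2^k} corner combinations (every factor at an
#' extreme level) are forced into the sample when \eqn{2^k \le n/2}, plus
#' one center combination (middle level per factor, lower-middle for even
#' level counts) to allow curvature detection.
#'
#' @param factors `factor_spec` list; every factor needs explicit levels.
#' @param replicates Replicates applied after grid construction.
#' @param seed Integer seed for the subsample.
#' @return A `design_table` with roles `corner`, `center` and `sample`.
#' @export
design_random <- function(factors, replicates = 1L, seed = NULL) {
  factors <- as_factor_specs(factors)
  require_levels(factors, "random design")
  g <- full_grid(factors)
  G <- nrow(g)
  k <- length(factors)

  lvl_key <- function(df) do.call(paste, c(df[names(factors)], sep = "\r"))
  corner_grid <- full_grid(lapply(factors, function(f) {
    f$levels <- f$levels[c(1L, length(f$levels))]
    f
  }))
  center_row <- as.data.frame(lapply(factors, function(f) middle_level(f$levels)))
  names(center_row) <- names(factors)

  if (G <= 50L) {
    g$role <- "sample"
    g$role[lvl_key(g) %in% lvl_key(corner_grid)] <- "corner"
    g$role[lvl_key(g) == lvl_key(center_row)] <- "center"
    g <- rep_rows(g, as.integer(replicates))
    return(new_design_table(g, "RD", factors))
  }

  n <- min(100L, max(20L, as.integer(round(0.30 * G))))
  idx <- with_seed(seed, sample.int(G, n))
  key_all <- lvl_key(g)
  forced_keys <- character(0)
  if (2^k <= n / 2) forced_keys <- lvl_key(corner_grid)
  forced_keys <- c(forced_keys, lvl_key(center_row))
  forced_idx <- match(forced_keys, key_all)
  forced_idx <- forced_idx[!is.na(forced_idx)]
  missing <- setdiff(forced_idx, idx)
  if (length(missing) > 0L) {
    replaceable <- which(!(idx %in% forced_idx))
    swap <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                      sample(replaceable, length(missing)))
    idx[swap] <- missing
  }
  sel <- g[sort(idx), , drop = FALSE]
  sel$role <- "sample"
  sel$role[lvl_key(sel) %in% lvl_key(corner_grid)] <- "corner"
  sel$role[lvl_key(sel) == lvl_key(center_row)] <- "center"
  sel <- rep_rows(sel, as.integer(replicates))
  new_design_table(sel, "RD", factors)
}

#' Cap excessive replication
#'
#' Laboratory sheets sometimes accumulate more replicates per treatment
#' than the analysis needs. For every unique factor-level combination the
#' first `max_replicates` rows (in input order) are retained and the rest
#' dropped; the removed rows are attached as the `"cleanup_report"`
#' attribute.
#'
#' @param design A `design_table` or plain data frame of runs.
#' @param max_replicates Per-treatment cap (default 5).
#' @return The trimmed table, with attribute `cleanup_report` holding a
#'   list `(removed = <tibble>, n_removed = <int>)`.
#' @export
cleanup_replicates <- function(design, max_replicates = 5L) {
  if (max_replicates < 1L) stop("max_replicates must be >= 1", call. = FALSE)
  stopifnot(nrow(design) >= 1L)
  fac_cols <- if (!is.null(attr(design, "factors"))) {
    names(attr(design, "factors"))
  } else {
    setdiff(names(design), c("role", "replicate"))
  }
  key <- do.call(paste, c(design[fac_cols], sep = "\r"))
  within_count <- stats::ave(seq_along(key), key, FUN = seq_along)
  keep <- within_count <= max_replicates
  removed <- design[!keep, , drop = FALSE]
  out <- design[keep, , drop = FALSE]
  if (!is.null(attr(design, "coded"))) {
    attr(out, "coded") <- attr(design, "coded")[keep, , drop = FALSE]
  }
  attr(out, "cleanup_report") <- list(removed = as_tibble(removed),
                                      n_removed = sum(!keep))
  out
}

#' Write a design table to CSV
#'
#' One row per run, factor columns in actual units plus `role` and
#' `replicate`; optionally a companion CSV in coded units.
#'
#' @param design A `design_table`.
#' @param path Output CSV path.
#' @param coded_path Optional path for the coded companion table.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, coded_path = NULL) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  if (!is.null(coded_path) && !is.null(design_coded(design))) {
    utils::write.csv(as.data.frame(design_coded(design)), coded_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Plot a design table
#'
#' Scatter-matrix style view of the first two factors (or the pair given),
#' coloured by point role — a quick visual check that cube, axial and
#' center points sit where the design intends.
#'
#' @param object A `design_table`.
#' @param x,y Factor names to plot; defaults to the first two.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_table <- function(object, x = NULL, y = NULL, ...) {
  fns <- names(attr(object, "factors"))
  if (is.null(x)) x <- fns[1L]
  if (is.null(y)) y <- fns[min(2L, length(fns))]
  ggplot2::ggplot(object, ggplot2::aes(.data[[x]], .data[[y]],
                                       colour = .data$role)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(title = sprintf("%s design (%d runs)",
                                  attr(object, "design_type"), nrow(object))) +
    ggplot2::theme_minimal()
}
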