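#' Classify dataset columns into the four workflow roles
#'
#' Every column of an experimental table plays one of four roles:
#' * **A** — descriptor / metadata (run, block, replicate, treatment ids);
#'   excluded from model training but kept for traceability,
#' * **B** — quantitative predictor (concentrations, environment settings),
#' * **C** — categorical predictor (genotype, basal medium, ...; 2--20
#'   discrete levels),
#' * **D** — measured response to predict and optimize.
#'
#' Heuristics: unique-per-row identifier columns, or names matching
#' id/run/block/replicate/treatment patterns, become A; non-numeric columns
#' and numeric columns with 2--20 distinct values that look like discrete
#' dose steps become C; remaining numeric columns become B. Responses are
#' never auto-assigned — the auto-detection of "high-variability" outputs
#' is advisory only, so D roles must come through `roles`. User-supplied
#' roles always win over the heuristics.
#'
#' @param data A data frame.
#' @param roles Named character vector of overrides, e.g.
#'   `c(PR = "D", genotype = "C")`. Values in `A`, `B`, `C`, `D`.
#' @param categorical_max Upper bound of the distinct-level window used to
#'   flag discrete columns as categorical (default 20).
#' @return A tibble of class `variable_roles` with columns `column`,
#'   `role`, `provenance` (`auto`/`user`) and `n_levels`.
#' @examples
#' d <- data.frame(run = 1:6, BAP = c(0, 1, 2, 0, 1, 2),
#'                 basal = rep(c("MS", "DKW", "GNH"), 2),
#'                 PR = runif(6, 40, 100))
#' classify_variables(d, roles = c(PR = "D", BAP = "B"))
#' @export
classify_variables <- function(data, roles = NULL, categorical_max = 20L) {
  stopifnot(nrow(data) > 0L, ncol(data) > 0L)
  if (anyDuplicated(names(data))) stop("column names must be unique", call. = FALSE)
  id_pattern <- "(^|[._ ])(id|run|block|rep|replicate|treatment|sample|obs)([._ ]|$|s$)"
  out <- purrr::map_dfr(names(data), function(col) {
    x <- data[[col]]
    nu <- dplyr::n_distinct(x[!is.na(x)])
    role <- if (grepl(id_pattern, tolower(col)) ||
                (nu == nrow(data) && (is.character(x) || is.integer(x) ||
                                        (is.numeric(x) && all(x == round(x), na.rm = TRUE))))) {
      "A"
    } else if (!is.numeric(x)) {
      if (nu >= 2L && nu <= categorical_max) "C" else "A"
    } else if (nu >= 2L && nu <= categorical_max) {
      # numeric but only a few distinct values: discrete dose steps / codes
      "C"
    } else {
      "B"
    }
    tibble::tibble(column = col, role = role, provenance = "auto", n_levels = nu)
  })
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), names(data))
    if (length(bad)) stop("role overrides for unknown column(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!all(roles %in% c("A", "B", "C", "D"))) {
      stop("roles must be one of A, B, C, D", call. = FALSE)
    }
    hit <- match(names(roles), out$column)
    out$role[hit] <- unname(roles)
    out$provenance[hit] <- "user"
  }
  class(out) <- c("variable_roles", class(out))
  validate_roles(out)
  out
}

validate_roles <- function(classification) {
  miss <- character(0)
  if (!any(classification$role %in% c("B", "C"))) miss <- c(miss, ">=1 predictor (B or C)")
  if (!any(classification$role == "D")) miss <- c(miss, ">=1 response (D)")
  if (length(miss)) {
    stop("minimum design requirements not met: ", paste(miss, collapse = "; "),
         call. = FALSE)
  }
  invisible(classification)
}

roles_of <- function(classification, role) {
  classification$column[classification$role %in% role]
}

#' Integer-encode categorical predictors
#'
#' Each Type-C column is replaced by consecutive integers `0..L-1`
#' assigned in first-appearance order (e.g. `{"Genotype A", "Genotype B",
#' "Genotype C"} -> {0, 1, 2}`), so that the optimizer can treat the
#' column as a rounded integer axis. The per-column map is returned for
#' decoding optimized solutions back to labels.
#'
#' @param data A data frame.
#' @param classification A `variable_roles` table from
#'   [classify_variables()].
#' @return A list with `data` (encoded tibble) and `map` (an
#'   `encoding_map`: named list of level vectors, index `i` of each vector
#'   holding the label for code `i - 1`).
#' @export
encode_categoricals <- function(data, classification) {
  ccols <- roles_of(classification, "C")
  map <- list()
  out <- tibble::as_tibble(data)
  for (col in ccols) {
    x <- out[[col]]
    lv <- unique(x[!is.na(x)])
    map[[col]] <- lv
    out[[col]] <- match(x, lv) - 1L
  }
  class(map) <- "encoding_map"
  list(data = out, map = map)
}

#' Decode integer codes back to categorical labels
#'
#' @param data A data frame holding integer-coded Type-C columns.
#' @param map The `encoding_map` returned by [encode_categoricals()].
#' @return The decoded tibble.
#' @export
decode_categoricals <- function(data, map) {
  out <- tibble::as_tibble(data)
  for (col in intersect(names(map), names(out))) {
    codes <- out[[col]]
    if (any(!is.na(codes) & (codes < 0 | codes > length(map[[col]]) - 1L))) {
      stop("unseen code in column '", col, "' during decoding", call. = FALSE)
    }
    out[[col]] <- map[[col]][codes + 1L]
  }
  out
}

#' Complete-case deletion
#'
#' Any row containing a missing value — in any column, descriptors
#' included — is removed before model training. The indices and count of
#' the removed rows are attached as the `"dropped"` attribute.
#'
#' @param data A data frame.
#' @return The complete-case tibble with attribute
#'   `dropped = list(indices, n)`.
#' @export
drop_incomplete_rows <- function(data) {
  cc <- stats::complete.cases(data)
  if (!any(cc)) stop("all rows contain missing values; nothing left to analyse",
                     call. = FALSE)
  out <- tibble::as_tibble(data)[cc, , drop = FALSE]
  attr(out, "dropped") <- list(indices = which(!cc), n = sum(!cc))
  out
}

#' Automated data health check
#'
#' Reports, per column: missing-value counts; interquartile-range outlier
#' fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quantiles) with flagged
#' row indices for every numeric B/D column; and the Pearson correlation
#' matrix over quantitative predictors and responses, listing pairs with
#' `|r| > threshold` (default 0.8) as potentially collinear. Categorical
#' integer codes carry no metric meaning and are excluded from the
#' correlation scan. The input data is never modified.
#'
#' @param data A data frame.
#' @param classification A `variable_roles` table.
#' @param iqr_multiplier Fence width in IQR units (default 1.5).
#' @param cor_threshold Absolute correlation above which a pair is
#'   reported (default 0.8).
#' @return A `quality_report` list: `missing`, `outliers`, `correlation`
#'   (matrix), `collinear` (tibble), `warnings`.
#' @export
health_check <- function(data, classification, iqr_multiplier = 1.5,
                         cor_threshold = 0.8) {
  validate_roles(classification)
  warnings <- character(0)
  missing <- purrr::map_int(data, ~ sum(is.na(.x)))

  num_cols <- intersect(roles_of(classification, c("B", "D")), names(data))
  num_cols <- num_cols[vapply(data[num_cols], is.numeric, logical(1))]

  outliers <- purrr::map(num_cols, function(col) {
    x <- data[[col]]
    ok <- !is.na(x)
    if (sum(ok) < 4L) {
      warnings <<- c(warnings, sprintf("column '%s': < 4 non-missing values, outlier scan skipped", col))
      return(NULL)
    }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - iqr_multiplier * iqr
    hi <- q[2] + iqr_multiplier * iqr
    flagged <- which(ok & (x < lo | x > hi))
    list(q1 = q[1], q3 = q[2], lower = lo, upper = hi, flagged = flagged)
  })
  names(outliers) <- num_cols
  outliers <- outliers[!vapply(outliers, is.null, logical(1))]

  varying <- num_cols[vapply(num_cols, function(col) {
    v <- stats::var(data[[col]], na.rm = TRUE)
    ok <- is.finite(v) && v > 0
    if (!ok) warnings <<- c(warnings,
      sprintf("column '%s': constant, excluded from correlation analysis", col))
    ok
  }, logical(1))]
  correlation <- NULL
  collinear <- tibble::tibble(var1 = character(0), var2 = character(0),
                              r = numeric(0))
  if (length(varying) >= 2L) {
    correlation <- stats::cor(data[varying], use = "pairwise.complete.obs",
                              method = "pearson")
    iu <- which(upper.tri(correlation) & abs(correlation) > cor_threshold,
                arr.ind = TRUE)
    collinear <- tibble::tibble(
      var1 = rownames(correlation)[iu[, 1]],
      var2 = colnames(correlation)[iu[, 2]],
      r = correlation[iu]
    )
  }

  structure(
    list(missing = missing, outliers = outliers, correlation = correlation,
         collinear = collinear, iqr_multiplier = iqr_multiplier,
         cor_threshold = cor_threshold, n_rows = nrow(data),
         warnings = warnings),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("# Data health check over %d rows\n", x$n_rows))
  cat(sprintf("  missing cells: %d in %d column(s)\n",
              sum(x$missing), sum(x$missing > 0)))
  nfl <- sum(vapply(x$outliers, function(o) length(o$flagged), integer(1)))
  cat(sprintf("  IQR outliers (x%.1f fences): %d flagged value(s)\n",
              x$iqr_multiplier, nfl))
  cat(sprintf("  collinear pairs (|r| > %.2f): %d\n",
              x$cor_threshold, nrow(x$collinear)))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tidy a quality report
#'
#' @param x A `quality_report`.
#' @param ... Unused.
#' @return One row per scanned numeric column: missing count, quartiles,
#'   fences and the number of flagged outliers.
#' @export
tidy.quality_report <- function(x, ...) {
  purrr::map_dfr(names(x$outliers), function(col) {
    o <- x$outliers[[col]]
    tibble::tibble(column = col, missing = unname(x$missing[col]),
                   q1 = o$q1, q3 = o$q3, lower_fence = o$lower,
                   upper_fence = o$upper, n_outliers = length(o$flagged))
  })
}

#' Plot a quality report correlation heatmap
#'
#' @param object A `quality_report`.
#' @param ... Unused.
#' @return A ggplot heatmap of the predictor/response correlation matrix.
#' @export
autoplot.quality_report <- function(object, ...) {
  if (is.null(object$correlation)) {
    stop("no correlation matrix available (fewer than 2 varying numeric columns)",
         call. = FALSE)
  }
  df <- as.data.frame(as.table(object$correlation))
  names(df) <- c("var1", "var2", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Predictor/response correlations") +
    ggplot2::theme_minimal()
}
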