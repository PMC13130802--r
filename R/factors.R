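#' Declare one experimental factor
#'
#' A factor is either `continuous` (a concentration, temperature, pH, ...)
#' with a biologically viable range `[min, max]`, or `categorical`
#' (genotype, basal medium, ...) with 2--20 discrete levels. Continuous
#' factors may additionally carry an explicit `levels` vector, which is
#' required by the grid-based designs (full factorial, random design).
#'
#' @param name Column name used in generated design tables. Must be unique
#'   within one design.
#' @param kind `"continuous"` or `"categorical"`.
#' @param min,max Range of a continuous factor in actual units (`min < max`).
#' @param levels Ordered vector of levels: numeric concentrations for a
#'   continuous factor used in a grid design, labels for a categorical one.
#' @param units Free-text units, kept as metadata (e.g. `"mg/L"`).
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("BAP", min = 0, max = 5, units = "uM")
#' factor_spec("basal", kind = "categorical", levels = c("MS", "DKW", "GNH"))
#' @export
factor_spec <- function(name, kind = c("continuous", "categorical"),
                        min = NULL, max = NULL, levels = NULL, units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (is.null(min) && !is.null(levels)) min <- base::min(levels)
    if (is.null(max) && !is.null(levels)) max <- base::max(levels)
    if (is.null(min) || is.null(max)) {
      stop("continuous factor '", name, "' needs min and max (or explicit levels)",
           call. = FALSE)
    }
    single_level <- !is.null(levels) && length(levels) == 1L
    if (!(is.numeric(min) && is.numeric(max) &&
          (min < max || (single_level && min == max)))) {
      stop("factor '", name, "': min must be < max", call. = FALSE)
    }
    if (!is.null(levels) && !is.numeric(levels)) {
      stop("factor '", name, "': levels of a continuous factor must be numeric",
           call. = FALSE)
    }
  } else {
    if (is.null(levels) || length(levels) < 2L || length(levels) > 20L) {
      stop("categorical factor '", name, "' needs between 2 and 20 levels",
           call. = FALSE)
    }
    if (anyDuplicated(levels)) {
      stop("categorical factor '", name, "' has duplicated levels", call. = FALSE)
    }
    min <- NULL
    max <- NULL
  }
  structure(
    list(name = name, kind = kind, min = min, max = max,
         levels = levels, units = units),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<factor %s: continuous [%g, %g] %s>\n", x$name, x$min, x$max, x$units))
  } else {
    cat(sprintf("<factor %s: categorical {%s}>\n", x$name,
                paste(x$levels, collapse = ", ")))
  }
  invisible(x)
}

# Normalize 'factors' argument: a factor_spec, or a list of them.
# Enforces unique names.
as_factor_specs <- function(factors) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (!is.list(factors) || !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a factor_spec or a list of factor_spec objects",
         call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("factor names must be unique", call. = FALSE)
  names(factors) <- nms
  factors
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")

require_continuous <- function(factors, design) {
  kinds <- vapply(factors, `[[`, character(1), "kind")
  if (any(kinds != "continuous")) {
    stop(design, " designs support continuous factors only; categorical factor(s): ",
         paste(names(factors)[kinds != "continuous"], collapse = ", "),
         call. = FALSE)
  }
  zero <- vapply(factors, function(f) f$min >= f$max, logical(1))
  if (any(zero)) {
    stop(design, " needs a non-degenerate range for every factor; zero range: ",
         paste(names(factors)[zero], collapse = ", "), call. = FALSE)
  }
  invisible(factors)
}

require_levels <- function(factors, design) {
  has <- vapply(factors, function(f) !is.null(f$levels), logical(1))
  if (!all(has)) {
    stop(design, " needs an explicit level list for every factor; missing for: ",
         paste(names(factors)[!has], collapse = ", "), call. = FALSE)
  }
  invisible(factors)
}

# coded (cube = +-1, center = 0, axial = +-alpha) <-> actual units
coded_to_actual <- function(coded, spec) {
  mid <- (spec$min + spec$max) / 2
  half <- (spec$max - spec$min) / 2
  mid + coded * half
}

actual_to_coded <- function(actual, spec) {
  mid <- (spec$min + spec$max) / 2
  half <- (spec$max - spec$min) / 2
  (actual - mid) / half
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses (and advances) the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
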