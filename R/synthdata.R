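# Synthetic fixtures with known structure: the ZDT2 benchmark (known
# Pareto front f2 = 1 - f1^2) and a tissue-culture-like response-surface
# simulator emulating a four-input, four-response shoot proliferation
# dataset. Both are seeded and fully reproducible.

#' ZDT2 benchmark dataset
#'
#' Draws `n_samples` points uniformly from `[0, 1]^d` and evaluates the
#' ZDT2 test functions `f1 = x1`,
#' `f2 = g (1 - (f1/g)^2)` with `g = 1 + 9 mean(x2..xd)`, then adds
#' Gaussian noise with standard deviation `noise * sd(response)` per
#' response. Both responses are minimization objectives; the theoretical
#' Pareto front is `f2 = 1 - f1^2` at `g = 1`.
#'
#' @param n_samples Number of rows (default 750).
#' @param n_variables Number of input variables `d >= 2` (default 10).
#' @param noise Noise fraction (default 0.10 = 10% Gaussian noise).
#' @param seed Integer seed.
#' @return A tibble `x1..xd, f1, f2` with a `"roles"` attribute marking
#'   inputs as quantitative predictors and the two responses.
#' @export
make_zdt2 <- function(n_samples = 750L, n_variables = 10L, noise = 0.10,
                      seed = NULL) {
  stopifnot(n_samples >= 10L, n_variables >= 2L, noise >= 0)
  with_seed(seed, {
    X <- matrix(stats::runif(n_samples * n_variables), n_samples)
    F <- zdt2_eval(X)
    f1 <- F[, 1]
    f2 <- F[, 2]
    if (noise > 0) {
      f1 <- f1 + stats::rnorm(n_samples, 0, noise * stats::sd(f1))
      f2 <- f2 + stats::rnorm(n_samples, 0, noise * stats::sd(f2))
    }
    out <- tibble::as_tibble(as.data.frame(X))
    names(out) <- paste0("x", seq_len(n_variables))
    out$f1 <- f1
    out$f2 <- f2
    attr(out, "roles") <- c(stats::setNames(rep("B", n_variables),
                                            paste0("x", seq_len(n_variables))),
                            f1 = "D", f2 = "D")
    out
  })
}

# noiseless ZDT2 objectives for a matrix of rows in [0,1]^d
zdt2_eval <- function(X) {
  X <- matrix(X, ncol = ncol(X))
  f1 <- X[, 1]
  g <- 1 + 9 * rowMeans(X[, -1, drop = FALSE])
  cbind(f1, g * (1 - (f1 / g)^2))
}

#' ZDT2 as a direct optimization problem
#'
#' The noiseless two-objective ZDT2 function wrapped as a
#' [direct_problem()] over `[0, 1]^d` for benchmarking the
#' multi-objective optimizers against the known front.
#'
#' @param n_variables Decision-space dimension (default 10).
#' @return An `optimization_problem`.
#' @export
zdt2_problem <- function(n_variables = 10L) {
  direct_problem(zdt2_eval, lower = rep(0, n_variables),
                 upper = rep(1, n_variables), n_obj = 2L)
}

# ---- tissue-culture response-surface simulator ------------------------------

# Input ranges (actual units) of the four media components
TISSUE_BOUNDS <- list(
  BAP = c(0, 5),        # cytokinin, uM
  IBA = c(0, 1),        # auxin, uM
  PG = c(0, 0.5),       # phloroglucinol, mM
  sucrose = c(40, 120)  # mM
)

# Noiseless response surfaces on a matrix with columns BAP, IBA, PG, sucrose.
# PR: bounded logistic-quadratic (%); SN: peaked quadratic count;
# SL: quadratic, antagonistic to SN along the cytokinin axis;
# BCW: monotone callus weight, the minimization objective.
tissue_truth <- function(X) {
  u1 <- X[, 1] / 5
  u2 <- X[, 2] / 1
  u3 <- X[, 3] / 0.5
  u4 <- (X[, 4] - 40) / 80
  d_pr <- 2.5 * (u1 - 0.45)^2 + 1.2 * (u2 - 0.30)^2 + 0.8 * (u3 - 0.55)^2 +
    1.5 * (u4 - 0.60)^2
  PR <- 100 * stats::plogis(3.8 - 4 * d_pr)
  d_sn <- 1.5 * (u1 - 0.50)^2 + 0.8 * (u2 - 0.35)^2 + 0.5 * (u3 - 0.50)^2 +
    0.8 * (u4 - 0.55)^2
  SN <- 13 * pmax(0, 1 - 2.2 * d_sn)
  d_sl <- 1.6 * (u1 - 0.25)^2 + 0.7 * (u2 - 0.30)^2 + 0.4 * (u3 - 0.45)^2 +
    0.7 * (u4 - 0.50)^2
  SL <- 5.8 * pmax(0, 1 - 1.8 * d_sl)
  BCW <- 0.05 + 0.45 * (0.7 * u1 + 0.3 * u4)^1.5
  cbind(PR = PR, SN = SN, SL = SL, BCW = BCW)
}

TISSUE_DIRECTIONS <- c(PR = "maximize", SN = "maximize", SL = "maximize",
                       BCW = "minimize")

#' Tissue-culture response-surface simulator
#'
#' Emulates a four-input, four-response shoot proliferation experiment:
#' a full factorial over cytokinin (BAP), auxin (IBA), phloroglucinol
#' (PG) and sucrose, each at `n_levels` levels, replicated
#' `n_replicates` times (the defaults give the 3^4 x 9 = 729-observation
#' layout typical of such studies). Responses are a bounded
#' logistic-quadratic proliferation rate PR (0--100%), a peaked
#' quadratic shoot number SN, a quadratic shoot length SL whose optimum
#' sits at lower cytokinin than SN's (the classic antagonism), and a
#' monotone basal callus weight BCW to be minimized. Heteroscedastic
#' Gaussian noise with per-response standard deviation
#' `noise * sd(response) * (0.5 + response/max)` is added and responses
#' are clipped to their valid ranges (PR to `[0, 100]`, the rest to
#' `>= 0`).
#'
#' The returned ground truth contains the analytic input maximizing the
#' true cumulative normalized fitness (normalized against the true
#' response extremes over the input box), for parameter-recovery tests.
#'
#' @param n_levels Levels per factor in the factorial (default 3).
#' @param n_replicates Replicates per treatment (default 9).
#' @param noise Noise fraction (default 0.05).
#' @param sampling `"factorial"` (default; emulates the replicated
#'   3^4 layout of real proliferation studies) or `"uniform"`
#'   (space-filling draws over the input box, the appropriate design
#'   when the goal is locating an interior optimum rather than ranking
#'   discrete treatments).
#' @param n_samples Number of rows for `sampling = "uniform"`
#'   (default 750).
#' @param seed Integer seed.
#' @return A list with `data` (tibble, `"roles"` attribute attached),
#'   `ground_truth` (`optimum` inputs, `optimum_values` responses,
#'   `cumulative` at the optimum, `directions`, `bounds`) and the truth
#'   function `truth(X)`.
#' @export
make_tissue4x4 <- function(n_levels = 3L, n_replicates = 9L, noise = 0.05,
                           sampling = c("factorial", "uniform"),
                           n_samples = 750L, seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(n_levels >= 2L, n_replicates >= 1L, noise >= 0, n_samples >= 10L)
  X <- if (sampling == "factorial") {
    grid <- expand.grid(lapply(TISSUE_BOUNDS, function(b) {
      seq(b[1], b[2], length.out = n_levels)
    }), KEEP.OUT.ATTRS = FALSE)
    as.matrix(grid[rep(seq_len(nrow(grid)), each = n_replicates), ])
  } else {
    with_seed(if (is.null(seed)) NULL else seed + 1L, {
      U <- matrix(stats::runif(n_samples * 4L), n_samples)
      lo <- vapply(TISSUE_BOUNDS, `[[`, numeric(1), 1L)
      hi <- vapply(TISSUE_BOUNDS, `[[`, numeric(1), 2L)
      m <- sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
      colnames(m) <- names(TISSUE_BOUNDS)
      m
    })
  }
  Y <- tissue_truth(X)
  data <- with_seed(seed, {
    if (noise > 0) {
      for (k in seq_len(ncol(Y))) {
        scale_k <- 0.5 + Y[, k] / max(Y[, k])
        Y[, k] <- Y[, k] + stats::rnorm(nrow(Y), 0,
                                        noise * stats::sd(Y[, k]) * scale_k)
      }
    }
    Y[, "PR"] <- pmin(100, pmax(0, Y[, "PR"]))
    Y[, "SN"] <- pmax(0, Y[, "SN"])
    Y[, "SL"] <- pmax(0, Y[, "SL"])
    Y[, "BCW"] <- pmax(0, Y[, "BCW"])
    out <- tibble::as_tibble(cbind(as.data.frame(X), as.data.frame(Y)))
    attr(out, "roles") <- c(stats::setNames(rep("B", 4), names(TISSUE_BOUNDS)),
                            stats::setNames(rep("D", 4), colnames(Y)))
    out
  })
  list(data = data, ground_truth = tissue_ground_truth(),
       truth = tissue_truth)
}

# analytic optimum of the true cumulative normalized fitness: dense grid
# plus local polish (deterministic; no RNG involved)
tissue_ground_truth <- function() {
  lo <- vapply(TISSUE_BOUNDS, `[[`, numeric(1), 1L)
  hi <- vapply(TISSUE_BOUNDS, `[[`, numeric(1), 2L)
  dense <- as.matrix(expand.grid(lapply(TISSUE_BOUNDS, function(b) {
    seq(b[1], b[2], length.out = 17)
  }), KEEP.OUT.ATTRS = FALSE))
  Yd <- tissue_truth(dense)
  y_min <- apply(Yd, 2, min)
  y_max <- apply(Yd, 2, max)
  cum_of <- function(X) {
    Y <- tissue_truth(matrix(X, ncol = 4))
    z <- sweep(sweep(Y, 2, y_min), 2, y_max - y_min, "/")
    z <- pmin(pmax(z, 0), 1)   # argument order keeps the dim attribute
    z[, "BCW"] <- 1 - z[, "BCW"]
    rowSums(z)
  }
  start <- dense[which.max(cum_of(dense)), ]
  opt <- stats::optim(start, function(x) -cum_of(matrix(x, 1)),
                      method = "L-BFGS-B", lower = lo, upper = hi)
  xopt <- opt$par
  names(xopt) <- names(TISSUE_BOUNDS)
  vals <- drop(tissue_truth(matrix(xopt, 1)))
  list(optimum = xopt, optimum_values = vals, cumulative = -opt$value,
       directions = TISSUE_DIRECTIONS,
       bounds = TISSUE_BOUNDS, y_min = y_min, y_max = y_max)
}
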