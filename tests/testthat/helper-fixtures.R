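# Shared fixtures and independent oracles.

cont_factors <- function(k, lo = 0, hi = 10) {
  lapply(LETTERS[seq_len(k)], function(n) factor_spec(n, min = lo, max = hi))
}

level_factors <- function(k, levels) {
  lapply(LETTERS[seq_len(k)], function(n) factor_spec(n, levels = levels))
}

cat_factors <- function(k, levels) {
  lapply(LETTERS[seq_len(k)], function(n) {
    factor_spec(n, kind = "categorical", levels = levels)
  })
}

# small linear-signal regression dataset: y = 3 x1 + noise, 3 inert inputs
linear_dataset <- function(n = 120, noise_sd = 0.2, seed = 7) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      x1 = runif(n), x2 = runif(n), x3 = runif(n), x4 = runif(n),
      y = 3 * runif(n)  # placeholder, replaced below
    )
    d$y <- 3 * d$x1 + rnorm(n, 0, noise_sd)
    d
  })
}

linear_roles <- c(x1 = "B", x2 = "B", x3 = "B", x4 = "B", y = "D")

# brute-force non-dominated ranking oracle: repeated peeling with an
# independent pairwise dominance check (minimization)
brute_nds_rank <- function(F) {
  n <- nrow(F)
  dom_pair <- function(a, b) all(a <= b) && any(a < b)
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    r <- r + 1L
    open <- which(is.na(rank))
    for (i in open) {
      dominated <- FALSE
      for (j in open) {
        if (i != j && dom_pair(F[j, ], F[i, ])) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) rank[i] <- r
    }
  }
  rank
}

# Monte-Carlo hypervolume oracle (minimization, points must dominate ref)
mc_hypervolume <- function(P, ref, n_samples = 1e6, seed = 99) {
  withr::with_seed(seed, {
    m <- length(ref)
    lo <- apply(P, 2, min)
    M <- matrix(runif(n_samples * m, rep(lo, each = n_samples),
                      rep(ref, each = n_samples)), ncol = m)
    dom <- rep(FALSE, n_samples)
    for (i in seq_len(nrow(P))) {
      inside <- rep(TRUE, n_samples)
      for (k in seq_len(m)) inside <- inside & (M[, k] >= P[i, k])
      dom <- dom | inside
    }
    mean(dom) * prod(ref - lo)
  })
}

# a transparent surrogate stand-in for objective specs: predicts fn(newdata)
lookup_model <- function(fn) structure(list(fn = fn), class = "test_lookup")
assign("predict.test_lookup",
       function(object, newdata, ...) object$fn(newdata),
       envir = globalenv())

# cheap 2-objective direct problem for evaluation-budget checks
toy_biobjective <- function(d = 4) {
  direct_problem(function(X) cbind(rowSums(X^2), rowSums((X - 1)^2)),
                 lower = rep(0, d), upper = rep(1, d), n_obj = 2L)
}
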