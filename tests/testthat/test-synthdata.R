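test_that("ZDT2 responses satisfy their closed forms without noise", {
  d <- make_zdt2(n_samples = 60, n_variables = 6, noise = 0, seed = 2)
  X <- as.matrix(d[, paste0("x", 1:6)])
  g <- 1 + 9 * rowMeans(X[, -1])
  expect_equal(d$f1, X[, 1], tolerance = 1e-12)
  expect_equal(d$f2, g * (1 - (d$f1 / g)^2), tolerance = 1e-12)

  # x = 0 vector: f1 = 0, g = 1, f2 = 1
  F0 <- mediaopt:::zdt2_eval(matrix(0, 1, 6))
  expect_equal(as.numeric(F0), c(0, 1))
  # on the Pareto subspace (x2..xd = 0): f2 = 1 - f1^2
  Xf <- cbind(seq(0, 1, 0.1), matrix(0, 11, 5))
  Ff <- mediaopt:::zdt2_eval(Xf)
  expect_equal(Ff[, 2], 1 - Ff[, 1]^2, tolerance = 1e-12)
})

test_that("ZDT2 generator is seed-stable and injects the requested noise level", {
  a <- make_zdt2(750, 10, noise = 0.10, seed = 33)
  b <- make_zdt2(750, 10, noise = 0.10, seed = 33)
  expect_identical(a, b)
  expect_equal(dim(a), c(750L, 12L))
  expect_equal(unname(attr(a, "roles")[c("x1", "f1")]), c("B", "D"))

  clean <- mediaopt:::zdt2_eval(as.matrix(a[, paste0("x", 1:10)]))
  for (k in 1:2) {
    injected <- sd(a[[paste0("f", k)]] - clean[, k])
    target <- 0.10 * sd(clean[, k])
    expect_equal(injected, target, tolerance = 0.15)
  }
})

test_that("tissue simulator reproduces the Use Case I layout and clips responses to valid ranges", {
  sim <- make_tissue4x4(seed = 1)
  expect_equal(nrow(sim$data), 729)           # 3^4 treatments x 9 replicates
  expect_equal(nrow(dplyr::distinct(sim$data[, 1:4])), 81)
  expect_true(all(sim$data$PR >= 0 & sim$data$PR <= 100))
  expect_true(all(sim$data$SN >= 0))
  expect_true(all(sim$data$BCW >= 0))
  expect_identical(sim$data, make_tissue4x4(seed = 1)$data)
  expect_false(identical(sim$data$PR, make_tissue4x4(seed = 2)$data$PR))
})

test_that("the tissue ground truth is the noiseless optimum of its own surfaces", {
  sim <- make_tissue4x4(noise = 0, seed = 3)
  gt <- sim$ground_truth
  at_opt <- drop(sim$truth(matrix(gt$optimum, 1)))
  expect_equal(at_opt, gt$optimum_values, tolerance = 1e-12)
  # no nearby point beats the reported optimum on true cumulative fitness
  norm_cum <- function(X) {
    Y <- sim$truth(X)
    z <- sweep(sweep(Y, 2, gt$y_min), 2, gt$y_max - gt$y_min, "/")
    z <- pmin(pmax(z, 0), 1)
    z[, "BCW"] <- 1 - z[, "BCW"]
    rowSums(z)
  }
  withr::with_seed(4, {
    lo <- vapply(gt$bounds, `[[`, numeric(1), 1)
    hi <- vapply(gt$bounds, `[[`, numeric(1), 2)
    probe <- matrix(runif(400 * 4, rep(lo, each = 400), rep(hi, each = 400)),
                    ncol = 4)
  })
  expect_gte(gt$cumulative, max(norm_cum(probe)) - 1e-6)
})

test_that("uniform sampling mode covers the input box", {
  sim <- make_tissue4x4(sampling = "uniform", n_samples = 300, seed = 5)
  expect_equal(nrow(sim$data), 300)
  for (v in names(mediaopt:::TISSUE_BOUNDS)) {
    b <- mediaopt:::TISSUE_BOUNDS[[v]]
    expect_true(all(sim$data[[v]] >= b[1] & sim$data[[v]] <= b[2]))
    expect_gt(diff(range(sim$data[[v]])) / diff(b), 0.9)
  }
})
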