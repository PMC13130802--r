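test_that("full factorial enumerates every combination the declared number of times", {
  f <- level_factors(3, c(0, 1, 2, 3, 4))
  d1 <- design_ffd(f)
  expect_equal(nrow(d1), 125)
  expect_equal(nrow(dplyr::distinct(d1[, c("A", "B", "C")])), 125)

  d3 <- design_ffd(f, replicates = 3)
  expect_equal(nrow(d3), 375)
  counts <- dplyr::count(d3, A, B, C)
  expect_true(all(counts$n == 3))

  expect_equal(nrow(design_ffd(level_factors(1, 7))), 1)
  expect_error(design_ffd(cont_factors(2)), "level list")
})

test_that("full factorial row order is lexicographic and deterministic", {
  f <- level_factors(2, c(1, 2))
  d <- design_ffd(f)
  expect_equal(d$A, c(1, 1, 2, 2))
  expect_equal(d$B, c(1, 2, 1, 2))
})

test_that("central composite design has cube, axial and center points in the stated counts", {
  d2 <- design_ccd(cont_factors(2))
  expect_equal(nrow(d2), 12)   # 4 cube + 4 axial + 4 center
  expect_equal(sum(d2$role == "cube"), 4)
  expect_equal(sum(d2$role == "axial"), 4)
  expect_equal(sum(d2$role == "center"), 4)

  coded <- design_coded(d2)
  ax <- coded[d2$role == "axial", ]
  expect_equal(sort(abs(as.matrix(ax))[abs(as.matrix(ax)) > 0]), rep(0.8, 4))

  d3 <- design_ccd(cont_factors(3))
  expect_equal(nrow(d3), 20)   # 8 + 6 + max(4, 6)

  expect_error(design_ccd(cont_factors(1)), ">= 2 factors")
  expect_error(design_ccd(cat_factors(2, c("a", "b")), alpha = 0.8),
               "continuous")
})

test_that("CCD decoding is linear, invertible and stays within factor limits", {
  f <- cont_factors(2, lo = 0, hi = 10)
  d <- design_ccd(f, alpha = 0.8)
  coded <- as.matrix(design_coded(d))
  actual <- as.matrix(d[, c("A", "B")])
  # actual = midpoint + coded * half-range; +0.8 axial on [0, 10] -> 9.0
  expect_equal(actual, 5 + coded * 5, ignore_attr = TRUE)
  expect_true(any(abs(actual - 9.0) < 1e-12))
  # encode(decode(c)) = c
  recoded <- (actual - 5) / 5
  expect_lt(max(abs(recoded - coded)), 1e-12)
  # alpha <= 1 never leaves [min, max]
  expect_true(all(actual >= 0 & actual <= 10))
})

test_that("Box-Behnken uses edge midpoints only and needs three factors", {
  d <- design_bbd(cont_factors(3))
  expect_equal(nrow(d), 18)    # 4 * C(3,2) + max(4, 6)
  coded <- as.matrix(design_coded(d))
  extremes_per_row <- rowSums(abs(coded) == 1)
  expect_true(all(extremes_per_row <= 2))
  expect_false(any(extremes_per_row == 3))  # no full corners
  expect_error(design_bbd(cont_factors(2)), "requires >= 3 factors")
})

test_that("Latin hypercube puts exactly one sample in every interval for every factor", {
  f <- cont_factors(3, lo = 0, hi = 1)
  for (seed in c(1, 2, 42)) {
    d <- design_lhs(f, n_runs = 10, seed = seed)
    for (col in c("A", "B", "C")) {
      occupancy <- table(cut(d[[col]], breaks = seq(0, 1, by = 0.1),
                             include.lowest = TRUE))
      expect_true(all(occupancy == 1))
    }
  }
  expect_equal(nrow(design_lhs(f, n_runs = 1, seed = 1)), 1)
  d1 <- design_lhs(f, n_runs = 1, seed = 5)
  expect_true(all(d1$A >= 0 & d1$A <= 1))
  expect_identical(design_lhs(f, 10, seed = 3), design_lhs(f, 10, seed = 3))
  expect_error(design_lhs(cat_factors(2, c("a", "b")), 5), "continuous")
})

test_that("random design falls back to the full grid at 50 combinations or fewer", {
  f <- level_factors(2, 1:7)          # 49 combinations
  d <- design_random(f, seed = 1)
  expect_equal(nrow(d), 49)
  expect_equal(nrow(dplyr::distinct(d[, c("A", "B")])), 49)
})

test_that("random design subsample stays in the 20-100 run window and includes corners and center", {
  f5 <- level_factors(5, c(0, 1, 2, 3, 4))   # G = 3125
  d <- design_random(f5, seed = 11)
  expect_gte(nrow(d), 20)
  expect_lte(nrow(d), 100)

  f2 <- level_factors(2, 1:9)                # G = 81 -> n = 24
  d2 <- design_random(f2, seed = 3)
  key <- paste(d2$A, d2$B)
  for (corner in c("1 1", "1 9", "9 1", "9 9")) expect_true(corner %in% key)
  expect_true("5 5" %in% key)                # middle level center
  expect_identical(design_random(f2, seed = 3), design_random(f2, seed = 3))
})

test_that("replicate cleanup caps each treatment and reports removals", {
  one <- design_ffd(level_factors(1, 5), replicates = 8)
  kept <- cleanup_replicates(one)
  expect_equal(nrow(kept), 5)
  expect_equal(attr(kept, "cleanup_report")$n_removed, 3)

  ok <- design_ffd(level_factors(1, 5), replicates = 5)
  expect_equal(nrow(cleanup_replicates(ok)), 5)

  three <- design_ffd(level_factors(1, c(1, 2, 3)), replicates = 4)
  expect_equal(nrow(cleanup_replicates(three, max_replicates = 1)), 3)
  # first occurrences kept, order preserved
  first <- cleanup_replicates(three, 1)
  expect_equal(first$replicate, c(1L, 1L, 1L))
  expect_error(cleanup_replicates(three, 0), "max_replicates")
})

test_that("design export is byte-identical under identical seed and config", {
  f <- cont_factors(3)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_design(design_lhs(f, 15, seed = 9), p1)
  write_design(design_lhs(f, 15, seed = 9), p2)
  expect_identical(readLines(p1), readLines(p2))
})
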