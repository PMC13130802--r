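toy_data <- function() {
  tibble::tibble(
    run = 1:12,
    basal = rep(c("MS", "DKW", "GNH"), 4),
    BAP = rep(c(0, 0.5, 1, 2), 3),
    dose = seq(0.1, 1.2, by = 0.1) * 7,        # 12 distinct values
    PR = c(55, 60, 70, 80, 85, 90, 40, 45, 88, 92, 71, 66)
  )
}

test_that("variable classification follows the id / 2-20 level / numeric heuristics", {
  d <- toy_data()
  cl <- classify_variables(d, roles = c(PR = "D", dose = "B"))
  roles <- setNames(cl$role, cl$column)
  expect_equal(roles[["run"]], "A")       # identifier
  expect_equal(roles[["basal"]], "C")     # three labels -> categorical
  expect_equal(cl$n_levels[cl$column == "basal"], 3L)
  expect_equal(roles[["BAP"]], "C")       # 4 distinct numeric values
  expect_equal(roles[["PR"]], "D")        # user override
  expect_equal(cl$provenance[cl$column == "PR"], "user")

  # 21 distinct values sits just outside the categorical window
  d21 <- tibble::tibble(x = rep(seq_len(21), 2), y = rnorm(42))
  cl21 <- classify_variables(d21, roles = c(y = "D"))
  expect_equal(cl21$role[cl21$column == "x"], "B")
  d20 <- tibble::tibble(x = rep(seq_len(20), 2), y = rnorm(40))
  cl20 <- classify_variables(d20, roles = c(y = "D"))
  expect_equal(cl20$role[cl20$column == "x"], "C")
})

test_that("classification without predictors or responses fails with the missing roles named", {
  d <- toy_data()
  expect_error(classify_variables(d), "response")
  expect_error(
    classify_variables(tibble::tibble(id = 1:5, y = rnorm(5)),
                       roles = c(y = "D")),
    "predictor")
  expect_error(classify_variables(d, roles = c(PR = "X")), "A, B, C, D")
  expect_error(classify_variables(d, roles = c(nope = "D")), "unknown column")
})

test_that("classification is idempotent on an already-classified dataset", {
  d <- toy_data()
  overrides <- c(PR = "D", dose = "B")
  cl1 <- classify_variables(d, roles = overrides)
  enc <- encode_categoricals(d, cl1)
  cl2 <- classify_variables(enc$data, roles = overrides)
  expect_equal(setNames(cl2$role, cl2$column), setNames(cl1$role, cl1$column))
})

test_that("integer encoding assigns consecutive codes in first-appearance order and round-trips", {
  d <- tibble::tibble(
    g = c("Genotype A", "Genotype B", "Genotype C", "Genotype A"),
    h = c("Genotype C", "Genotype A", "Genotype A", "Genotype B"),
    y = c(1.5, 2.5, 3.5, 4.5)
  )
  cl <- classify_variables(d, roles = c(g = "C", h = "C", y = "D"))
  enc <- encode_categoricals(d, cl)
  expect_equal(enc$data$g, c(0L, 1L, 2L, 0L))
  # per-column scope: same labels, independent maps
  expect_equal(enc$data$h, c(0L, 1L, 1L, 2L))
  expect_equal(enc$map$g, c("Genotype A", "Genotype B", "Genotype C"))
  expect_equal(enc$map$h, c("Genotype C", "Genotype A", "Genotype B"))

  dec <- decode_categoricals(enc$data, enc$map)
  expect_equal(dec$g, d$g)
  expect_equal(dec$h, d$h)

  bad <- enc$data
  bad$g[1] <- 9L
  expect_error(decode_categoricals(bad, enc$map), "unseen code")
})

test_that("complete-case deletion removes any row with a missing cell, descriptors included", {
  d <- tibble::tibble(id = 1:10, x = c(NA, 2:10), y = c(1:9, NA))
  out <- drop_incomplete_rows(d)
  expect_equal(nrow(out), 8)
  expect_equal(attr(out, "dropped")$indices, c(1L, 10L))

  full <- tibble::tibble(x = 1:3, y = 4:6)
  expect_equal(nrow(drop_incomplete_rows(full)), 3)

  # missing only in a descriptor column still drops the row
  da <- tibble::tibble(id = c(1, NA, 3), x = c(1, 2, 3), y = c(4, 5, 6))
  expect_equal(nrow(drop_incomplete_rows(da)), 2)

  allna <- tibble::tibble(x = c(NA_real_, NA_real_))
  expect_error(drop_incomplete_rows(allna), "all rows")
})

test_that("health check flags IQR outliers with hand-computed fences", {
  d <- tibble::tibble(x = c(1:10, 100), y = c(2 * (1:10), 150))
  cl <- classify_variables(d, roles = c(x = "B", y = "D"))
  qr <- health_check(d, cl)
  # type-7 quartiles of {1..10, 100}: Q1 = 3.5, Q3 = 8.5, upper fence 16
  expect_equal(qr$outliers$x$q1, 3.5)
  expect_equal(qr$outliers$x$q3, 8.5)
  expect_equal(qr$outliers$x$upper, 16)
  expect_equal(qr$outliers$x$flagged, 11L)
})

test_that("health check reports perfectly correlated pairs and excludes constants", {
  d <- tibble::tibble(x = as.numeric(1:20), y = 2 * as.numeric(1:20),
                      z = rep(5, 20))
  cl <- classify_variables(d, roles = c(x = "B", y = "D", z = "B"))
  qr <- health_check(d, cl)
  expect_equal(nrow(qr$collinear), 1)
  expect_equal(qr$collinear$r, 1.0)
  expect_true(any(grepl("constant", qr$warnings)))
  expect_false("z" %in% rownames(qr$correlation))
  # zero IQR, no flags for the constant column
  expect_equal(length(qr$outliers$z$flagged), 0)
  # side-effect free
  d2 <- tibble::tibble(x = as.numeric(1:20), y = 2 * as.numeric(1:20),
                       z = rep(5, 20))
  expect_identical(d, d2)
})

test_that("short numeric columns skip the outlier scan with a warning", {
  d <- tibble::tibble(x = c(1, 2, NA, NA, NA), y = c(1, 2, 3, 4, 5))
  cl <- classify_variables(d, roles = c(x = "B", y = "D"))
  qr <- health_check(d, cl)
  expect_false("x" %in% names(qr$outliers))
  expect_true(any(grepl("skipped", qr$warnings)))
})
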