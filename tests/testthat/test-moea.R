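test_that("fast non-dominated sorting matches the brute-force dominance oracle", {
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(3:50, 1)
      m <- sample(2:4, 1)
      F <- matrix(runif(n * m), n, m)
      expect_equal(mediaopt:::nds_rank(F), brute_nds_rank(F))
    }
  })
})

test_that("constrained domination lets feasible candidates dominate infeasible ones", {
  F <- rbind(c(0.1, 0.1),   # infeasible, best objectives
             c(0.9, 0.9),   # feasible, poor objectives
             c(0.5, 0.4))   # feasible
  pen <- c(2, 0, 0)
  # (0.5, 0.4) dominates (0.9, 0.9); both feasible rows dominate the
  # infeasible one, so the ranking is 3, 2, 1
  expect_equal(mediaopt:::nds_rank(F, pen), c(3L, 2L, 1L))
  # without penalties the first row leads instead
  expect_equal(mediaopt:::nds_rank(F)[1], 1L)
})

test_that("crowding distance assigns infinite distance to front boundaries", {
  F <- cbind(c(0, 0.2, 0.5, 1), c(1, 0.8, 0.5, 0))
  cd <- mediaopt:::crowding_distance(F)
  expect_equal(cd[1], Inf)
  expect_equal(cd[4], Inf)
  expect_true(all(is.finite(cd[2:3])))
})

test_that("exact hypervolume matches closed forms and a Monte-Carlo oracle", {
  expect_equal(hypervolume(rbind(c(0, 0)), c(1, 1)), 1.0)
  # inclusion-exclusion: 0.5 + 0.5 - 0.25
  expect_equal(hypervolume(rbind(c(0, 0.5), c(0.5, 0)), c(1, 1)), 0.75)
  expect_warning(hypervolume(rbind(c(2, 2)), c(1, 1)), "do not dominate")

  withr::with_seed(17, {
    for (i in 1:3) {
      P <- matrix(runif(8 * 3), 8, 3)
      ref <- rep(1.2, 3)
      exact <- hypervolume(P, ref)
      mc <- mc_hypervolume(P, ref, n_samples = 2e5, seed = 40 + i)
      expect_equal(exact, mc, tolerance = 0.02)
    }
  })
})

test_that("hypervolume contributions agree with leave-one-out recomputation", {
  withr::with_seed(23, {
    P <- matrix(runif(12 * 2), 12, 2)
    ref <- c(1.1, 1.1)
    fast <- mediaopt:::hv_contributions(P, ref)
    slow <- vapply(seq_len(nrow(P)), function(i) {
      mediaopt:::hypervolume_safe(P, ref) -
        mediaopt:::hypervolume_safe(P[-i, , drop = FALSE], ref)
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-12)
  })
})

test_that("NSGA-II meets the exact evaluation budget and returns a non-dominated set", {
  prob <- toy_biobjective()
  res <- run_nsga2(prob, ea_control("NSGA2", mu = 20, lambda = 10,
                                    generations = 15, seed = 5))
  expect_equal(res$evaluations, 20 + 10 * 15)
  F <- cbind(res$solutions$pred_f1, res$solutions$pred_f2)
  expect_true(all(mediaopt:::nds_rank(F) == 1L))

  res2 <- run_nsga2(prob, ea_control("NSGA2", mu = 20, lambda = 10,
                                     generations = 15, seed = 5))
  expect_identical(res$solutions, res2$solutions)
  expect_identical(res$history, res2$history)
  expect_error(run_nsga2(direct_problem(function(X) matrix(rowSums(X), ncol = 1),
                                        c(0), c(1), 1),
                         ea_control("NSGA2", mu = 10, generations = 2)),
               "2 objectives")
})

test_that("SMS-EMOA removes the minimal-hypervolume-contribution member", {
  # 3-candidate toy front: exclusive contributions by inclusion-exclusion
  P <- rbind(c(0.1, 0.8), c(0.4, 0.4), c(0.45, 0.38))
  ref <- c(1.1, 1.1)
  contrib <- mediaopt:::hv_contributions(P, ref)
  brute <- vapply(1:3, function(i) {
    hypervolume(P, ref) - hypervolume(P[-i, , drop = FALSE], ref)
  }, numeric(1))
  expect_equal(contrib, brute)
  expect_equal(which.min(contrib), 3L)   # nearly dominated by point 2
})

test_that("SMS-EMOA population hypervolume never decreases under a fixed reference", {
  prob <- zdt2_problem(5)
  ref <- c(1.1, 11)
  hv_of <- function(res) {
    F <- cbind(res$solutions$pred_f1, res$solutions$pred_f2)
    mediaopt:::hypervolume_safe(F, ref)
  }
  short <- run_smsemoa(prob, ea_control("SMSEMOA", mu = 20, generations = 50,
                                        seed = 9), ref_point = ref)
  long <- run_smsemoa(prob, ea_control("SMSEMOA", mu = 20, generations = 200,
                                       seed = 9), ref_point = ref)
  expect_gte(hv_of(long), hv_of(short) - 1e-12)
  expect_equal(short$evaluations, 20 + 50)
  expect_error(run_smsemoa(prob, ea_control("NSGA2", mu = 10, lambda = 2,
                                            generations = 5)),
               "lambda = 1")
})

test_that("distance filtering keeps the best-cumulative solution and collapses duplicates", {
  sols <- tibble::tibble(a = c(0, 0, 1, 1, 0.5), b = c(0, 0, 1, 1, 0.5),
                         cumulative = c(0.2, 0.2, 0.9, 0.9, 0.5),
                         penalty = 0)
  attr(sols, "decision_vars") <- c("a", "b")
  one <- filter_solutions(sols, 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$cumulative, 0.9)

  # duplicates add no spread: max-min selection stops at 3 distinct points
  all_k <- filter_solutions(sols, 5)
  expect_identical(all_k, sols)
  three <- filter_solutions(sols, 4)
  expect_equal(nrow(three), 3)
})

test_that("sequential filtering prioritizes objectives stepwise and keeps ties", {
  sols <- tibble::tibble(pred_PR = c(10, 9, 8, 8, 7, 6, 5, 4, 3, 2),
                         pred_SN = c(1, 5, 9, 2, 8, 3, 7, 4, 6, 10))
  out <- sequential_filter(sols, c("pred_PR", "pred_SN"), keep_fraction = 0.5)
  expect_lte(nrow(out), 3)
  # step-1 survivors all have PR >= every dropped PR
  step1 <- sequential_filter(sols, "pred_PR", keep_fraction = 0.5)
  expect_gte(min(step1$pred_PR), max(sols$pred_PR[!sols$pred_PR %in% step1$pred_PR]))
  # ties at the cutoff are kept
  tied <- sequential_filter(tibble::tibble(v = c(3, 2, 2, 1)), "v", 0.5)
  expect_equal(nrow(tied), 3)
  # minimization priority flips the order
  mn <- sequential_filter(sols, c(pred_PR = "pred_PR"), 0.1,
                          directions = c(pred_PR = "minimize"))
  expect_equal(mn$pred_PR, 2)
})
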