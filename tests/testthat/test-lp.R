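test_that("the simplex solves textbook cases exactly", {
  # three-reaction chain in -> A -> out capped at 5
  A <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE)
  r <- lp_solve(c(0, 0, 1), A, c(0, 0), rep(0, 3), c(5, 1000, 1000))
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 5)
  # equality-constrained box problem
  r2 <- lp_solve(c(1, 2), matrix(c(1, 1), 1, 2), 3, c(0, 0), c(2, 2))
  expect_equal(r2$objective, 2 * 2 + 1 * 1)
  # infeasible
  r3 <- lp_solve(1, matrix(1, 1, 1), 5, 0, 2)
  expect_equal(r3$status, "infeasible")
  # negative lower bounds (reversible flux)
  A4 <- matrix(c(1, 1), 1, 2)
  r4 <- lp_solve(c(1, 0), A4, 0, c(-3, -3), c(3, 3))
  expect_equal(r4$objective, 3)
})

test_that("the simplex matches brute-force vertex enumeration on 100 seeded networks", {
  agree <- 0L
  for (seed in 1:100) {
    net <- random_small_network(seed, n = 6, m = 3)
    ours <- lp_solve(net$obj, net$A, rep(0, nrow(net$A)), net$lb, net$ub)
    ref <- brute_force_lp(net$obj, net$A, net$lb, net$ub)
    if (!ref$feasible) {
      expect_equal(ours$status, "infeasible")
    } else {
      expect_equal(ours$status, "optimal")
      expect_equal(ours$objective, ref$objective,
                   tolerance = 1e-6 * (1 + abs(ref$objective)))
    }
    agree <- agree + 1L
  }
  expect_equal(agree, 100L)
})

test_that("larger random instances satisfy their own optimality certificates", {
  # feasibility and constraint satisfaction on 8-reaction instances
  for (seed in 101:120) {
    net <- random_small_network(seed, n = 8, m = 4)
    r <- lp_solve(net$obj, net$A, rep(0, 4), net$lb, net$ub)
    ref <- brute_force_lp(net$obj, net$A, net$lb, net$ub)
    if (r$status == "optimal") {
      expect_true(ref$feasible)
      expect_lt(max(abs(net$A %*% r$solution)), 1e-8)
      expect_true(all(r$solution >= net$lb - 1e-8))
      expect_true(all(r$solution <= net$ub + 1e-8))
      expect_equal(r$objective, ref$objective,
                   tolerance = 1e-6 * (1 + abs(ref$objective)))
    } else {
      expect_false(ref$feasible)
    }
  }
})
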