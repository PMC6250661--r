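test_that("solve_lp solves small known LPs exactly", {
  # max x1 + x2 s.t. x1 + x2 - s = 0 (s is the "uptake"), s <= 4
  S <- matrix(c(1, 1, -1), 1, 3)
  sol <- solve_lp(S, c(1, 1, 0), lb = c(0, 0, 0), ub = c(Inf, Inf, 4),
                  direction = "max")
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 4)

  # min x1 + 2 x2 s.t. x1 + x2 = 3, both in [0, 2] -> x = (2, 1), obj 4
  S <- matrix(c(1, 1), 1, 2)
  sol <- solve_lp(S, c(1, 2), lb = c(0, 0), ub = c(2, 2), b = 3,
                  direction = "min")
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 4)
  expect_equal(unname(sol$x), c(2, 1))
})

test_that("solve_lp handles negative and infinite bounds", {
  # max x2 s.t. x1 + x2 = 0, x1 in [-5, 5]: x2 free -> optimum 5
  S <- matrix(c(1, 1), 1, 2)
  sol <- solve_lp(S, c(0, 1), lb = c(-5, -Inf), ub = c(5, Inf),
                  direction = "max")
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  expect_equal(unname(sol$x), c(-5, 5))
})

test_that("solve_lp reports infeasible and unbounded problems", {
  S <- matrix(c(1, 1), 1, 2)
  sol <- solve_lp(S, c(1, 0), lb = c(2, 2), ub = c(3, 3), b = 1,
                  direction = "min")
  expect_identical(sol$status, "infeasible")

  S <- matrix(0, 1, 1)
  sol <- solve_lp(S, 1, lb = 0, ub = Inf, direction = "max")
  expect_identical(sol$status, "unbounded")
})

test_that("solve_lp rejects inconsistent box bounds", {
  expect_error(solve_lp(matrix(1, 1, 1), 1, lb = 2, ub = 1), "lb > ub")
})

test_that("solve_lp agrees with pracma::linprog on seeded random LPs", {
  skip_if_not_installed("pracma")
  for (seed in 1:25) {
    lp <- random_lp(seed)
    n <- lp$n
    u <- rep(5, n)
    # min obj'x s.t. A x = b, 0 <= x <= u (box upper bounds passed to
    # pracma as inequality rows, since its lb/ub path is unreliable)
    obj <- abs(lp$obj) + 0.1
    mine <- solve_lp(lp$A, obj, lb = rep(0, n), ub = u, b = lp$b,
                     direction = "min")
    theirs <- tryCatch(
      pracma::linprog(obj, A = diag(n), b = u, Aeq = lp$A, beq = lp$b,
                      maxiter = 100),
      error = function(e) NULL)
    expect_identical(mine$status, "optimal")
    if (!is.null(theirs) && isTRUE(theirs$errno == 0)) {
      expect_equal(mine$objective, theirs$fval, tolerance = 1e-7)
      # primal feasibility of our solution
      expect_equal(as.numeric(lp$A %*% mine$x), lp$b, tolerance = 1e-7)
      expect_true(all(mine$x >= -1e-9) && all(mine$x <= u + 1e-9))
    }
  }
})

test_that("max and min of the same LP bracket every feasible value", {
  for (seed in 26:30) {
    lp <- random_lp(seed)
    n <- lp$n
    u <- rep(3, n)
    lo <- solve_lp(lp$A, lp$obj, rep(0, n), u, b = lp$b, direction = "min")
    hi <- solve_lp(lp$A, lp$obj, rep(0, n), u, b = lp$b, direction = "max")
    expect_identical(lo$status, "optimal")
    expect_identical(hi$status, "optimal")
    expect_lte(lo$objective, hi$objective + 1e-9)
    # the construction point x0 = runif(n, 0, 2) is feasible and interior
    set.seed(seed)
    invisible(matrix(stats::rnorm(4 * n), 4, n))
    x0 <- stats::runif(n, 0, 2)
    val <- sum(lp$obj * x0)
    expect_lte(lo$objective, val + 1e-7)
    expect_gte(hi$objective, val - 1e-7)
  }
})
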