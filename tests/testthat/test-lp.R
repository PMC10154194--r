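test_that("the simplex solves small LPs with known optima", {
  ## max x + y s.t. x + 2y <= 4, 3x + y <= 6  -> x = 8/5, y = 6/5
  r <- simplex_lp(c(1, 1), rbind(c(1, 2), c(3, 1)), c("<=", "<="), c(4, 6),
                  maximize = TRUE)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 14 / 5)
  expect_equal(r$x, c(8 / 5, 6 / 5))

  ## min 2x + 3y s.t. x + y >= 10, x <= 4 -> x = 4, y = 6
  r2 <- simplex_lp(c(2, 3), rbind(c(1, 1), c(1, 0)), c(">=", "<="), c(10, 4))
  expect_equal(r2$objective, 26)

  ## equality constraints
  r3 <- simplex_lp(c(1, 2), rbind(c(1, 1)), "=", 5)
  expect_equal(r3$objective, 5)
  expect_equal(r3$x, c(5, 0))
})

test_that("infeasible and unbounded problems are recognized", {
  inf <- simplex_lp(c(1), rbind(1, 1), c("<=", ">="), c(1, 2))
  expect_equal(inf$status, "infeasible")
  unb <- simplex_lp(c(-1), matrix(1, 1, 1), ">=", 0)
  expect_equal(unb$status, "unbounded")
})

test_that("solves are deterministic and exact at degenerate vertices", {
  set.seed(31)
  for (k in 1:5) {
    n <- 6; m <- 8
    A <- matrix(rnorm(m * n), m, n)
    x0 <- runif(n)
    b <- as.numeric(A %*% x0) + runif(m, 0, 0.5)
    obj <- rnorm(n)
    r1 <- simplex_lp(obj, rbind(A, diag(n)), rep("<=", m + n), c(b, rep(5, n)))
    r2 <- simplex_lp(obj, rbind(A, diag(n)), rep("<=", m + n), c(b, rep(5, n)))
    expect_identical(r1$x, r2$x)
    expect_identical(r1$objective, r2$objective)
  }
  ## heavily degenerate: many redundant rows through the same vertex
  A <- rbind(c(1, 1), c(2, 2), c(1, 1), c(1, 0), c(0, 1))
  r <- simplex_lp(c(-1, -1), A, rep("<=", 5), c(2, 4, 2, 2, 2))
  expect_equal(r$objective, -2)
})

test_that("badly scaled problems are solved to full precision", {
  ## coefficients spanning ten orders of magnitude
  A <- rbind(c(1e6, 2e-3), c(3e-4, 5e6))
  b <- c(4e6, 1e7)
  r <- simplex_lp(c(1e6, 1e6), A, c(">=", ">="), b)
  ## solve the 2x2 system directly as the oracle
  xref <- solve(A, b)
  expect_equal(r$x, unname(xref), tolerance = 1e-9)
})
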