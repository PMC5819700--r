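test_that("single-input single-output CCR reduces to a ratio rule", {
  d <- data.frame(unit = c("A", "B"), x = c(2, 4), y = c(4, 4))
  r <- dea_efficiency(d, "x", "y")
  expect_equal(r$theta, c(1, 0.5))
  # general analytic rule on a random instance
  set.seed(21)
  d2 <- data.frame(unit = letters[1:7],
                   x = runif(7, 1, 10), y = runif(7, 1, 10))
  ratio <- (d2$y / d2$x) / max(d2$y / d2$x)
  r2 <- dea_efficiency(d2, "x", "y")
  expect_equal(r2$theta, ratio, tolerance = 1e-9)
})

test_that("a single DMU evaluated against itself is efficient", {
  r <- dea_solve(matrix(c(3, 5), 1), matrix(7, 1), eval = 1)
  expect_equal(r$theta, 1)
  expect_equal(unname(r$slack_input), c(0, 0))
  expect_equal(r$k, 1)
})

test_that("CCR efficiency and slack sums match basis enumeration", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:5, 1); m <- sample(1:3, 1); s <- sample(1:2, 1)
    inst <- rand_dea_instance(n, m, s)
    for (j in seq_len(n)) {
      want <- bf_ccr(inst$X, inst$Y, j)
      got <- dea_solve(inst$X, inst$Y, eval = j)
      expect_equal(got$theta, want$theta, tolerance = 1e-6)
      expect_equal(norm_slacksum(got, inst$X, inst$Y), want$slacksum,
                   tolerance = 1e-6)
    }
  }
})

test_that("efficiency classification follows the three-way rule", {
  expect_equal(classify_efficiency(1, 0), "efficient")
  expect_equal(classify_efficiency(1, 0.3), "weakly_efficient")
  expect_equal(classify_efficiency(0.51, 0), "non_efficient")
  # constructed weakly efficient unit: same ray position, extra input
  # in a dimension where another unit does strictly better
  d <- data.frame(unit = c("A", "B"),
                  x1 = c(2, 2), x2 = c(1, 3), y = c(4, 4))
  r <- dea_efficiency(d, c("x1", "x2"), "y")
  expect_equal(r$theta[2], 1)
  expect_gt(r$slack_in_x2[2], 0)
  expect_equal(r$efficiency_class, c("efficient", "weakly_efficient"))
})

test_that("frontier projection lands on the frontier", {
  expect_equal(project_to_frontier(0.5, 4, 1, 0, 0)$ideal_input, 2)
  expect_error(project_to_frontier(0.1, 1, 1, 0.5, 0), "degenerate")
  set.seed(41)
  for (i in 1:10) {
    inst <- rand_dea_instance(5, 2, 2)
    for (j in 1:5) {
      r <- dea_solve(inst$X, inst$Y, eval = j)
      r2 <- dea_solve(inst$X, inst$Y,
                      x0 = r$ideal_input, y0 = r$ideal_output)
      expect_equal(r2$theta, 1, tolerance = 1e-7)
      expect_equal(norm_slacksum(r2, inst$X, inst$Y), 0,
                   tolerance = 1e-7)
      # projecting a projected point changes nothing
      r3 <- dea_solve(inst$X, inst$Y,
                      x0 = r2$theta * r$ideal_input - r2$slack_input,
                      y0 = r$ideal_output + r2$slack_output)
      expect_equal(r3$theta, 1, tolerance = 1e-7)
    }
  }
})

test_that("returns-to-scale classification follows the k rule", {
  expect_equal(returns_to_scale(c(1, 0.73, 1.10)),
               c("invariant", "increasing", "decreasing"))
  expect_equal(returns_to_scale(1 + 1e-9), "invariant")
})

test_that("BCC dominates CCR and boundary units are VRS-efficient", {
  set.seed(51)
  for (i in 1:8) {
    inst <- rand_dea_instance(6, 2, 2)
    for (j in 1:6) {
      crs <- dea_solve(inst$X, inst$Y, eval = j, rts = "crs")
      vrs <- dea_solve(inst$X, inst$Y, eval = j, rts = "vrs")
      expect_gte(vrs$theta, crs$theta - 1e-8)
      expect_lte(scale_efficiency(crs$theta, vrs$theta), 1)
    }
  }
  # the DMU with the smallest single input is VRS-efficient
  d <- data.frame(unit = 1:5, x = c(9, 3, 5, 7, 4), y = c(1, 1, 2, 3, 1))
  v <- dea_efficiency(d, "x", "y", returns = "vrs")
  expect_equal(v$theta[2], 1)
  # identical DMUs are all VRS-efficient
  d2 <- data.frame(unit = 1:4, x = 2, y = 3)
  expect_equal(dea_efficiency(d2, "x", "y", returns = "vrs")$theta,
               rep(1, 4))
  expect_equal(scale_efficiency(0.5, 0.8), 0.625)
  expect_error(scale_efficiency(0.9, 0.8), "inconsistent")
})

test_that("dominated units never score above their dominators", {
  set.seed(61)
  for (i in 1:10) {
    inst <- rand_dea_instance(5, 2, 2)
    # plant a dominated copy of unit 1
    X <- rbind(inst$X, inst$X[1, ] * 1.2)
    Y <- rbind(inst$Y, inst$Y[1, ] * 0.9)
    d <- data.frame(unit = 1:6, X, Y)
    colnames(d) <- c("unit", "x1", "x2", "y1", "y2")
    r <- dea_efficiency(d, c("x1", "x2"), c("y1", "y2"))
    expect_gte(r$theta[1], r$theta[6])
    expect_true(any(abs(r$theta - 1) < 1e-8))
  }
})

test_that("efficiency is invariant to the units of measurement", {
  set.seed(71)
  inst <- rand_dea_instance(6, 3, 2)
  d <- data.frame(unit = 1:6, inst$X, inst$Y)
  colnames(d) <- c("unit", paste0("x", 1:3), paste0("y", 1:2))
  base <- dea_efficiency(d, paste0("x", 1:3), paste0("y", 1:2))
  for (col in c("x2", "y1")) {
    for (c0 in c(0.01, 100)) {
      d2 <- d
      d2[[col]] <- d2[[col]] * c0
      r <- dea_efficiency(d2, paste0("x", 1:3), paste0("y", 1:2))
      expect_equal(r$theta, base$theta, tolerance = 1e-8)
      expect_equal(r$efficiency_class, base$efficiency_class)
      expect_equal(r$k, base$k, tolerance = 1e-8)
    }
  }
})

test_that("positive data are required", {
  d <- data.frame(unit = 1:2, x = c(1, -1), y = c(1, 1))
  expect_error(dea_efficiency(d, "x", "y"), "positive")
})
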