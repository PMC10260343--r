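test_that("BOIN boundaries match the closed form and bracket the target", {
  b <- boin_boundaries(0.30, 0.18, 0.42)
  expect_equal(b$lambda_e, 0.2364, tolerance = 1e-3)
  expect_equal(b$lambda_d, 0.3586, tolerance = 1e-3)
  b2 <- boin_boundaries(0.25, 0.15, 0.35)
  le <- log((1 - 0.15) / (1 - 0.25)) /
    log(0.25 * (1 - 0.15) / (0.15 * (1 - 0.25)))
  ld <- log((1 - 0.25) / (1 - 0.35)) /
    log(0.35 * (1 - 0.25) / (0.25 * (1 - 0.35)))
  expect_equal(b2$lambda_e, le, tolerance = 1e-10)
  expect_equal(b2$lambda_d, ld, tolerance = 1e-10)
  for (phi in c(0.2, 0.25, 0.3, 0.35)) {
    bb <- boin_boundaries(phi)
    expect_true(bb$lambda_e < phi && phi < bb$lambda_d)
  }
  expect_error(boin_boundaries(0.3, 0.4, 0.5), "phi")
})

test_that("BOIN moves with the observed rate and respects eliminations", {
  b <- boin_boundaries(0.30, 0.18, 0.42)
  rs <- row_state(7); rs$current <- 3L
  rs$n[3] <- 10L; rs$x[3] <- 2L
  expect_identical(boin_next(rs, b), 4L)    # 0.20 < lambda_e
  rs$x[3] <- 5L
  expect_identical(boin_next(rs, b), 2L)    # 0.50 > lambda_d
  rs$x[3] <- 3L
  expect_identical(boin_next(rs, b), 3L)    # in the interval
  rs$x[3] <- 2L; rs$eliminated[4] <- TRUE
  expect_identical(boin_next(rs, b), 3L)    # never assign an eliminated level
  rs$current <- 1L; rs$n[1] <- 2L; rs$x[1] <- 2L
  expect_identical(boin_next(rs, b), 1L)    # de-escalation floored at 1
})

test_that("BOIN decisions depend only on the current level's counts", {
  b <- boin_boundaries(0.30)
  r1 <- row_state(7); r1$current <- 2L; r1$n[2] <- 6L; r1$x[2] <- 1L
  r2 <- r1; r2$n[5] <- 12L; r2$x[5] <- 9L   # unrelated history elsewhere
  expect_identical(boin_next(r1, b), boin_next(r2, b))
})

test_that("BOIN elimination uses the Beta(1,1) posterior tail", {
  rs <- row_state(7); rs$n[2] <- 3L; rs$x[2] <- 3L; rs$current <- 2L
  # Pr(p > 0.3 | Beta(4, 1)) = 1 - 0.3^4 = 0.9919
  expect_equal(1 - pbeta(0.3, 4, 1), 1 - 0.3^4)
  out <- boin_eliminate(rs, 0.30)
  expect_true(all(out$eliminated[2:7]))
  expect_false(out$eliminated[1])
  expect_false(out$stopped_safety)
  rs0 <- row_state(7); rs0$n[1] <- 3L; rs0$x[1] <- 0L
  expect_false(any(boin_eliminate(rs0, 0.30)$eliminated))
  rs2 <- row_state(7); rs2$n[1] <- 2L; rs2$x[1] <- 2L
  expect_false(any(boin_eliminate(rs2, 0.30)$eliminated))  # needs n >= 3
  rs1 <- row_state(7); rs1$n[1] <- 3L; rs1$x[1] <- 3L
  expect_true(boin_eliminate(rs1, 0.30)$stopped_safety)
})

test_that("PAVA reproduces simple pooled means and leaves monotone input", {
  expect_equal(pava_isotonic(c(0.1, 0.2, 0.5)), c(0.1, 0.2, 0.5))
  expect_equal(pava_isotonic(c(0.5, 0.1), c(1, 1)), c(0.3, 0.3))
  expect_error(pava_isotonic(c(1, 2), c(1, -1)), "weights")
})

test_that("PAVA matches the brute-force level-set oracle", {
  set.seed(601)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    v <- runif(k)
    w <- runif(k, 0.2, 3)
    expect_equal(pava_isotonic(v, w), oracle_pava(v, w), tolerance = 1e-8)
  }
})

test_that("BOIN MTD selection follows the adjusted estimates", {
  rs <- row_state(7); rs$stopped_safety <- TRUE
  expect_identical(boin_select_mtd(rs, 0.30), NA_integer_)
  one <- row_state(7); one$n[3] <- 9L; one$x[3] <- 3L
  expect_identical(boin_select_mtd(one, 0.30), 3L)
  # hand-computed three-level case
  rs3 <- row_state(7)
  rs3$n[1:3] <- c(3L, 9L, 6L); rs3$x[1:3] <- c(0L, 2L, 3L)
  a <- rs3$x[1:3] + 0.05; b <- rs3$n[1:3] - rs3$x[1:3] + 0.05
  pm <- a / (a + b)
  w <- (a + b)^2 * (a + b + 1) / (a * b)
  adj <- oracle_pava(pm, w)
  want <- which.min(abs(adj - 0.30))
  expect_identical(boin_select_mtd(rs3, 0.30), want)
})

test_that("3+3 cohort decisions follow the rule table", {
  rs <- row_state(7); rs$current <- 2L
  rs$n[2] <- 3L; rs$x[2] <- 0L
  expect_identical(three_plus_three_next(rs), "escalate")
  rs$x[2] <- 1L
  expect_identical(three_plus_three_next(rs), "expand")
  rs$n[2] <- 6L; rs$x[2] <- 1L
  expect_identical(three_plus_three_next(rs), "escalate")
  rs$x[2] <- 2L
  expect_identical(three_plus_three_next(rs), "stop")
  rs$n[2] <- 3L; rs$x[2] <- 3L
  expect_identical(three_plus_three_next(rs), "stop")
  rs$n[2] <- 4L
  expect_error(three_plus_three_next(rs), "cohort")
})

test_that("3+3 MTD is the level below the stop, top level if clean", {
  rs <- row_state(7); rs$stop_level <- 3L
  expect_identical(three_plus_three_mtd(rs), 2L)
  rs$stop_level <- 1L
  expect_identical(three_plus_three_mtd(rs), NA_integer_)
  rs$stop_level <- NA_integer_
  expect_identical(three_plus_three_mtd(rs), 7L)
})

test_that("reversal is row 2 strictly above row 1, both defined", {
  expect_true(reversal(5, 6))
  expect_false(reversal(6, 5))
  expect_false(reversal(5, 5))
  expect_false(reversal(NA, 4))
  expect_false(reversal(4, NA))
})

test_that("3+3 sample sizes are multiples of 3 and bounded by 6 per level", {
  d <- three_plus_three_design()
  sc <- illustration_scenario()
  for (i in 1:50) {
    tr <- run_trial(d, sc, seed = 700 + i)
    expect_identical(tr$n %% 3L, 0L)
    expect_true(all(tr$alloc <= 6L))
    expect_lte(tr$n, 2L * 6L * 7L)
  }
})

test_that("a uniformly toxic scenario stops BOIN rows at level 1", {
  d <- parallel_boin_design()
  hot <- tox_scenario(rbind(rep(0.85, 7), rep(0.9, 7)), target = 0.30,
                      max_shift = 1)
  tr <- run_trial(d, hot, seed = 99)
  expect_true(all(tr$stopped_by_row))
  expect_identical(tr$mtd, c(NA_integer_, NA_integer_))
  expect_lt(tr$n, 2L * d$n_per_row)
})
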