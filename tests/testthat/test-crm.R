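design <- shift_crm_design()

test_that("power-model likelihood reduces to the Bernoulli terms at a = 0", {
  g <- dose_grid(2)
  m <- structure(list(shift = 0L,
                      skeleton = rbind(c(0.5, 0.6), c(0.5, 0.6))),
                 class = "working_model")
  st0 <- trial_state(data.frame(patient = 1, row = 1, level = 1, dlt = 0), g)
  st1 <- trial_state(data.frame(patient = 1, row = 1, level = 1, dlt = 1), g)
  expect_equal(power_model_loglik(m, st0, 0), log(0.5))
  expect_equal(power_model_loglik(m, st1, 0), log(0.5))
})

test_that("likelihood matches an independently coded evaluator", {
  st <- interim_state()
  for (m in design$models) {
    p <- m$skeleton[cbind(st$records$row, st$records$level)]
    for (a in seq(-3, 3, by = 0.25)) {
      expect_equal(power_model_loglik(m, st, a),
                   oracle_loglik(p, st$records$dlt, a), tolerance = 1e-12)
    }
  }
})

test_that("fitting requires heterogeneous data", {
  g <- dose_grid(7)
  st <- trial_state(data.frame(patient = 1:3, row = 1, level = 1:3, dlt = 0), g)
  expect_identical(st$stage, "initial")
  expect_error(fit_working_model(design$models[[1]], st), "heterogeneity")
})

test_that("the MLE matches a dense brute-force grid search", {
  g <- dose_grid(7)
  base <- design$base
  # one DLT where the skeleton is 0.30, one non-DLT where it is ~0.12
  st <- trial_state(data.frame(patient = 1:2, row = 1, level = c(4, 2),
                               dlt = c(1, 0)), g)
  fit <- fit_working_model(design$models[[1]], st)
  lam_grid <- exp(seq(log(1e-4), log(1e4), length.out = 1e6))
  p <- design$models[[1]]$skeleton[1, c(4, 2)]
  ll <- log(p[1]^lam_grid) + log(1 - p[2]^lam_grid)
  lam_best <- lam_grid[which.max(ll)]
  expect_equal(fit$dlt_estimates,
               design$models[[1]]$skeleton^lam_best, tolerance = 1e-4)
})

test_that("the optimized likelihood dominates random parameter draws", {
  set.seed(501)
  st <- interim_state()
  fit <- fit_working_model(design$models[[2]], st)
  for (a in runif(100, -10, 10)) {
    expect_gte(fit$loglik,
               power_model_loglik(design$models[[2]], st, a) - 1e-9)
  }
})

test_that("crm_fit methods expose the estimate, likelihood, and predictions", {
  st <- interim_state()
  fit <- fit_working_model(design$models[[2]], st)
  expect_named(coef(fit), "a_hat")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(predict(fit), fit$model$skeleton^exp(fit$a_hat))
  expect_true(all(is.finite(fit$loglik)))
})

test_that("model selection takes the largest likelihood, ties at random", {
  fits <- list(structure(list(loglik = -3.0), class = "crm_fit"),
               structure(list(loglik = -2.5), class = "crm_fit"))
  expect_identical(select_working_model(fits), 2L)
  tied <- list(structure(list(loglik = -2.5), class = "crm_fit"),
               structure(list(loglik = -2.5), class = "crm_fit"))
  set.seed(502)
  picks <- replicate(10000, select_working_model(tied))
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)
})

test_that("interim data tie the two models and recommend (5, 4)", {
  st <- interim_state()
  fits <- lapply(design$models, fit_working_model, state = st)
  # all interim data sit in row 1, where the two skeletons coincide
  expect_identical(fits[[1]]$loglik, fits[[2]]$loglik)
  expect_identical(unname(row_recommendations(fits[[1]], 0.30)), c(5L, 5L))
  expect_identical(unname(row_recommendations(fits[[2]], 0.30)), c(5L, 4L))
  # the one-level-shift model's recommendation pair differs by its shift
  rec <- row_recommendations(fits[[2]], 0.30)
  expect_identical(unname(rec[2] - rec[1]), design$models[[2]]$shift)
})

test_that("row recommendations pick closest-to-target, ties lower", {
  f <- structure(list(dlt_estimates = rbind(c(0.10, 0.28, 0.50),
                                            c(0.25, 0.35, 0.60))),
                 class = "crm_fit")
  expect_identical(unname(row_recommendations(f, 0.30)), c(2L, 1L))
})

test_that("updating with row-1 data moves the fitted row-2 probabilities", {
  st <- interim_state()  # every patient in row 1
  fit <- fit_working_model(design$models[[2]], st)
  expect_false(isTRUE(all.equal(fit$dlt_estimates[2, ],
                                fit$model$skeleton[2, ])))
})

test_that("initial escalation walks row 1 then row 2 in cohorts of one", {
  g <- dose_grid(7)
  st <- trial_state(NULL, g)
  expect_identical(initial_escalation_next(st)[c("row", "level")],
                   list(row = 1L, level = 1L))
  st3 <- trial_state(data.frame(patient = 1:3, row = 1, level = 1:3, dlt = 0), g)
  expect_identical(initial_escalation_next(st3)$level, 4L)
  st7 <- trial_state(data.frame(patient = 1:7, row = 1, level = 1:7, dlt = 0), g)
  nxt <- initial_escalation_next(st7)
  expect_identical(c(nxt$row, nxt$level), c(2L, 1L))
  # a first-patient DLT repeats the lowest combination
  stD <- trial_state(data.frame(patient = 1, row = 1, level = 1, dlt = 1), g)
  rep1 <- initial_escalation_next(stD)
  expect_identical(c(rep1$row, rep1$level), c(1L, 1L))
  expect_error(initial_escalation_next(interim_state()), "stage")
})

test_that("stage flips to modeling exactly at first heterogeneity", {
  g <- dose_grid(7)
  recs <- data.frame(patient = 1:5, row = 1, level = 1:5,
                     dlt = c(0, 0, 0, 0, 1))
  for (k in 1:5) {
    st <- trial_state(recs[1:k, ], g)
    expect_identical(st$stage, if (k < 5) "initial" else "modeling")
  }
  # all-DLT data are still homogeneous
  stD <- trial_state(data.frame(patient = 1:2, row = 1, level = 1, dlt = 1), g)
  expect_identical(stD$stage, "initial")
})

test_that("modeling-stage assignments go to a recommended row at 1:1", {
  set.seed(503)
  st <- interim_state()
  draws <- replicate(400, {
    nxt <- next_assignment(st, design)
    c(nxt$row, nxt$level)
  })
  # both tied models agree on row 1; row 2 depends on which model the
  # random tie-break selected (level 4 under shift -1, 5 under shift 0)
  expect_true(all(draws[2, draws[1, ] == 1] == 5L))
  expect_true(all(draws[2, draws[1, ] == 2] %in% c(4L, 5L)))
  expect_setequal(unique(draws[2, draws[1, ] == 2]), c(4L, 5L))
  full <- trial_state(data.frame(patient = 1:39, row = 1,
                                 level = rep(1:5, length.out = 39),
                                 dlt = rep(c(0, 1), length.out = 39)),
                      dose_grid(7))
  expect_null(next_assignment(full, design))
})

test_that("safety rule uses the exact lower binomial bound at (1,1)", {
  g <- dose_grid(7)
  expect_false(safety_stop(trial_state(NULL, g), design))
  st33 <- trial_state(data.frame(patient = 1:3, row = 1, level = 1, dlt = 1), g)
  # lower 90% bound for 3/3 is 0.1^(1/3) ~ 0.464 > 0.30
  expect_equal(qbeta(0.10, 3, 1), 0.1^(1/3))
  expect_true(safety_stop(st33, design))
  st16 <- trial_state(data.frame(patient = 1:6, row = 1, level = 1,
                                 dlt = c(1, 0, 0, 0, 0, 0)), g)
  expect_false(safety_stop(st16, design))
})

test_that("final selection returns no MTD on stopped or inestimable trials", {
  g <- dose_grid(7)
  st <- interim_state()
  expect_identical(final_selection(st, design, stopped = TRUE),
                   c(NA_integer_, NA_integer_))
  clean <- trial_state(data.frame(patient = 1:5, row = 1, level = 1:5, dlt = 0), g)
  expect_identical(final_selection(clean, design),
                   c(NA_integer_, NA_integer_))
  set.seed(504)
  sel <- final_selection(st, design)
  expect_true(sel[2] <= sel[1])
})
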