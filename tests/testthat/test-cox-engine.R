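test_that("the fitted coefficient matches brute-force partial-likelihood maximization", {
  # 3 subjects, x = (1,0,1), event times 1,2,3, all deaths
  iv <- simple_intervals(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1))
  fit <- fit_portfolio_cox(iv, model_spec(list("x")))
  oracle <- brute_force_cox(cbind(c(1, 0, 1)), c(1, 2, 3), c(1, 1, 1))
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  expect_equal(unname(fit$beta), -0.3466, tolerance = 1e-4)
})

test_that("fits match the brute-force oracle on random small fixtures", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    p <- sample(1:2, 1)
    X <- matrix(round(rnorm(n * p), 2), n, p)
    time <- seq_len(n) # distinct times: no ties
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1
    iv <- simple_intervals(X[, 1], time, event)
    model <- model_spec(list("x"))
    if (p == 2) {
      iv$z <- X[, 2]
      attr(iv, "diseases") <- c("x", "z")
      model <- model_spec(list("x", "z"))
    }
    fit <- fit_portfolio_cox(iv, model)
    if (!fit$converged) next # monotone likelihood: flagged, not compared
    oracle <- brute_force_cox(X, time, event)
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-4)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("null log partial likelihood counts risk-set sizes", {
  iv <- simple_intervals(c(1, 0, 1, 0), c(1, 2, 3, 4), c(1, 1, 1, 1))
  fit <- fit_portfolio_cox(iv, model_spec(list("x")))
  expect_equal(fit$loglik_null, -(log(4) + log(3) + log(2) + log(1)))
})

test_that("aliased columns are excluded and reported, not silently dropped", {
  iv <- simple_intervals(c(1, 1, 1, 1), c(1, 2, 3, 4), c(1, 1, 0, 1),
                         covname = "const")
  iv$x <- c(1, 0, 1, 0)
  attr(iv, "diseases") <- c("const", "x")
  fit <- fit_portfolio_cox(iv, model_spec(list("const", "x")))
  expect_identical(fit$aliased, "const")
  expect_identical(names(fit$beta), "x")
})

test_that("shifting a covariate by a constant leaves the estimate unchanged", {
  set.seed(33)
  iv <- simple_intervals(rbinom(60, 1, 0.5), rexp(60), rbinom(60, 1, 0.8))
  fit1 <- fit_portfolio_cox(iv, model_spec(list("x")))
  iv2 <- iv
  iv2$x <- iv2$x + 7
  fit2 <- fit_portfolio_cox(iv2, model_spec(list("x")))
  expect_equal(unname(fit1$beta), unname(fit2$beta), tolerance = 1e-8)
})

test_that("likelihood-ratio tests behave on nested models", {
  tc <- planted_config(diseases = c("A", "B"), beta = c(A = 0.6))
  cohort <- simulate_cohort(tc, 500, seed = 14)
  iv <- build_intervals(cohort$subjects, cohort$events)$intervals
  mA <- model_spec(list("A"))
  mAB <- model_spec(list("A", "B"))
  fA <- fit_portfolio_cox(iv, mA)
  fAB <- fit_portfolio_cox(iv, mAB)
  same <- lrt(fA, fA)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  out <- lrt(fA, fAB)
  expect_gte(out$statistic, 0)
  expect_identical(out$df, 1L)
  expect_error(lrt(fAB, fA), "not nested")

  # a disease-by-education block adds 5 design columns
  mEd <- close_hierarchy(list(c("A", "education")))
  mEd <- model_spec(c(mEd$terms, mAB$terms))
  fEd <- fit_portfolio_cox(iv, mEd)
  base <- model_spec(c(mAB$terms, list(new_term("education"))))
  fBase <- fit_portfolio_cox(iv, base)
  expect_identical(lrt(fBase, fEd)$df, 5L)
})

test_that("schoenfeld residuals follow the risk-weighted-mean formula", {
  iv <- simple_intervals(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1))
  at_zero <- fit_portfolio_cox(iv, model_spec(list("x")), init = 0,
                               max_iter = 0)
  r0 <- schoenfeld_residuals(at_zero)
  # first event: observed 1 minus risk-set mean 2/3
  expect_equal(unname(r0[1, "x"]), 1 - 2 / 3, tolerance = 1e-10)
  expect_equal(unname(r0[2, "x"]), 0 - 1 / 2, tolerance = 1e-10)

  # at the MLE the residuals solve the score equation: they sum to ~0
  fit <- fit_portfolio_cox(iv, model_spec(list("x")))
  expect_lt(abs(sum(schoenfeld_residuals(fit))), 1e-6)
})

test_that("the PH diagnostic reports one test per design column", {
  tc <- planted_config(diseases = c("A", "B"), beta = c(A = 0.5))
  cohort <- simulate_cohort(tc, 400, seed = 15)
  iv <- build_intervals(cohort$subjects, cohort$events)$intervals
  fit <- build_ome(iv)
  tb <- schoenfeld_check(fit)
  expect_setequal(setdiff(tb$column, "GLOBAL"), names(fit$beta))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
})

test_that("PH-test p-values are roughly uniform when hazards are proportional", {
  ps <- numeric(80)
  for (k in seq_along(ps)) {
    tc <- planted_config(diseases = "A", beta = c(A = 0.5), onset = 0.3,
                         pre = 0.2)
    cohort <- simulate_cohort(tc, 400, seed = 300 + k)
    iv <- build_intervals(cohort$subjects, cohort$events,
                          diseases = "A")$intervals
    fit <- fit_portfolio_cox(iv, model_spec(list("A")))
    ps[k] <- schoenfeld_check(fit)$p[1]
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("breslow baseline increments are d/n at beta = 0 and cumulate monotonically", {
  iv <- simple_intervals(c(1, 0, 1, 0, 1), 1:5, c(1, 0, 1, 1, 0))
  fit <- fit_portfolio_cox(iv, model_spec())
  bh <- breslow_baseline(fit)
  # one event among n at risk -> increment 1/n
  expect_equal(bh$increments, c(1 / 5, 1 / 3, 1 / 2))
  expect_true(all(diff(cumsum(bh$increments)) >= 0))
})

test_that("divergent coefficients are flagged as non-converged", {
  # perfect separation: the covariate identifies the only death
  iv <- simple_intervals(c(1, 0, 0, 0), c(1, 5, 6, 7), c(1, 0, 0, 0))
  fit <- fit_portfolio_cox(iv, model_spec(list("x")))
  expect_false(fit$converged)
  expect_error(fit_portfolio_cox(iv[iv$event == FALSE, ],
                                 model_spec(list("x"))), "no events")
})
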