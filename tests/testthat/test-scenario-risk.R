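test_that("intercept-only gamma regression recovers the plain mean", {
  reg <- manual_registry(list(
    list(end = 5, diagnoses = c(A = 1)),
    list(end = 5, diagnoses = c(A = 2)),
    list(end = 5, diagnoses = c(A = 3))))
  t1 <- expansion_times(reg$subjects, reg$events, "A",
                        diseases = character(0))
  expect_equal(t1, 2, tolerance = 0.01)
})

test_that("expansion times recover exponential onset means", {
  # A is the only active clock at 0.5/yr: first expansion mean 2 years
  tc <- truth_config(disease_labels = c("A", "B"),
                     onset_rate = c(A = 0.5, B = 0),
                     baseline_hazard = data.frame(time = 0, rate = 0.02),
                     pre_hd_prob = 0, emigration_rate = 0,
                     calendar_window = c(1950, 2030))
  cohort <- simulate_cohort(tc, 5000, seed = 50)
  tA <- expansion_times(cohort$subjects, cohort$events, "A")[1]
  expect_lt(abs(tA - 2) / 2, 0.10)

  # with a competing slower clock the fitted times stay ordered in j
  tc2 <- truth_config(disease_labels = c("A", "B"),
                      onset_rate = c(A = 0.5, B = 0.25),
                      baseline_hazard = data.frame(time = 0, rate = 0.02),
                      pre_hd_prob = 0, emigration_rate = 0,
                      calendar_window = c(1950, 2030))
  cohort2 <- simulate_cohort(tc2, 4000, seed = 52)
  tAB <- expansion_times(cohort2$subjects, cohort2$events, c("A", "B"))
  expect_lt(tAB[1], tAB[2])
})

test_that("scenario specifications validate their trajectories", {
  expect_error(scenario_spec(expansions = data.frame(disease = c("A", "B"),
                                                     time = c(3, 2))),
               "strictly increasing")
  expect_error(scenario_spec(baseline = "A",
                             expansions = data.frame(disease = "A",
                                                     time = 1)),
               "distinct")
})

test_that("risk curves match the closed form under an analytic baseline", {
  # hazard 0.1/yr as increments of 0.01 at a fine grid
  times <- (1:100) / 10
  bh <- structure(list(times = times,
                       increments = rep(0.01, length(times))),
                  class = "baseline_hazard")
  fit <- make_main_fit(c(A = 0.7), c("A", "B"))
  rc <- risk_curve(fit, bh, scenario_spec(), grid = c(0, 2.5, 5, 10))
  expect_equal(rc$risk, 1 - exp(-0.1 * c(0, 2.5, 5, 10)), tolerance = 1e-9)
  expect_equal(rc$risk[1], 0)
  expect_true(all(diff(rc$risk) >= 0))
  expect_true(all(rc$risk >= 0 & rc$risk <= 1))
})

test_that("zero-contrast expansions leave the curve unchanged, positive ones raise it", {
  times <- seq(0.25, 10, by = 0.25)
  bh <- structure(list(times = times,
                       increments = rep(0.02, length(times))),
                  class = "baseline_hazard")
  fit <- make_main_fit(c(A = 0.7, B = 0), c("A", "B"))
  base <- risk_curve(fit, bh, scenario_spec())
  nullx <- risk_curve(fit, bh,
                      scenario_spec(expansions = data.frame(disease = "B",
                                                            time = 3)))
  expect_equal(nullx$risk, base$risk)
  up <- risk_curve(fit, bh,
                   scenario_spec(expansions = data.frame(disease = "A",
                                                         time = 3)))
  expect_true(all(up$risk[up$time <= 3] == base$risk[base$time <= 3]))
  expect_true(all(up$risk[up$time > 3] > base$risk[base$time > 3]))
  expect_error(risk_curve(fit, bh, scenario_spec(
    expansions = data.frame(disease = "ZZ", time = 1))), "not in the fitted")
})

test_that("a stronger portfolio effect can coexist with lower absolute risk", {
  # higher education: larger portfolio log-effect but a strongly negative
  # main effect, so its absolute risk stays below the no-education curve
  model <- model_spec(c(as.list(c("A", coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())),
                        list(c("A", "education"))))
  cm <- coxportfolio:::build_design(model, profile_frame("A"))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta["A"] <- 0.5
  beta["edu_long"] <- -1.2
  beta["A:edu_long"] <- 0.4
  fit <- fake_fit(model, beta, "A")
  eff_none <- portfolio_log_effect(fit, "A", education = "none")$log_hr
  eff_long <- portfolio_log_effect(fit, "A", education = "long")$log_hr
  expect_gt(eff_long, eff_none) # inverse gradient on the log-hazard scale
  times <- seq(0.25, 10, by = 0.25)
  bh <- structure(list(times = times,
                       increments = rep(0.02, length(times))),
                  class = "baseline_hazard")
  sc <- function(edu) scenario_spec(
    expansions = data.frame(disease = "A", time = 2), education = edu)
  r_none <- risk_curve(fit, bh, sc("none"))
  r_long <- risk_curve(fit, bh, sc("long"))
  expect_true(all(r_long$risk[-1] < r_none$risk[-1])) # risk still lower
})

test_that("with no covariate effects the curve equals the Nelson-Aalen transform", {
  tc <- planted_config(diseases = c("A", "B"), beta = numeric(0),
                       onset = 0.1)
  cohort <- simulate_cohort(tc, 800, seed = 51)
  iv <- build_intervals(cohort$subjects, cohort$events)$intervals
  fit <- fit_portfolio_cox(iv, model_spec())
  bh <- breslow_baseline(fit)
  rc <- risk_curve(fit, bh, scenario_spec())
  expect_equal(rc$risk, 1 - exp(-cumsum(bh$increments)), tolerance = 1e-12)
})
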