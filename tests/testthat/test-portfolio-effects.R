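test_that("portfolio effects are exactly additive in a main-effects model", {
  fit <- make_main_fit(c(A = 0.5, B = 0.3), c("A", "B", "C"))
  eff <- portfolio_log_effect(fit, c("A", "B"))
  expect_equal(eff$log_hr, 0.8, tolerance = 1e-12)
  empty <- portfolio_log_effect(fit, character(0))
  expect_identical(empty$log_hr, 0)
  expect_identical(empty$hr, 1)
  expect_error(portfolio_log_effect(fit, "ZZ"), "not in the fitted model")
})

test_that("interaction terms enter the portfolio contrast", {
  model <- model_spec(c(as.list(c("A", "B", "C",
                                  coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())),
                        list(c("A", "B"))))
  cm <- coxportfolio:::build_design(model, profile_frame(c("A", "B", "C")))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta[c("A", "B", "A:B")] <- c(0.5, 0.3, -0.2)
  fit <- fake_fit(model, beta, c("A", "B", "C"))
  eff <- portfolio_log_effect(fit, c("A", "B"))
  expect_equal(eff$log_hr, 0.6, tolerance = 1e-12)
  expect_equal(eff$hr, exp(0.6), tolerance = 1e-12)
})

test_that("aggregation is a weighted mean on the log-hazard scale", {
  # education modifies the effect: log 2 for none, log 4 for short
  model <- model_spec(c(as.list(c("A", coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())),
                        list(c("A", "education"))))
  cm <- coxportfolio:::build_design(model, profile_frame("A"))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta["A"] <- log(2)
  beta["A:edu_short"] <- log(4) - log(2)
  fit <- fake_fit(model, beta, "A")
  weights <- data.frame(portfolio = "A", sex = "male",
                        education = c("none", "short"), count = c(3, 1))
  agg <- aggregate_effects(fit, weights, min_count = 1)
  expect_equal(agg$hr, 2^(3 / 4) * 4^(1 / 4), tolerance = 1e-12)

  # single stratum: aggregation is the identity
  agg1 <- aggregate_effects(fit, weights[1, ], min_count = 1)
  expect_equal(agg1$hr, 2, tolerance = 1e-12)

  # portfolios below the count threshold are excluded
  w9 <- data.frame(portfolio = c("A", ""), sex = "male",
                   education = "none", count = c(9, 50))
  expect_identical(nrow(aggregate_effects(fit, w9, min_count = 10)), 0L)
  expect_identical(nrow(aggregate_effects(fit, w9, min_count = 9)), 1L)
})

test_that("portfolio weights count each distinct state a person ever holds", {
  reg <- manual_registry(list(
    list(end = 6, diagnoses = c(A = -1, B = 2)), # states {A}, {A,B}
    list(end = 5, diagnoses = c(A = 1)),         # states {}, {A}
    list(end = 4, sex = "female")))              # state {}
  w <- portfolio_weights(reg$subjects, reg$events, diseases = c("A", "B"))
  cnt <- function(p, sx) {
    r <- w[w$portfolio == p & w$sex == sx, "count"]
    if (length(r)) sum(r) else 0L
  }
  expect_identical(cnt("A", "male"), 2L)
  expect_identical(cnt("A+B", "male"), 1L)
  expect_identical(cnt("", "male"), 1L)
  expect_identical(cnt("", "female"), 1L)
  # same-day double diagnosis is one state change
  reg2 <- manual_registry(list(list(end = 6, diagnoses = c(A = 2, B = 2))))
  w2 <- portfolio_weights(reg2$subjects, reg2$events, diseases = c("A", "B"))
  expect_false("A" %in% w2$portfolio)
  expect_true("A+B" %in% w2$portfolio)
})

test_that("the additive-to-interaction multiplier is 1 for identical fits", {
  fit <- make_main_fit(c(A = 0.5, B = 0.3), c("A", "B"))
  weights <- data.frame(portfolio = c("A", "B", "A+B"),
                        sex = "male", education = "none",
                        count = c(20, 30, 15))
  m <- multiplier_vs_additive(fit, fit, weights, sizes = 2:3)
  expect_equal(m$multiplier, rep(1, nrow(m)), tolerance = 1e-12)

  # brute-force recomputation of the weighted mean from the detail table
  model <- model_spec(c(as.list(c("A", "B", coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())),
                        list(c("A", "B"))))
  cm <- coxportfolio:::build_design(model, profile_frame(c("A", "B")))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta[c("A", "B", "A:B")] <- c(0.5, 0.3, 0.4)
  fit_all <- fake_fit(model, beta, c("A", "B"))
  m2 <- multiplier_vs_additive(fit_all, fit, weights, sizes = 2:3,
                               min_count = 1)
  det <- attr(m2, "detail")
  for (i in seq_len(nrow(m2))) {
    ws <- det[det$size == m2$size[i] & det$sex == m2$sex[i], ]
    expect_equal(m2$mean_log_diff[i],
                 sum(ws$delta * ws$count) / sum(ws$count),
                 tolerance = 1e-12)
  }
  # the pair with a positive planted interaction is amplified
  expect_equal(m2$multiplier[m2$size == 3], exp(0.4), tolerance = 1e-12)
})

test_that("sex contrasts respond to sex-by-disease interactions", {
  model <- model_spec(c(as.list(c("OP", "ST", coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())),
                        list(c("OP", "sex_female"))))
  cm <- coxportfolio:::build_design(model, profile_frame(c("OP", "ST")))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta["sex_female"] <- -0.3
  beta["OP:sex_female"] <- -0.4
  fit <- fake_fit(model, beta, c("OP", "ST"))
  expect_equal(sex_contrast(fit, character(0))$hr, exp(-0.3),
               tolerance = 1e-12)
  expect_equal(sex_contrast(fit, "ST")$hr, exp(-0.3), tolerance = 1e-12)
  expect_equal(sex_contrast(fit, c("OP", "ST"))$hr, exp(-0.7),
               tolerance = 1e-12)
})

test_that("conditional disease effects shrink under negative interactions", {
  diseases <- c("D", "X1", "X2", "X3")
  inter <- lapply(c("X1", "X2", "X3"), function(x) c("D", x))
  model <- model_spec(c(as.list(c(diseases, coxportfolio:::intrinsic_vars(),
                                  coxportfolio:::poly_vars())), inter))
  cm <- coxportfolio:::build_design(model, profile_frame(diseases))$colmap
  beta <- stats::setNames(rep(0, nrow(cm)), cm$column)
  beta["D"] <- 1.0
  beta[c("D:X1", "D:X2", "D:X3")] <- -0.1
  fit <- fake_fit(model, beta, diseases)
  weights <- data.frame(
    portfolio = c("D", "D+X1", "D+X1+X2", "D+X1+X2+X3", "X1"),
    sex = "male", education = "none", count = c(30, 25, 20, 15, 40))
  tab <- conditional_disease_effect(fit, "D", weights)
  expect_equal(tab$hr, exp(c(1.0, 0.9, 0.8, 0.7)), tolerance = 1e-12)
  # portfolios without the disease contribute nothing (X1 alone ignored)
  expect_equal(sum(tab$total_weight), 90)

  # in a main-effects model the conditional effect is flat in size
  fit0 <- make_main_fit(c(D = 1.0), diseases)
  tab0 <- conditional_disease_effect(fit0, "D", weights)
  expect_equal(tab0$hr, rep(exp(1), nrow(tab0)), tolerance = 1e-12)
})
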