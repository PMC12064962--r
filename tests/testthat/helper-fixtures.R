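# Shared fixtures and independent oracles for the test suite.

# --- hand-built registries -------------------------------------------------

# A registry built from explicit years-since-HD offsets; dates are laid out
# from a fixed HD date so day rounding is exact.
manual_registry <- function(subject_spec) {
  hd <- as.Date("2000-01-01")
  subs <- list(); evs <- list()
  for (i in seq_along(subject_spec)) {
    s <- subject_spec[[i]]
    end_date <- hd + round(s$end * 365.25)
    subs[[i]] <- data.frame(
      person_id = i, sex = s$sex %||% "male",
      birth_date = hd - round((s$age %||% 70) * 365.25),
      education = s$education %||% "none",
      hd_date = hd, end_date = end_date,
      end_status = s$status %||% "death", stringsAsFactors = FALSE)
    ev <- data.frame(person_id = i, label = "HD", date = hd,
                     stringsAsFactors = FALSE)
    if (!is.null(s$diagnoses))
      ev <- rbind(ev, data.frame(
        person_id = i, label = names(s$diagnoses),
        date = hd + round(unname(s$diagnoses) * 365.25),
        stringsAsFactors = FALSE))
    if ((s$status %||% "death") == "death")
      ev <- rbind(ev, data.frame(person_id = i, label = "death",
                                 date = end_date, stringsAsFactors = FALSE))
    evs[[i]] <- ev
  }
  list(subjects = do.call(rbind, subs), events = do.call(rbind, evs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal interval data for direct Cox fitting: single binary covariate x,
# all subjects entering at 0.
simple_intervals <- function(x, time, event, covname = "x") {
  out <- data.frame(person_id = seq_along(x), start = 0, stop = time,
                    event = as.logical(event))
  out[[covname]] <- x
  attr(out, "diseases") <- covname
  attr(out, "centering") <- list(mean_age = 0, mean_calendar = 0)
  out
}

# A fabricated converged fit with prescribed coefficients, for contrast
# arithmetic that depends only on (model, beta, covariance).
fake_fit <- function(model, beta, diseases,
                     covariance = diag(1e-4, length(beta))) {
  cm <- coxportfolio:::build_design(
    model, profile_frame(diseases))$colmap
  stopifnot(setequal(names(beta), cm$column))
  beta <- beta[cm$column]
  dimnames(covariance) <- list(names(beta), names(beta))
  structure(list(beta = beta, se = sqrt(diag(covariance)),
                 covariance = covariance, loglik = 0, loglik_null = 0,
                 n_events = 1L, converged = TRUE, aliased = character(0),
                 model = model, colmap = cm,
                 centering = list(mean_age = 0, mean_calendar = 0),
                 diseases = diseases, intervals = NULL),
            class = "portfolio_cox_fit")
}

# Fabricated main-effects fit with the given nonzero coefficients.
make_main_fit <- function(betas, diseases) {
  model <- model_spec(as.list(c(diseases,
                                coxportfolio:::intrinsic_vars(),
                                coxportfolio:::poly_vars())))
  cm <- coxportfolio:::build_design(model, profile_frame(diseases))$colmap
  full <- stats::setNames(rep(0, nrow(cm)), cm$column)
  full[names(betas)] <- betas
  fake_fit(model, full, diseases)
}

# One all-zero covariate row carrying every base column for the diseases.
profile_frame <- function(diseases) {
  row <- as.list(stats::setNames(rep(0, length(diseases)), diseases))
  row$sex_female <- 0
  for (lev in education_levels()[-1]) row[[paste0("edu_", lev)]] <- 0
  for (v in c("age", "age2", "age3", "cal", "cal2", "cal3")) row[[v]] <- 0
  as.data.frame(row, check.names = FALSE)
}

# --- independent oracles ---------------------------------------------------

# Log partial likelihood for right-censored data without ties, enumerated
# directly from its definition (independent of the fitting engine).
enum_partial_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force maximizer of the enumerated partial likelihood: coarse grid
# then Nelder-Mead refinement.
brute_force_cox <- function(X, time, event) {
  p <- ncol(X)
  obj <- function(b) -enum_partial_loglik(b, X, time, event)
  if (p == 1) {
    grid <- seq(-5, 5, by = 0.05)
    b0 <- grid[which.min(vapply(grid, obj, 0))]
    opt <- stats::optim(b0, obj, method = "Brent", lower = -10, upper = 10)
  } else {
    grid <- as.matrix(expand.grid(rep(list(seq(-3, 3, by = 0.25)), p)))
    b0 <- grid[which.min(apply(grid, 1, obj)), ]
    opt <- stats::optim(b0, obj, control = list(reltol = 1e-14,
                                                maxit = 5000))
  }
  list(beta = opt$par, loglik = -opt$value)
}

# Standard planted-effect cohort used across tests.
planted_config <- function(diseases = c("A", "B"),
                           beta = c(A = 0.7, B = 0.5, "A+B" = -0.3),
                           onset = 0.15, rate = 0.05, pre = 0.25) {
  truth_config(disease_labels = diseases, onset_rate = onset,
               beta_truth = beta,
               baseline_hazard = data.frame(time = 0, rate = rate),
               pre_hd_prob = pre, emigration_rate = 0.005)
}
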