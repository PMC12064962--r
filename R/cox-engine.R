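#' Fit the extended Cox model on counting-process intervals
#'
#' Maximizes the partial likelihood of the proportional-hazards model
#' \eqn{h_i(t) = h_0(t)\exp(\sum_j \beta_j X_{ij}(t))} on start-stop data
#' with the Efron correction for tied event times (day-granularity data
#' make ties common). The design matrix is expanded from the model's term
#' set by [design_columns()]; aliased (constant or linearly dependent)
#' columns are dropped from the estimate and reported in `$aliased`, never
#' silently discarded.
#'
#' @param intervals Interval data.frame from [build_intervals()] (or the
#'   list it returns).
#' @param model A hierarchically closed [model_spec()]. An empty model
#'   fits the null (covariate-free) partial likelihood.
#' @param init Optional initial coefficient vector (warm start).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return A `portfolio_cox_fit`: list with `beta`, `se`, `covariance`,
#'   `loglik` (at optimum), `loglik_null`, `n_events`, `converged`,
#'   `aliased`, `model`, `colmap`, `centering`, and the interval data
#'   needed by downstream estimators.
#' @export
fit_portfolio_cox <- function(intervals, model, init = NULL, max_iter = 50L) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      !is.null(intervals$intervals)) intervals <- intervals$intervals
  validate_model_spec(model)
  if (sum(intervals$event) < 1) stop("no events in the interval data")
  des <- build_design(model, intervals)
  y <- survival::Surv(intervals$start, intervals$stop,
                      as.integer(intervals$event))
  ctl <- survival::coxph.control(iter.max = max_iter, eps = 1e-10)
  if (ncol(des$X) == 0L) {
    cfit <- survival::coxph(y ~ 1, ties = "efron", control = ctl)
    ll <- rep(cfit$loglik[1L], 2)
    beta <- numeric(0); V <- matrix(0, 0, 0); aliased <- character(0)
    conv <- TRUE
  } else {
    init <- if (is.null(init)) rep(0, ncol(des$X))
    else if (!is.null(names(init))) {
      # named init: warm start from another fit's coefficients
      v <- init[colnames(des$X)]
      v[is.na(v)] <- 0
      unname(v)
    } else init
    # agreg.fit is the counting-process engine behind coxph(); calling it
    # directly skips the model-frame machinery, which matters when the
    # selection procedures fit hundreds of candidate models
    cfit <- suppressWarnings(
      survival::agreg.fit(des$X, y, strata = NULL, offset = NULL,
                          init = init, control = ctl, weights = NULL,
                          method = "efron", rownames = NULL))
    names(cfit$coefficients) <- colnames(des$X)
    keep <- !is.na(cfit$coefficients)
    aliased <- colnames(des$X)[!keep]
    beta <- cfit$coefficients[keep]
    V <- cfit$var[keep, keep, drop = FALSE]
    dimnames(V) <- list(names(beta), names(beta))
    ll <- cfit$loglik
    conv <- all(abs(beta) <= 20) && cfit$iter < max_iter
  }
  structure(list(
    beta = beta, se = sqrt(pmax(diag(V), 0)), covariance = V,
    loglik = ll[2L], loglik_null = ll[1L],
    n_events = sum(intervals$event), converged = conv, aliased = aliased,
    model = model, colmap = des$colmap,
    centering = attr(intervals, "centering"),
    diseases = attr(intervals, "diseases"),
    intervals = intervals),
    class = "portfolio_cox_fit")
}

#' @export
print.portfolio_cox_fit <- function(x, ...) {
  cat("portfolio_cox_fit: ", length(x$beta), " coefficients, ",
      x$n_events, " events, loglik ", format(x$loglik), ", ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (length(x$aliased))
    cat("  aliased columns dropped:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient table with wide confidence intervals
#'
#' @param fit A `portfolio_cox_fit`.
#' @param ci_level Confidence level (default 0.999, i.e. 99.9\% CIs).
#' @return data.frame: term, column, coef, se, z, p, ci_low, ci_high.
#' @export
coef_table <- function(fit, ci_level = 0.999) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  cm <- fit$colmap[match(names(fit$beta), fit$colmap$column), ]
  data.frame(term = cm$term, column = names(fit$beta),
             coef = unname(fit$beta), se = unname(fit$se),
             z = unname(fit$beta / fit$se),
             p = unname(2 * stats::pnorm(-abs(fit$beta / fit$se))),
             ci_low = unname(fit$beta - z * fit$se),
             ci_high = unname(fit$beta + z * fit$se),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested fits
#'
#' @param nested,full `portfolio_cox_fit`s on the same intervals, with the
#'   nested model's term set contained in the full model's.
#' @return List: `statistic` (2 * loglik difference), `df` (design-column
#'   difference), `p` (chi-square upper tail).
#' @export
lrt <- function(nested, full) {
  if (!all(names(nested$model$terms) %in% names(full$model$terms)))
    stop("models are not nested")
  if (nested$n_events != full$n_events)
    stop("fits are not on the same interval data")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-8) stop("negative LRT statistic: fits are inconsistent")
  stat <- max(stat, 0)
  df <- length(full$beta) - length(nested$beta)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Proportional-hazards diagnostics from Schoenfeld residuals
#'
#' Per design column, the score test of zero slope of the scaled
#' Schoenfeld residuals against event time (identity transform) — the
#' standard check that a covariate's effect is constant over follow-up.
#'
#' @param fit Converged `portfolio_cox_fit` with at least one coefficient.
#' @return data.frame: column, chisq, df, p (plus a GLOBAL row).
#' @export
schoenfeld_check <- function(fit) {
  if (!fit$converged) stop("PH diagnostics require a converged fit")
  if (!length(fit$beta)) stop("null model has no covariates to check")
  cf <- full_coxph(fit)
  zp <- survival::cox.zph(cf, transform = "identity")
  tb <- as.data.frame(zp$table)
  nm <- rownames(tb)
  orig <- attr(cf, "column_names")
  safe <- make.names(orig, unique = TRUE)
  nm[match(safe, nm)] <- orig
  data.frame(column = nm, chisq = tb$chisq, df = tb$df, p = tb$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Raw Schoenfeld residuals
#'
#' Observed covariate of the failing subject minus the risk-set-weighted
#' covariate mean, one row per event time.
#'
#' @param fit A `portfolio_cox_fit`.
#' @return Matrix of residuals (events x design columns).
#' @export
schoenfeld_residuals <- function(fit) {
  cf <- full_coxph(fit)
  r <- stats::residuals(cf, type = "schoenfeld")
  if (is.null(dim(r))) r <- matrix(r, ncol = 1)
  colnames(r) <- attr(cf, "column_names")
  r
}

# Reconstruct a full coxph object at the stored coefficients (the fast
# fitting path bypasses the model-frame machinery that cox.zph and
# residuals.coxph rely on). Zero update iterations keep the coefficients
# exactly as fitted.
full_coxph <- function(fit) {
  iv <- fit$intervals
  X <- build_design(fit$model, iv)$X
  X <- X[, setdiff(colnames(X), fit$aliased), drop = FALSE]
  safe <- make.names(colnames(X), unique = TRUE)
  dat <- as.data.frame(X)
  names(dat) <- safe
  dat$.start <- iv$start; dat$.stop <- iv$stop
  dat$.event <- as.integer(iv$event)
  fml <- stats::as.formula(
    paste("survival::Surv(.start, .stop, .event) ~",
          paste(sprintf("`%s`", safe), collapse = " + ")))
  cf <- suppressWarnings(survival::coxph(
    fml, data = dat, ties = "efron", init = unname(fit$beta),
    control = survival::coxph.control(iter.max = 0)))
  attr(cf, "column_names") <- colnames(X)
  cf
}

#' Breslow estimate of the baseline cumulative hazard
#'
#' At each distinct event time \eqn{t_e}, the hazard increment
#' \eqn{d\Lambda_0(t_e) = d_e / \sum_{at\,risk} \exp(\eta_i)}, where
#' \eqn{d_e} is the number of deaths at \eqn{t_e} and the sum runs over
#' intervals with start < \eqn{t_e} <= stop. The reference is the all-zero
#' design row: male, no education, no diseases beyond HD, mean age and
#' calendar time.
#'
#' @param fit Converged `portfolio_cox_fit`.
#' @return A `baseline_hazard`: list with `times` (sorted distinct event
#'   times) and `increments`.
#' @export
breslow_baseline <- function(fit) {
  iv <- fit$intervals
  eta <- if (length(fit$beta)) {
    X <- build_design(fit$model, iv)$X[, names(fit$beta), drop = FALSE]
    drop(X %*% fit$beta)
  } else rep(0, nrow(iv))
  et <- sort(unique(iv$stop[iv$event]))
  w <- exp(eta)
  inc <- vapply(et, function(te) {
    at_risk <- iv$start < te & te <= iv$stop
    d <- sum(iv$event[at_risk] & iv$stop[at_risk] == te)
    d / sum(w[at_risk])
  }, 0)
  structure(list(times = et, increments = inc), class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("baseline_hazard: ", length(x$times), " event times, Lambda0(max) = ",
      format(sum(x$increments)), "\n", sep = "")
  invisible(x)
}
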