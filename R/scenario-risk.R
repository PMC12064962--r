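#' Data-driven expansion times via gamma regression
#'
#' For a hypothetical disease trajectory, the times at which the portfolio
#' expands are estimated from the cohort: for j = 1, 2, 3, the time of the
#' j-th post-HD portfolio expansion is regressed (gamma GLM, log link) on
#' indicators of which diseases constitute a person's first j diagnoses,
#' and the scenario's j-th time is the fitted mean at the scenario's own
#' first j diagnoses. Only the fitted mean is used, so the gamma shape is
#' profiled out by the GLM fit.
#'
#' @param subjects,events Registry tables.
#' @param sequence Character vector of diseases in scenario order (the
#'   first `min(3, length(sequence))` get data-driven times).
#' @param diseases Indicator catalogue for the regressions; default: the
#'   observed disease labels. An empty catalogue gives intercept-only
#'   regressions (the plain mean expansion time).
#' @return Numeric vector of fitted expansion times (years since HD),
#'   strictly increasing; errors if no qualifying persons exist for some
#'   j or if the fitted times do not increase.
#' @export
expansion_times <- function(subjects, events, sequence, diseases = NULL) {
  admin <- c("HD", "death", "emigration")
  if (is.null(diseases))
    diseases <- sort(setdiff(unique(events$label), admin))
  ev <- events[!(events$label %in% admin), ]
  idx <- match(ev$person_id, subjects$person_id)
  ev$t <- as.numeric(ev$date - subjects$hd_date[idx]) / 365.25
  ev <- ev[ev$t > 0, ]
  ev <- ev[order(ev$person_id, ev$t, ev$label), ]
  by_p <- split(ev, ev$person_id)

  out <- numeric(0)
  for (j in seq_len(min(3L, length(sequence)))) {
    has_j <- vapply(by_p, nrow, 0L) >= j
    if (!any(has_j))
      stop("no persons with a ", j, "-th portfolio expansion in the cohort")
    tj <- vapply(by_p[has_j], function(d) d$t[j], 0)
    firstj <- lapply(by_p[has_j], function(d) d$label[seq_len(j)])
    dat <- data.frame(time = tj)
    for (d in diseases)
      dat[[d]] <- vapply(firstj, function(f) as.numeric(d %in% f), 0)
    fml <- if (length(diseases))
      stats::as.formula(paste("time ~",
                              paste(sprintf("`%s`", diseases),
                                    collapse = " + ")))
    else time ~ 1
    gfit <- stats::glm(fml, data = dat,
                       family = stats::Gamma(link = "log"))
    nd <- as.data.frame(as.list(stats::setNames(
      as.numeric(diseases %in% sequence[seq_len(j)]), diseases)),
      check.names = FALSE)
    if (!length(diseases)) nd <- data.frame(row.names = 1)
    out <- c(out, unname(stats::predict(gfit, newdata = nd,
                                        type = "response")))
  }
  if (length(out) > 1L && any(diff(out) <= 0))
    stop("fitted expansion times are not strictly increasing: ",
         paste(signif(out, 4), collapse = ", "))
  out
}

#' Define a hypothetical disease-trajectory scenario
#'
#' @param baseline Diseases already present at HD diagnosis (t = 0).
#' @param expansions data.frame with columns `disease` and `time` (years
#'   since HD, strictly increasing and positive), in trajectory order.
#' @param sex,education Intrinsic profile; age and calendar time sit at
#'   their cohort means.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(baseline = character(0),
                          expansions = data.frame(disease = character(0),
                                                  time = numeric(0)),
                          sex = "male", education = "none") {
  stopifnot(is.data.frame(expansions),
            all(c("disease", "time") %in% names(expansions)))
  if (nrow(expansions)) {
    if (any(expansions$time <= 0) ||
        is.unsorted(expansions$time, strictly = TRUE))
      stop("expansion times must be strictly increasing and > 0")
  }
  dall <- c(baseline, expansions$disease)
  if (anyDuplicated(dall)) stop("scenario diseases must be distinct")
  structure(list(baseline = as.character(baseline),
                 expansions = expansions, sex = sex, education = education),
            class = "scenario_spec")
}

#' Absolute mortality-risk curve for a scenario
#'
#' Combines the fitted coefficients with the Breslow baseline cumulative
#' hazard: the scenario's linear predictor \eqn{\eta(t)} is piecewise
#' constant, switching as the portfolio expands, and the cumulative risk
#' is \eqn{F(t) = 1 - \exp(-\sum_{t_e \le t} d\Lambda_0(t_e) e^{\eta(t_e)})}
#' over the baseline's event times (an expansion at \eqn{\tau} affects
#' event times after \eqn{\tau}). The curve starts at 0, is
#' non-decreasing, and stays in [0, 1].
#'
#' Scenarios describe how the model depicts a typical trajectory; because
#' expansion times condition on future events they are not prognostic
#' forecasts (see the `note` element of the result).
#'
#' @param fit Converged `portfolio_cox_fit`.
#' @param baseline A `baseline_hazard` from [breslow_baseline()] on the
#'   same cohort.
#' @param scenario A [scenario_spec()].
#' @param grid Optional time grid for reporting; the step function is
#'   carried onto it right-continuously. Default: the baseline's event
#'   times.
#' @return A `risk_curve`: list with `time`, `risk`, `scenario`, `note`.
#' @export
risk_curve <- function(fit, baseline, scenario, grid = NULL) {
  stopifnot(inherits(baseline, "baseline_hazard"),
            inherits(scenario, "scenario_spec"))
  check_in_model(fit, c(scenario$baseline, scenario$expansions$disease))
  te <- baseline$times
  eta <- numeric(length(te))
  bounds <- c(0, scenario$expansions$time, Inf)
  for (s in seq_len(length(bounds) - 1L)) {
    state <- c(scenario$baseline,
               scenario$expansions$disease[seq_len(s - 1L)])
    in_seg <- te > bounds[s] & te <= bounds[s + 1L]
    if (any(in_seg))
      eta[in_seg] <- sum(design_row(fit, state, scenario$sex,
                                    scenario$education) * fit$beta)
  }
  cumhaz <- cumsum(baseline$increments * exp(eta))
  Fstep <- 1 - exp(-cumhaz)
  if (is.null(grid)) {
    time <- te; risk <- Fstep
  } else {
    time <- grid
    risk <- stats::approx(c(0, te), c(0, Fstep), xout = grid,
                          method = "constant", f = 0, rule = 2)$y
  }
  structure(list(time = time, risk = risk, scenario = scenario,
                 note = paste("Scenario curves illustrate the fitted model;",
                              "expansion times condition on future events,",
                              "so they are not prognostic forecasts.")),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat("risk_curve: F(", format(max(x$time)), ") = ",
      format(x$risk[length(x$risk)]), " over ", length(x$time),
      " time points\n", sep = "")
  invisible(x)
}
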