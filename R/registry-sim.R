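#' Ground-truth configuration for the synthetic registry generator
#'
#' Describes a synthetic cohort of heart-disease (HD) patients: intrinsic
#' variables drawn at HD diagnosis, chronic-disease onset clocks, and a
#' death hazard of the extended-Cox form
#' \eqn{h(t) = h_0(t) \exp(\sum_j \beta_j X_j(t))}, where the disease
#' indicators \eqn{X_j(t)} are piecewise constant (0 before diagnosis, 1
#' after) and \eqn{\beta_j} may include planted interaction coefficients.
#' Time 0 is the HD diagnosis.
#'
#' @param disease_labels Diseases to simulate (default the 14-disease
#'   catalogue of [portfolio_diseases()]).
#' @param onset_rate Per-year hazard of acquiring each disease after HD;
#'   scalar or named vector over `disease_labels`.
#' @param beta_truth Named numeric vector of true log-hazard coefficients;
#'   names are serialized terms ([term_label()]) over disease labels and
#'   intrinsic column labels (`sex_female`, `edu_short`, ..., `age`,
#'   `age2`, `age3`, `cal`, `cal2`, `cal3`). Keys must form a
#'   hierarchically closed term set.
#' @param baseline_hazard data.frame with columns `time` (years since HD,
#'   starting at 0) and `rate` (per-year); piecewise constant, last segment
#'   extends indefinitely. This is the \eqn{h_0(t)} of the reference
#'   subject: male, no education, no diseases beyond HD, mean age and
#'   calendar time.
#' @param censor_time_years Maximum administrative follow-up in years
#'   (default `Inf`: follow-up ends at the calendar window's close).
#' @param admin_end_year Calendar year closing the observation window
#'   (default `calendar_window[2]`; `Inf` disables administrative
#'   censoring altogether).
#' @param emigration_rate Per-year hazard of censoring by emigration.
#' @param age_mean,age_sd Mean/SD of age at HD diagnosis in years
#'   (truncated at `age_min`).
#' @param age_min Minimum age at HD diagnosis (adults only).
#' @param calendar_window Two calendar years (decimal) bounding HD
#'   diagnosis dates and the administrative end of observation.
#' @param sex_prob Probability of male sex.
#' @param education_probs Probabilities over the 6 levels of
#'   [education_levels()]; must sum to 1.
#' @param pre_hd_prob Probability that a disease a subject acquires is
#'   already present before the HD diagnosis (pre-existing condition),
#'   scalar or named per disease. Makes prevalence at t = 0 smaller than
#'   lifetime prevalence, as in real HD trajectories.
#' @param pre_hd_window_years Pre-existing onsets are dated uniformly up to
#'   this many years before HD.
#' @param onset_multiplier Optional `function(disease, portfolio)` returning
#'   a multiplicative factor on that disease's onset rate given the current
#'   portfolio (portfolio-dependent disease accrual); `NULL` means 1.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated `truth_config` object.
#' @export
truth_config <- function(disease_labels = portfolio_diseases(),
                         onset_rate = 0.03,
                         beta_truth = numeric(0),
                         baseline_hazard = data.frame(time = 0, rate = 0.08),
                         censor_time_years = Inf,
                         admin_end_year = NULL,
                         emigration_rate = 0.005,
                         age_mean = 70, age_sd = 13, age_min = 18,
                         calendar_window = c(1995, 2016),
                         sex_prob = 0.53,
                         education_probs = c(none = 0.30, short = 0.35,
                                             medium = 0.15, long = 0.10,
                                             missing = 0.05,
                                             missing_before_1920 = 0.05),
                         pre_hd_prob = 0.35,
                         pre_hd_window_years = 10,
                         onset_multiplier = NULL,
                         seed = 1L) {
  disease_labels <- as.character(disease_labels)
  if (anyDuplicated(disease_labels)) stop("duplicate disease labels")
  if (length(onset_rate) == 1L && is.null(names(onset_rate)))
    onset_rate <- stats::setNames(rep(onset_rate, length(disease_labels)),
                                  disease_labels)
  onset_rate <- onset_rate[disease_labels]
  if (anyNA(onset_rate) || any(onset_rate < 0))
    stop("onset_rate must be non-negative and cover every disease label")
  if (length(pre_hd_prob) == 1L && is.null(names(pre_hd_prob)))
    pre_hd_prob <- stats::setNames(rep(pre_hd_prob, length(disease_labels)),
                                   disease_labels)
  pre_hd_prob <- pre_hd_prob[disease_labels]
  if (anyNA(pre_hd_prob) || any(pre_hd_prob < 0) || any(pre_hd_prob > 1))
    stop("pre_hd_prob must be probabilities covering every disease label")
  stopifnot(is.data.frame(baseline_hazard),
            all(c("time", "rate") %in% names(baseline_hazard)))
  if (baseline_hazard$time[1] != 0 || is.unsorted(baseline_hazard$time, strictly = TRUE))
    stop("baseline_hazard$time must start at 0 and be strictly increasing")
  if (any(baseline_hazard$rate < 0)) stop("baseline hazard rates must be >= 0")
  if (emigration_rate < 0) stop("emigration_rate must be >= 0")
  names(education_probs) <- names(education_probs) %||% education_levels()
  if (!setequal(names(education_probs), education_levels()) ||
      abs(sum(education_probs) - 1) > 1e-12)
    stop("education_probs must cover the 6 levels and sum to 1")
  beta_truth <- validate_truth_terms(beta_truth, disease_labels)
  structure(list(
    disease_labels = disease_labels, onset_rate = onset_rate,
    beta_truth = beta_truth, baseline_hazard = baseline_hazard,
    censor_time_years = censor_time_years,
    admin_end_year = admin_end_year %||% calendar_window[2],
    emigration_rate = emigration_rate,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    calendar_window = calendar_window, sex_prob = sex_prob,
    education_probs = education_probs[education_levels()],
    pre_hd_prob = pre_hd_prob, pre_hd_window_years = pre_hd_window_years,
    onset_multiplier = onset_multiplier, seed = seed),
    class = "truth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Check beta_truth keys: known labels, hierarchically closed, polynomials
# only as main effects.
validate_truth_terms <- function(beta_truth, disease_labels) {
  if (!length(beta_truth)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(beta_truth)) || any(!nzchar(names(beta_truth))))
    stop("beta_truth must be a named vector of serialized terms")
  known <- c(disease_labels, "sex_female",
             paste0("edu_", education_levels()[-1]),
             "age", "cal", poly_vars())
  terms <- lapply(names(beta_truth), parse_term)
  bad <- setdiff(unique(unlist(terms)), known)
  if (length(bad)) stop("unknown variable label(s) in beta_truth: ",
                        paste(bad, collapse = ", "))
  need <- unique(unlist(lapply(terms, term_subsets)))
  miss <- setdiff(need, names(beta_truth))
  if (length(miss))
    stop("beta_truth term set is not hierarchically closed; missing: ",
         paste(miss, collapse = ", "))
  beta_truth
}

#' @export
print.truth_config <- function(x, ...) {
  cat("truth_config: ", length(x$disease_labels), " diseases, ",
      length(x$beta_truth), " nonzero truth terms, baseline ",
      nrow(x$baseline_hazard), " segment(s)\n", sep = "")
  invisible(x)
}

# Time at which the integral of a piecewise-constant rate from t0 reaches
# `target`; Inf if it never does. Segments: rate[j] on [time[j], time[j+1]),
# last segment unbounded.
pc_hazard_quantile <- function(times, rates, t0, target) {
  k <- length(times)
  seg <- findInterval(t0, times)
  t <- t0
  acc <- target
  repeat {
    upper <- if (seg < k) times[seg + 1L] else Inf
    r <- rates[seg]
    if (r > 0) {
      dt <- acc / r
      if (t + dt <= upper) return(t + dt)
      acc <- acc - r * (upper - t)
    }
    if (!is.finite(upper)) return(Inf)
    t <- upper
    seg <- seg + 1L
  }
}

# Intrinsic covariate values for one subject as a named vector on the truth
# (column-label) scale; age/cal centered at the config means.
intrinsic_values <- function(sex_female, education, age, cal, config) {
  a <- age - config$age_mean
  cc <- cal - mean(config$calendar_window)
  v <- c(sex_female = as.numeric(sex_female),
         stats::setNames(as.numeric(paste0("edu_", education) ==
                                      paste0("edu_", education_levels()[-1])),
                         paste0("edu_", education_levels()[-1])),
         age = a, age2 = a^2, age3 = a^3, cal = cc, cal2 = cc^2, cal3 = cc^3)
  v
}

#' Simulate a synthetic HD registry cohort
#'
#' Generates subject and event tables with the structure the analysis
#' pipeline consumes: one HD diagnosis anchoring time 0 per subject,
#' dated chronic-disease diagnoses arriving before or after HD, and an end
#' of follow-up by death, emigration, or administrative censoring. Death
#' times are drawn from the proportional-hazards truth
#' \eqn{h_0(t)\exp(\mathrm{lp}(t))} by competing exponential clocks between
#' portfolio-change points; all times are rounded to whole days.
#'
#' @param config A [truth_config()].
#' @param n Number of subjects (`>= 1`).
#' @param seed Integer seed (default `config$seed`); fixed seed gives
#'   byte-identical output.
#' @return List with `subjects` (person_id, sex, birth_date, education,
#'   hd_date, end_date, end_status) and `events` (person_id, label, date)
#'   data.frames; dates are `Date`s.
#' @export
simulate_cohort <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "truth_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dl <- config$disease_labels
  nd <- length(dl)
  win <- config$calendar_window

  sex <- ifelse(stats::runif(n) < config$sex_prob, "male", "female")
  education <- sample(education_levels(), n, replace = TRUE,
                      prob = config$education_probs)
  age <- config$age_mean + config$age_sd * stats::rnorm(n)
  age <- pmax(age, config$age_min)
  hd_cal <- stats::runif(n, win[1], win[2])
  follow_limit <- pmin(config$censor_time_years,
                       config$admin_end_year - hd_cal)

  # split truth terms once: coefficient, disease components, intrinsic
  # components
  tt <- lapply(names(config$beta_truth), parse_term)
  t_beta <- unname(config$beta_truth)
  t_dis <- lapply(tt, function(t) match(intersect(t, dl), dl))
  t_int <- lapply(tt, function(t) setdiff(t, dl))
  nterm <- length(tt)

  base_t <- config$baseline_hazard$time
  base_r <- config$baseline_hazard$rate
  emr <- config$emigration_rate
  mult <- config$onset_multiplier

  # per-subject, per-term intrinsic products (constant over follow-up)
  ip <- matrix(1, n, max(nterm, 1L))
  if (nterm) for (i in seq_len(n)) {
    iv <- intrinsic_values(sex[i] == "female", education[i], age[i],
                           hd_cal[i], config)
    ip[i, ] <- vapply(t_int, function(v)
      if (length(v)) prod(iv[v]) else 1, 0)
  }

  if (is.null(mult)) {
    core <- simulate_core_cpp(
      as.integer(n), unname(config$onset_rate), unname(config$pre_hd_prob),
      config$pre_hd_window_years, base_t, base_r, emr, follow_limit,
      unname(t_beta), lapply(t_dis, function(ix) as.integer(ix - 1L)),
      ip[, seq_len(nterm), drop = FALSE])
  } else {
    core <- simulate_core_r(n, config, follow_limit, t_beta, t_dis, ip, mult)
  }
  status <- c("censored", "death", "emigration")[core$status + 1L]
  end_day <- pmax(1, round(core$end_time * 365.25))
  hd_date <- as.Date(round((hd_cal - 1970) * 365.25), origin = "1970-01-01")
  subjects <- data.frame(
    person_id = seq_len(n), sex = sex,
    birth_date = hd_date - round(pmax(age, config$age_min) * 365.25),
    education = education, hd_date = hd_date,
    end_date = hd_date + end_day,
    end_status = ifelse(status == "death", "death", "censored"),
    stringsAsFactors = FALSE)

  ev_pid <- core$ev_pid
  ev_lab <- dl[core$ev_dis]
  ev_day <- pmin(round(core$ev_time * 365.25), end_day[ev_pid])
  events <- data.frame(
    person_id = c(seq_len(n), ev_pid,
                  which(status == "death"), which(status == "emigration")),
    label = c(rep("HD", n), ev_lab,
              rep("death", sum(status == "death")),
              rep("emigration", sum(status == "emigration"))),
    date = c(hd_date, hd_date[ev_pid] + ev_day,
             subjects$end_date[status == "death"],
             subjects$end_date[status == "emigration"]),
    stringsAsFactors = FALSE)
  events <- events[order(events$person_id, events$date, events$label), ]
  rownames(events) <- NULL
  list(subjects = subjects, events = events)
}

# R fallback for the simulator core, used when disease onset rates depend
# on the current portfolio (onset_multiplier): same semantics as the
# compiled path, plus the multiplier applied to inactive diseases' rates.
simulate_core_r <- function(n, config, follow_limit, t_beta, t_dis, ip,
                            mult) {
  dl <- config$disease_labels
  nd <- length(dl)
  nterm <- length(t_beta)
  base_t <- config$baseline_hazard$time
  base_r <- config$baseline_hazard$rate
  emr <- config$emigration_rate
  end_time <- numeric(n)
  status <- integer(n)
  ev_pid <- ev_dis <- integer(0)
  ev_time <- numeric(0)
  for (i in seq_len(n)) {
    state <- config$onset_rate > 0 & stats::runif(nd) < config$pre_hd_prob
    onset_t <- rep(NA_real_, nd)
    onset_t[state] <- -stats::runif(sum(state), 0,
                                    config$pre_hd_window_years)
    emig <- if (emr > 0) stats::rexp(1) / emr else Inf
    limit <- min(follow_limit[i], emig)
    t <- 0
    repeat {
      lp <- if (nterm) sum(t_beta * ip[i, ] * vapply(t_dis, function(ix)
        if (length(ix)) prod(state[ix]) else 1, 0)) else 0
      death <- pc_hazard_quantile(base_t, base_r, t,
                                  stats::rexp(1) * exp(-lp))
      rates <- config$onset_rate
      for (d in which(!state))
        rates[d] <- rates[d] * mult(dl[d], dl[state])
      rates[state] <- 0
      onset <- ifelse(rates > 0, t + stats::rexp(nd) / pmax(rates, 1e-300),
                      Inf)
      j <- which.min(onset)
      t_on <- if (length(j)) onset[j] else Inf
      if (death <= min(t_on, limit)) {
        end_time[i] <- death; status[i] <- 1L; break
      }
      if (t_on <= limit) {
        state[j] <- TRUE
        onset_t[j] <- t_on
        t <- t_on
      } else {
        end_time[i] <- limit
        status[i] <- if (emig <= follow_limit[i]) 2L else 0L
        break
      }
    }
    got <- which(!is.na(onset_t))
    ev_pid <- c(ev_pid, rep(i, length(got)))
    ev_dis <- c(ev_dis, got)
    ev_time <- c(ev_time, onset_t[got])
  }
  list(end_time = end_time, status = status, ev_pid = ev_pid,
       ev_dis = ev_dis, ev_time = ev_time)
}

#' Write a registry to delimited text files
#'
#' Writes `subjects.csv` and `events.csv` with fixed column order and
#' ISO-8601 dates; the output round-trips losslessly through
#' [read_registry()] and rewriting is byte-identical.
#'
#' @param subjects,events Registry tables as from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_registry <- function(subjects, events, dir) {
  if (anyDuplicated(subjects$person_id)) stop("duplicate person_id in subjects")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- subjects[order(subjects$person_id),
                c("person_id", "sex", "birth_date", "education",
                  "hd_date", "end_date", "end_status")]
  e <- events[order(events$person_id, events$date, events$label),
              c("person_id", "label", "date")]
  for (cn in c("birth_date", "hd_date", "end_date")) s[[cn]] <- format(s[[cn]])
  e$date <- format(e$date)
  ps <- file.path(dir, "subjects.csv"); pe <- file.path(dir, "events.csv")
  utils::write.csv(s, ps, row.names = FALSE, quote = FALSE)
  utils::write.csv(e, pe, row.names = FALSE, quote = FALSE)
  invisible(c(subjects = ps, events = pe))
}

#' Read a registry written by [write_registry()]
#'
#' @param dir Directory containing `subjects.csv` and `events.csv`.
#' @return List with `subjects` and `events` data.frames (dates parsed).
#' @export
read_registry <- function(dir) {
  ps <- file.path(dir, "subjects.csv"); pe <- file.path(dir, "events.csv")
  for (p in c(ps, pe)) if (!file.exists(p)) stop("missing registry file: ", p)
  s <- utils::read.csv(ps, stringsAsFactors = FALSE,
                       colClasses = c(person_id = "integer"))
  e <- utils::read.csv(pe, stringsAsFactors = FALSE,
                       colClasses = c(person_id = "integer"))
  for (cn in c("birth_date", "hd_date", "end_date")) s[[cn]] <- as.Date(s[[cn]])
  e$date <- as.Date(e$date)
  list(subjects = s, events = e)
}
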