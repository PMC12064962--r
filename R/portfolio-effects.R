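#' Disease-portfolio effect machinery
#'
#' A disease portfolio is the set of co-occurring chronic diseases a
#' patient holds at some time (HD itself is implicit: every subject has
#' it). Portfolio effects are linear contrasts of the fitted log-hazard:
#' the linear predictor with the portfolio's diseases switched on minus
#' the predictor with no diseases, holding sex and education fixed and
#' age/calendar time at their (centered) means — so in a main-effects
#' model the effect is the sum of the member diseases' coefficients, while
#' interaction terms make it depend on the full portfolio and on the
#' intrinsic variables. Standard errors follow from the coefficient
#' covariance by the delta method; the reported intervals are 99.9\% CIs.
#'
#' @name portfolio-effects
NULL

# Bracket notation label for a portfolio.
portfolio_label <- function(diseases) {
  if (!length(diseases)) "[]" else
    paste0("[", paste(sort(diseases), collapse = ", "), "]")
}

# One-row data.frame of base covariate values for a covariate profile at
# mean (centered zero) age and calendar time.
profile_row <- function(fit, diseases_on, sex, education) {
  row <- as.list(stats::setNames(rep(0, length(fit$diseases)), fit$diseases))
  row[diseases_on] <- 1
  row$sex_female <- as.numeric(sex == "female")
  for (lev in education_levels()[-1])
    row[[paste0("edu_", lev)]] <- as.numeric(education == lev)
  for (v in c("age", "age2", "age3", "cal", "cal2", "cal3")) row[[v]] <- 0
  as.data.frame(row, check.names = FALSE)
}

# Design row over the fitted (non-aliased) columns.
design_row <- function(fit, diseases_on, sex, education) {
  X <- design_for_terms(fit$model$terms,
                        profile_row(fit, diseases_on, sex, education))$X
  drop(X[1, names(fit$beta), drop = FALSE])
}

check_in_model <- function(fit, diseases) {
  bad <- setdiff(diseases, fit$diseases)
  if (length(bad))
    stop("disease(s) not in the fitted model: ", paste(bad, collapse = ", "))
}

# Wrap a contrast vector into an effect-estimate row.
contrast_estimate <- function(fit, contrast, ci_level, meta) {
  log_hr <- sum(contrast * fit$beta)
  se <- sqrt(drop(t(contrast) %*% fit$covariance %*% contrast))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- cbind(meta, data.frame(
    log_hr = log_hr, se = se, hr = exp(log_hr),
    ci_low = exp(log_hr - z * se), ci_high = exp(log_hr + z * se)))
  attr(out, "contrast") <- contrast
  out
}

#' Log-hazard effect of a disease portfolio
#'
#' Contrast of the given portfolio against the same-sex, same-education
#' reference with only HD, at mean age and calendar time.
#'
#' @param fit Converged `portfolio_cox_fit`.
#' @param portfolio Character vector of disease labels (may be empty).
#' @param sex `"male"` or `"female"`.
#' @param education One of [education_levels()].
#' @param ci_level CI level (default 99.9\%).
#' @return One-row data.frame: portfolio, sex, education, log_hr, se, hr,
#'   ci_low, ci_high; the contrast vector is attached as an attribute.
#' @export
portfolio_log_effect <- function(fit, portfolio, sex = "male",
                                 education = "none", ci_level = 0.999) {
  check_in_model(fit, portfolio)
  contrast <- design_row(fit, portfolio, sex, education) -
    design_row(fit, character(0), sex, education)
  contrast_estimate(fit, contrast, ci_level,
                    data.frame(portfolio = portfolio_label(portfolio),
                               sex = sex, education = education,
                               stringsAsFactors = FALSE))
}

#' Count individuals by the portfolios they ever hold
#'
#' A person passes through a sequence of portfolio states as diagnoses
#' accrue; each distinct state they ever hold (including the initial state
#' at HD diagnosis) counts them once toward that portfolio within their
#' (sex, education) stratum — "had exactly this combination of diseases at
#' some time". Diagnoses sharing a date enter as one state change.
#'
#' @param subjects,events Registry tables.
#' @param diseases Disease labels; default: observed labels.
#' @return data.frame: portfolio (serialized label, `""` for HD only),
#'   sex, education, count.
#' @export
portfolio_weights <- function(subjects, events, diseases = NULL) {
  admin <- c("HD", "death", "emigration")
  if (is.null(diseases))
    diseases <- sort(setdiff(unique(events$label), admin))
  if (length(diseases) > 52) stop("too many diseases for bitmask states")
  ev <- events[events$label %in% diseases, ]
  if (anyDuplicated(ev[, c("person_id", "label")]))
    stop("more than one event per (person, label)")
  sidx <- match(ev$person_id, subjects$person_id)
  pre <- ev$date <= subjects$hd_date[sidx]
  # portfolio states as bitmasks: the state sequence of a person is the
  # cumulative OR of disease bits over date groups, starting from the
  # pre-HD set; diagnoses sharing a date are one state change
  bit <- 2^(match(ev$label, diseases) - 1)
  base <- rep(0, nrow(subjects))
  if (any(pre)) {
    pr <- stats::aggregate(bit[pre],
                           by = list(pid = ev$person_id[pre]), FUN = sum)
    base[match(pr$pid, subjects$person_id)] <- pr$x
  }
  dt <- data.table::data.table(pid = ev$person_id[!pre],
                               date = ev$date[!pre], bit = bit[!pre])
  post <- dt[, list(db = sum(bit)), by = c("pid", "date")]
  data.table::setorder(post, pid, date)
  post[, "mask" := cumsum(db) + base[match(pid, subjects$person_id)],
       by = "pid"]
  st <- rbind(data.frame(pid = subjects$person_id, mask = base),
              data.frame(pid = post$pid, mask = post$mask))
  sx <- subjects$sex[match(st$pid, subjects$person_id)]
  edu <- subjects$education[match(st$pid, subjects$person_id)]
  cnt <- stats::aggregate(
    list(count = rep(1L, nrow(st))),
    by = list(mask = st$mask, sex = sx, education = edu), FUN = sum)
  decode <- function(m) paste(
    diseases[(m %/% 2^(seq_along(diseases) - 1)) %% 2 >= 1],
    collapse = "+")
  umask <- unique(cnt$mask)
  key <- stats::setNames(vapply(umask, decode, ""), format(umask))
  out <- data.frame(portfolio = unname(key[format(cnt$mask)]),
                    sex = cnt$sex, education = cnt$education,
                    count = cnt$count, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$portfolio, out$sex, out$education), ]
  rownames(out) <- NULL
  out
}

# Portfolio size in the field's counting: member diseases plus HD.
portfolio_size <- function(portfolio_key) {
  ifelse(nzchar(portfolio_key),
         lengths(strsplit(portfolio_key, "+", fixed = TRUE)) + 1L, 1L)
}

#' Aggregate portfolio effects across education with prevalence weights
#'
#' For each (portfolio, sex), the per-education log-hazard effects are
#' combined as a weighted arithmetic mean on the log-hazard scale, with
#' weights equal to the number of individuals observed with exactly that
#' portfolio in the (sex, education) stratum; the result is exponentiated
#' for reporting and portfolios with fewer than `min_count` individuals in
#' the sex stratum are excluded. CIs come from the aggregated contrast and
#' the coefficient covariance.
#'
#' @param fit Converged `portfolio_cox_fit`.
#' @param weights Occurrence counts from [portfolio_weights()].
#' @param sizes Optional portfolio sizes (diseases + HD) to keep.
#' @param exclude_diseases Drop portfolios containing any of these.
#' @param min_count Exclusion threshold (default 10 individuals).
#' @param top Keep the `top` largest HRs per (size, sex); `NULL` for all.
#' @param ci_level CI level.
#' @return Ranked data.frame: size, sex, rank, portfolio, hr, ci_low,
#'   ci_high, log_hr, se, n_individuals.
#' @export
aggregate_effects <- function(fit, weights, sizes = NULL,
                              exclude_diseases = NULL, min_count = 10,
                              top = NULL, ci_level = 0.999) {
  w <- weights[nzchar(weights$portfolio), ]
  w$size <- portfolio_size(w$portfolio)
  if (!is.null(sizes)) w <- w[w$size %in% sizes, ]
  if (!is.null(exclude_diseases)) {
    keep <- !vapply(strsplit(w$portfolio, "+", fixed = TRUE),
                    function(d) any(d %in% exclude_diseases), TRUE)
    w <- w[keep, ]
  }
  res <- list()
  for (key in unique(w$portfolio)) {
    p <- strsplit(key, "+", fixed = TRUE)[[1]]
    if (length(setdiff(p, fit$diseases))) next
    for (sx in unique(w$sex[w$portfolio == key])) {
      ws <- w[w$portfolio == key & w$sex == sx, ]
      total <- sum(ws$count)
      if (total < min_count) next
      cmat <- vapply(seq_len(nrow(ws)), function(i)
        attr(portfolio_log_effect(fit, p, sx, ws$education[i],
                                  ci_level), "contrast"),
        numeric(length(fit$beta)))
      agg <- drop(cmat %*% (ws$count / total))
      est <- contrast_estimate(fit, agg, ci_level, data.frame(
        size = length(p) + 1L, sex = sx, portfolio = portfolio_label(p),
        n_individuals = total, stringsAsFactors = FALSE))
      res[[length(res) + 1L]] <- est
    }
  }
  if (!length(res))
    return(data.frame(size = integer(0), sex = character(0),
                      rank = integer(0), portfolio = character(0),
                      hr = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), log_hr = numeric(0),
                      se = numeric(0), n_individuals = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$size, out$sex, -out$log_hr), ]
  out$rank <- stats::ave(-out$log_hr, out$size, out$sex, FUN = rank)
  if (!is.null(top)) out <- out[out$rank <= top, ]
  rownames(out) <- NULL
  out[, c("size", "sex", "rank", "portfolio", "hr", "ci_low", "ci_high",
          "log_hr", "se", "n_individuals")]
}

#' Multiplier converting additive-model HRs into interaction-model HRs
#'
#' Per observed portfolio and stratum, the difference on the log-hazard
#' scale between the interaction model's portfolio effect and the additive
#' (main-effects-only) model's; per portfolio size and sex, the
#' occurrence-weighted mean difference is exponentiated, giving the
#' average factor by which the additive model's HR must be multiplied to
#' recover the interaction model's HR. Identical fits give multiplier 1.
#'
#' @param fit_all Interaction-model fit.
#' @param fit_ome Additive-model fit on the same intervals.
#' @param weights Occurrence counts from [portfolio_weights()].
#' @param sizes Portfolio sizes (diseases + HD) to report (default 2:8).
#' @param min_count Exclude portfolios with fewer individuals per sex.
#' @return data.frame: size, sex, multiplier, mean_log_diff,
#'   n_portfolios, total_weight. Also returns the per-portfolio
#'   differences as attribute `"detail"`.
#' @export
multiplier_vs_additive <- function(fit_all, fit_ome, weights, sizes = 2:8,
                                   min_count = 10) {
  if (fit_all$n_events != fit_ome$n_events)
    stop("fits are not on the same interval data")
  w <- weights[nzchar(weights$portfolio), ]
  w$size <- portfolio_size(w$portfolio)
  w <- w[w$size %in% sizes, ]
  keep <- !vapply(strsplit(w$portfolio, "+", fixed = TRUE),
                  function(p) length(setdiff(p, fit_all$diseases)) > 0, TRUE)
  w <- w[keep, ]
  if (min_count > 0) {
    tot <- stats::aggregate(count ~ portfolio + sex, data = w, FUN = sum)
    ok <- tot[tot$count >= min_count, c("portfolio", "sex")]
    w <- merge(w, ok, by = c("portfolio", "sex"))
  }
  if (!nrow(w))
    return(data.frame(size = integer(0), sex = character(0),
                      multiplier = numeric(0), mean_log_diff = numeric(0),
                      n_portfolios = integer(0), total_weight = numeric(0)))
  w$delta <- vapply(seq_len(nrow(w)), function(i) {
    p <- strsplit(w$portfolio[i], "+", fixed = TRUE)[[1]]
    portfolio_log_effect(fit_all, p, w$sex[i], w$education[i])$log_hr -
      portfolio_log_effect(fit_ome, p, w$sex[i], w$education[i])$log_hr
  }, 0)
  res <- list()
  for (s in sort(unique(w$size))) for (sx in sort(unique(w$sex))) {
    ws <- w[w$size == s & w$sex == sx, ]
    if (!nrow(ws)) next
    md <- sum(ws$delta * ws$count) / sum(ws$count)
    res[[length(res) + 1L]] <- data.frame(
      size = s, sex = sx, multiplier = exp(md), mean_log_diff = md,
      n_portfolios = length(unique(ws$portfolio)),
      total_weight = sum(ws$count), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "detail") <- w
  out
}

#' Female-versus-male hazard ratio for a fixed portfolio
#'
#' Linear-predictor difference female minus male with the portfolio and
#' education held fixed, at mean age and calendar time. Without sex
#' interactions this is the sex main effect for every portfolio.
#'
#' @inheritParams portfolio_log_effect
#' @return One-row effect data.frame as in [portfolio_log_effect()].
#' @export
sex_contrast <- function(fit, portfolio, education = "none",
                         ci_level = 0.999) {
  check_in_model(fit, portfolio)
  contrast <- design_row(fit, portfolio, "female", education) -
    design_row(fit, portfolio, "male", education)
  contrast_estimate(fit, contrast, ci_level,
                    data.frame(portfolio = portfolio_label(portfolio),
                               contrast = "female_vs_male",
                               education = education,
                               stringsAsFactors = FALSE))
}

#' Aggregated conditional effect of one disease by portfolio size
#'
#' For every observed portfolio containing the disease, the contrast
#' between the portfolio with and without the disease is computed per
#' (sex, education) stratum and aggregated on the log-hazard scale with
#' occurrence weights, by portfolio size and sex — the "effect of the
#' disease given the rest of the portfolio". With negative
#' disease-by-disease interactions the conditional HR shrinks as the
#' portfolio grows.
#'
#' @param fit Converged `portfolio_cox_fit`.
#' @param disease Disease label present in the model.
#' @param weights Occurrence counts from [portfolio_weights()].
#' @return data.frame: size, sex, hr, mean_log_hr, n_portfolios,
#'   total_weight.
#' @export
conditional_disease_effect <- function(fit, disease, weights) {
  check_in_model(fit, disease)
  w <- weights[nzchar(weights$portfolio), ]
  plist <- strsplit(w$portfolio, "+", fixed = TRUE)
  keep <- vapply(plist, function(p)
    disease %in% p && !length(setdiff(p, fit$diseases)), TRUE)
  w <- w[keep, ]; plist <- plist[keep]
  if (!nrow(w)) stop("no observed portfolio contains ", disease)
  w$size <- lengths(plist) + 1L
  w$delta <- vapply(seq_len(nrow(w)), function(i) {
    p <- plist[[i]]
    portfolio_log_effect(fit, p, w$sex[i], w$education[i])$log_hr -
      portfolio_log_effect(fit, setdiff(p, disease), w$sex[i],
                           w$education[i])$log_hr
  }, 0)
  res <- list()
  for (s in sort(unique(w$size))) for (sx in sort(unique(w$sex))) {
    ws <- w[w$size == s & w$sex == sx, ]
    if (!nrow(ws)) next
    md <- sum(ws$delta * ws$count) / sum(ws$count)
    res[[length(res) + 1L]] <- data.frame(
      size = s, sex = sx, hr = exp(md), mean_log_hr = md,
      n_portfolios = length(unique(ws$portfolio)),
      total_weight = sum(ws$count), stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
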