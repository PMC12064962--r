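#' Configuration for stability selection with LASSO-Cox
#'
#' Defaults mirror the full-scale analysis design: 3400 subsamples, 10
#' variables per subsample with all their interactions up to order 5, and
#' a selection-frequency threshold of 0.9. Validation runs use a few
#' hundred subsamples.
#'
#' @param n_subsamples Number of random subsamples.
#' @param vars_per_subsample Variables drawn per subsample.
#' @param max_order Highest interaction order in the subsample design.
#' @param threshold Selection-frequency threshold pi in (0, 1].
#' @param subject_fraction Fraction of subjects drawn per subsample
#'   (classic stability selection subsamples observations; set to 1 to
#'   disable).
#' @param n_lambda Size of the log-spaced L1 penalty grid.
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param max_active Per-subsample cap on the number of active design
#'   columns: the penalty path is truncated once more than this many
#'   columns are nonzero, so a subsample "selects" the first entrants of
#'   its path rather than everything the unpenalized end would admit.
#'   Keeping per-subsample selections sparse is what makes selection
#'   frequencies discriminate signal from noise (default 10).
#' @param seed Seed for reproducible subsampling.
#' @return A `stability_config`.
#' @export
stability_config <- function(n_subsamples = 3400L, vars_per_subsample = 10L,
                             max_order = 5L, threshold = 0.9,
                             subject_fraction = 0.5, n_lambda = 30L,
                             lambda_min_ratio = 0.01, max_active = 10L,
                             seed = 1L) {
  stopifnot(threshold > 0, threshold <= 1, n_subsamples >= 1,
            vars_per_subsample >= 2, subject_fraction > 0,
            subject_fraction <= 1)
  structure(list(n_subsamples = as.integer(n_subsamples),
                 vars_per_subsample = as.integer(vars_per_subsample),
                 max_order = as.integer(max_order), threshold = threshold,
                 subject_fraction = subject_fraction,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 max_active = as.integer(max_active), seed = seed),
            class = "stability_config")
}

# All terms up to `max_order` over the drawn variables: interactions use
# linear components only; polynomial main effects ride along with their
# base numeric variable.
subsample_terms <- function(vars, max_order) {
  out <- lapply(vars, new_term)
  if ("age" %in% vars) out <- c(out, list("age2", "age3"))
  if ("cal" %in% vars) out <- c(out, list("cal2", "cal3"))
  for (k in 2:min(max_order, length(vars)))
    out <- c(out, utils::combn(sort(vars), k, simplify = FALSE))
  names(out) <- vapply(out, term_label, "")
  out
}

#' Stability selection of interaction terms via subsampled LASSO-Cox
#'
#' Repeatedly draws a random subset of variables and subjects, builds the
#' design containing all interactions of the drawn variables up to
#' `max_order`, and fits an L1-penalized Cox model over a log-spaced
#' penalty grid. A term counts as selected in a subsample when its
#' coefficient (any of its design columns) is nonzero anywhere on the
#' grid; it is eligible only in subsamples whose variable subset contains
#' all of its variables. Terms whose selection frequency
#' (selected/eligible) reaches the threshold form the stable set.
#' Subsamples without events are redrawn (and counted).
#'
#' @param intervals Encoded intervals from [build_intervals()].
#' @param config A [stability_config()].
#' @return A `stability_result`: list with `frequencies` (data.frame term,
#'   order, eligible, selected, frequency), `stable_terms` (list of
#'   terms), `subsample_vars` (list of drawn variable sets, for audit),
#'   `n_redrawn`, and `config`.
#' @export
stability_select <- function(intervals, config = stability_config()) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      !is.null(intervals$intervals)) intervals <- intervals$intervals
  diseases <- attr(intervals, "diseases")
  pool <- c(diseases, "sex_female", "education", "age", "cal")
  if (config$vars_per_subsample > length(pool))
    stop("vars_per_subsample exceeds the number of variables (",
         length(pool), ")")
  if (!is.null(config$seed)) set.seed(config$seed)

  ids <- unique(intervals$person_id)
  n_draw <- max(1L, floor(config$subject_fraction * length(ids)))
  eligible <- selected <- integer(0)
  bump <- function(counts, labs) {
    new <- setdiff(labs, names(counts))
    if (length(new)) counts[new] <- 0L
    counts[labs] <- counts[labs] + 1L
    counts
  }
  subsample_vars <- vector("list", config$n_subsamples)
  n_redrawn <- 0L

  for (b in seq_len(config$n_subsamples)) {
    repeat {
      vars <- sort(sample(pool, config$vars_per_subsample))
      rows <- if (config$subject_fraction < 1)
        intervals$person_id %in% sample(ids, n_draw)
      else rep(TRUE, nrow(intervals))
      if (sum(intervals$event[rows]) > 0L) break
      n_redrawn <- n_redrawn + 1L
    }
    subsample_vars[[b]] <- vars
    terms <- subsample_terms(vars, config$max_order)
    dat <- intervals[rows, , drop = FALSE]
    des <- design_for_terms(terms, dat)
    mu <- colMeans(des$X)
    keep <- colMeans(des$X * des$X) - mu^2 > 0
    X <- des$X[, keep, drop = FALSE]
    y <- survival::Surv(dat$start, dat$stop, as.integer(dat$event))
    sel_terms <- character(0)
    if (ncol(X) >= 2L) {
      lp <- tryCatch(
        lasso_cox_path(X, dat$start, dat$stop, dat$event,
                       nlambda = config$n_lambda,
                       lambda_min_ratio = config$lambda_min_ratio,
                       max_active = config$max_active),
        error = function(e) NULL)
      if (!is.null(lp)) {
        nz <- colnames(X)[lp$ever_active]
        sel_terms <- unique(des$colmap$term[des$colmap$column %in% nz])
      }
    }
    eligible <- bump(eligible, names(terms))
    if (length(sel_terms)) selected <- bump(selected, sel_terms)
  }

  labs <- names(eligible)
  sel <- ifelse(labs %in% names(selected), selected[labs], 0L)
  freq <- data.frame(term = labs,
                     order = lengths(lapply(labs, parse_term)),
                     eligible = unname(eligible[labs]),
                     selected = unname(as.integer(sel)),
                     stringsAsFactors = FALSE)
  freq$frequency <- freq$selected / freq$eligible
  freq <- freq[order(-freq$frequency, freq$order, freq$term), ]
  rownames(freq) <- NULL
  stable <- lapply(freq$term[freq$frequency >= config$threshold], parse_term)
  structure(list(frequencies = freq, stable_terms = stable,
                 subsample_vars = subsample_vars, n_redrawn = n_redrawn,
                 config = config),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result: ", length(x$subsample_vars), " subsamples, ",
      nrow(x$frequencies), " terms tracked, ",
      length(x$stable_terms), " stable at threshold ",
      x$config$threshold, "\n", sep = "")
  invisible(x)
}

#' Unregularized refit of the stably selected terms
#'
#' Closes the stable term set hierarchically, adds all main effects, fits
#' an unpenalized Cox model on all available data, and reduces it by
#' hierarchical backward elimination at level `alpha` (main effects are
#' never removed). An empty stable set falls back to the main-effects
#' model with a warning.
#'
#' @param intervals Encoded intervals.
#' @param stable_terms List of terms (or serialized labels), e.g. the
#'   `stable_terms` of [stability_select()].
#' @param alpha Backward-elimination test level.
#' @return A `portfolio_cox_fit` with mode `"STABLE"`.
#' @export
refit_stable <- function(intervals, stable_terms, alpha = 0.001) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      !is.null(intervals$intervals)) intervals <- intervals$intervals
  diseases <- attr(intervals, "diseases")
  base <- main_effects_model(diseases, mode = "STABLE")
  inter <- Filter(function(t) length(t) >= 2L,
                  lapply(stable_terms, function(t)
                    if (is.character(t) && length(t) == 1L) parse_term(t)
                    else new_term(t)))
  if (!length(inter)) {
    if (!length(stable_terms))
      warning("empty stable term set: returning the main-effects fit")
    return(fit_portfolio_cox(intervals, base))
  }
  model <- model_spec(c(base$terms,
                        lapply(unique(unlist(lapply(inter, term_subsets))),
                               parse_term)),
                      mode = "STABLE")
  fit <- fit_portfolio_cox(intervals, model)
  backward_eliminate(intervals, fit, alpha)$fit
}
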