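#' Configuration for hierarchical interaction selection
#'
#' @param alpha Test level for both the Bonferroni forward cutoff
#'   (`alpha / n_c` per candidate) and backward cleanup (default 0.001, a
#'   deliberately conservative level).
#' @param max_order Highest interaction order M to attempt (default 6; the
#'   search also stops early at the first order where nothing is added).
#' @param mode `"ALL"` (interactions among diseases and intrinsic
#'   variables, relaxed forward step) or `"DIO"` (diseases only, no
#'   relaxation).
#' @param relaxed Override the mode's default relaxation flag.
#' @param backward_scope `"path"` (clean up only terms added during the
#'   current k-level, the default) or `"all"` (all removable terms).
#' @return A `selection_config`.
#' @export
selection_config <- function(alpha = 0.001, max_order = 6L,
                             mode = c("ALL", "DIO"), relaxed = NULL,
                             backward_scope = c("path", "all")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, max_order >= 2)
  structure(list(alpha = alpha, max_order = as.integer(max_order),
                 mode = mode,
                 relaxed = relaxed %||% (mode == "ALL"),
                 backward_scope = match.arg(backward_scope)),
            class = "selection_config")
}

#' All-main-effects model specification
#'
#' The starting point of every selection procedure and the term set of the
#' additive reference: one order-1 term per disease indicator, sex,
#' education, and centered age/calendar time with their squared and cubic
#' terms.
#'
#' @param diseases Disease labels of the encoded cohort.
#' @param mode Mode tag for the resulting [model_spec()].
#' @return A `model_spec` containing only order-1 terms.
#' @export
main_effects_model <- function(diseases, mode = "ALL") {
  model_spec(as.list(main_effect_vars(diseases)), mode = mode)
}

#' Main-effects-only (OME) reference fit
#'
#' Fits the additive reference model containing only order-1 terms: the
#' disease indicators, sex, education dummies, and the centered age and
#' calendar time with their squared and cubic terms. With the full
#' 14-disease catalogue this is a 26-column design (14 + 1 + 5 + 3 + 3).
#'
#' @param intervals Encoded intervals from [build_intervals()].
#' @return A `portfolio_cox_fit` with mode `"OME"`.
#' @export
build_ome <- function(intervals) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      !is.null(intervals$intervals)) intervals <- intervals$intervals
  diseases <- attr(intervals, "diseases")
  fit_portfolio_cox(intervals, main_effects_model(diseases, mode = "OME"))
}

# One trace row.
trace_row <- function(step, k, term, p, cutoff, action) {
  data.frame(step = step, k = k, term = term, p = p, cutoff = cutoff,
             action = action, stringsAsFactors = FALSE)
}

#' Hierarchical forward-backward selection of interaction terms
#'
#' Starting from the all-main-effects model, interactions of order
#' k = 2, ..., M are sought by adding a single k-way term to an existing
#' (k-1)-way term (hierarchical closure is maintained throughout, so an
#' added term brings its lower-order components with it). Each k-level:
#'
#' * Forward: enumerate the n_c candidate k-way terms; the Bonferroni
#'   cutoff is `alpha / n_c` with n_c fixed at the level's first
#'   enumeration. Non-relaxed: every candidate is refit against the
#'   current model and the lowest LRT p below the cutoff is added,
#'   repeatedly. Relaxed (for large candidate sets): candidates are fit
#'   once against the level's starting model, ordered by p, and swept in
#'   that order, immediately adding any whose p against the *current*
#'   model clears the cutoff and discarding the rest; discarded terms are
#'   re-offered once through forward selection before backward cleanup.
#' * Backward: masked significances are cleaned up at level `alpha`,
#'   removing one at a time the least significant removable term (one
#'   with no retained superset); main effects are never removed.
#'
#' The search terminates early at the first order where no k-way term is
#' selected. In `"DIO"` mode candidates are restricted to disease
#' indicators and the forward step is not relaxed.
#'
#' @param intervals Encoded intervals from [build_intervals()].
#' @param config A [selection_config()].
#' @return List: `model` (selected `model_spec`), `fit` (its
#'   `portfolio_cox_fit`), `trace` (data.frame log with columns step, k,
#'   term, p, cutoff, action; replaying added/removed rows onto the
#'   starting model reproduces `model`).
#' @export
select_interactions <- function(intervals, config = selection_config()) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      !is.null(intervals$intervals)) intervals <- intervals$intervals
  diseases <- attr(intervals, "diseases")
  if (length(diseases) < 2L) stop("need at least 2 primary variables")
  allowed <- if (config$mode == "DIO") diseases
             else c(diseases, setdiff(intrinsic_vars(), NULL))

  model <- main_effects_model(diseases, mode = config$mode)
  fit <- fit_portfolio_cox(intervals, model)
  trace <- list()
  step <- 0L

  cand_fit_p <- function(cand, cur_fit) {
    # LRT p of adding `cand` (plus closure) to the current model
    m2 <- add_term_closed(cur_fit$model, cand)
    f2 <- tryCatch(fit_portfolio_cox(intervals, m2, init = cur_fit$beta),
                   error = function(e) NULL)
    if (is.null(f2) || !f2$converged) return(list(p = NA_real_, fit = NULL))
    list(p = lrt(cur_fit, f2)$p, fit = f2)
  }

  for (k in 2:config$max_order) {
    validate_model_spec(model)
    added_this_k <- character(0)
    cands <- candidate_k_terms(model, k, allowed)
    if (!length(cands)) break
    n_c <- length(cands)
    cutoff <- config$alpha / n_c

    if (!config$relaxed) {
      repeat {
        cands <- candidate_k_terms(model, k, allowed)
        if (!length(cands)) break
        ps <- vector("list", length(cands))
        for (i in seq_along(cands)) ps[[i]] <- cand_fit_p(cands[[i]], fit)
        pv <- vapply(ps, `[[`, 0, "p")
        for (i in which(is.na(pv))) {
          step <- step + 1L
          trace[[step]] <- trace_row(step, k, term_label(cands[[i]]),
                                     NA_real_, cutoff, "skipped")
        }
        if (all(is.na(pv)) || min(pv, na.rm = TRUE) >= cutoff) break
        best <- which.min(pv)
        model <- ps[[best]]$fit$model
        fit <- ps[[best]]$fit
        added_this_k <- c(added_this_k, term_label(cands[[best]]))
        step <- step + 1L
        trace[[step]] <- trace_row(step, k, term_label(cands[[best]]),
                                   pv[best], cutoff, "added")
      }
    } else {
      tried <- character(0)
      discarded <- character(0)
      repeat {
        cands <- candidate_k_terms(model, k, allowed)
        labs <- vapply(cands, term_label, "")
        new <- !(labs %in% tried)
        if (!any(new)) break
        cands <- cands[new]; labs <- labs[new]
        tried <- c(tried, labs)
        # initial simultaneous estimation against the level's current model
        first <- lapply(cands, cand_fit_p, cur_fit = fit)
        p0 <- vapply(first, `[[`, 0, "p")
        ord <- order(p0, na.last = TRUE)
        changed <- FALSE
        for (i in ord) {
          if (is.na(p0[i])) {
            step <- step + 1L
            trace[[step]] <- trace_row(step, k, labs[i], NA_real_, cutoff,
                                       "skipped")
            next
          }
          res <- if (changed) cand_fit_p(cands[[i]], fit) else first[[i]]
          if (!is.na(res$p) && res$p < cutoff) {
            model <- res$fit$model; fit <- res$fit
            added_this_k <- c(added_this_k, labs[i])
            changed <- TRUE
            step <- step + 1L
            trace[[step]] <- trace_row(step, k, labs[i], res$p, cutoff,
                                       "added")
          } else {
            discarded <- c(discarded, labs[i])
            step <- step + 1L
            trace[[step]] <- trace_row(step, k, labs[i], res$p, cutoff,
                                       "discarded")
          }
        }
      }
      # re-offer discarded terms once through (non-relaxed) forward selection
      offer <- setdiff(discarded, names(model$terms))
      repeat {
        offer <- setdiff(offer, names(model$terms))
        if (!length(offer)) break
        ps <- lapply(offer, function(lab) cand_fit_p(parse_term(lab), fit))
        pv <- vapply(ps, `[[`, 0, "p")
        if (all(is.na(pv)) || min(pv, na.rm = TRUE) >= cutoff) break
        best <- which.min(pv)
        model <- ps[[best]]$fit$model; fit <- ps[[best]]$fit
        added_this_k <- c(added_this_k, offer[best])
        step <- step + 1L
        trace[[step]] <- trace_row(step, k, offer[best], pv[best], cutoff,
                                   "added")
        offer <- offer[-best]
      }
    }

    # backward cleanup at level alpha over the k-level's selection path
    bw <- backward_eliminate(intervals, fit, config$alpha,
                             within = if (config$backward_scope == "path")
                               added_this_k else NULL)
    fit <- bw$fit; model <- fit$model
    if (nrow(bw$trace)) {
      bw$trace$step <- step + seq_len(nrow(bw$trace))
      bw$trace$k <- k
      step <- step + nrow(bw$trace)
      trace <- c(trace, split(bw$trace, seq_len(nrow(bw$trace))))
    }
    validate_model_spec(model)
    if (!any(lengths(model$terms) == k)) break
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    trace_row(integer(0), integer(0), character(0), numeric(0), numeric(0),
              character(0))
  rownames(trace) <- NULL
  list(model = model, fit = fit, trace = trace)
}

# Hierarchical backward elimination at level `alpha`: repeatedly drop the
# least significant term among those with no retained superset (main
# effects are never candidates), until every removable term tests below
# alpha. `within` optionally restricts eligible terms.
backward_eliminate <- function(intervals, fit, alpha, within = NULL) {
  trace <- list()
  repeat {
    rem <- removable_terms(fit$model, within = within)
    if (!length(rem)) break
    ps <- vapply(rem, function(lab) {
      m2 <- drop_term(fit$model, lab)
      f2 <- tryCatch(fit_portfolio_cox(intervals, m2, init = fit$beta),
                     error = function(e) NULL)
      if (is.null(f2)) return(NA_real_)
      lrt(f2, fit)$p
    }, 0)
    if (all(is.na(ps))) break
    drop_i <- which.max(ps) # NAs (non-convergent refits) are skipped
    if (ps[drop_i] < alpha) break
    fit <- fit_portfolio_cox(intervals, drop_term(fit$model, rem[drop_i]))
    trace[[length(trace) + 1L]] <-
      trace_row(NA_integer_, NA_integer_, rem[drop_i], ps[drop_i], alpha,
                "removed")
  }
  list(fit = fit,
       trace = if (length(trace)) do.call(rbind, trace) else
         trace_row(integer(0), integer(0), character(0), numeric(0),
                   numeric(0), character(0)))
}

#' Replay a selection trace onto the starting main-effects model
#'
#' Applies the `added`/`removed` actions of a selection trace in order and
#' returns the resulting model — by construction equal to the selection's
#' final model, which makes traces an audit trail.
#'
#' @param trace Trace data.frame from [select_interactions()].
#' @param diseases Disease labels of the encoded cohort.
#' @param mode Model mode tag.
#' @return A `model_spec`.
#' @export
replay_trace <- function(trace, diseases, mode = "ALL") {
  model <- main_effects_model(diseases, mode = mode)
  for (i in seq_len(nrow(trace))) {
    if (trace$action[i] == "added")
      model <- add_term_closed(model, parse_term(trace$term[i]))
    else if (trace$action[i] == "removed")
      model <- drop_term(model, trace$term[i])
  }
  model
}
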