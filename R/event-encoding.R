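#' Encode a registry as counting-process risk intervals
#'
#' Converts person/event tables into start-stop risk intervals on the
#' years-since-HD timescale, the format the extended Cox model consumes.
#' Each subject contributes one interval per inter-diagnosis segment;
#' disease indicators are piecewise constant, 0 before the diagnosis date
#' and 1 from it onward. Diagnoses dated at or before the HD diagnosis are
#' on from time 0 (pre-existing conditions); a diagnosis on the final day
#' of follow-up flips the indicator on the terminal interval (zero-length
#' intervals are never produced). Intervals are left-open/right-closed in
#' the risk-set sense: a subject is at risk at t iff start < t <= stop.
#'
#' Age and calendar time are fixed at HD diagnosis, mean-centered over the
#' encoded cohort, and expanded with quadratic and cubic columns of the
#' centered values. Sex enters as a female dummy, education as 5 dummies
#' against the "none" reference.
#'
#' @param subjects,events Registry tables ([simulate_cohort()] /
#'   [read_registry()]).
#' @param diseases Disease labels to encode as indicator covariates;
#'   default: every non-administrative label observed in `events`.
#' @return List with `intervals` (data.frame: person_id, start, stop,
#'   event, then covariate columns; attributes `diseases` and `centering`)
#'   and `centering` (list with `mean_age`, `mean_calendar` in years).
#' @export
build_intervals <- function(subjects, events, diseases = NULL) {
  admin <- c("HD", "death", "emigration")
  if (is.null(diseases))
    diseases <- sort(setdiff(unique(events$label), admin))
  unknown <- setdiff(unique(events$label), c(admin, diseases))
  if (length(unknown))
    stop("unknown event label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(events[, c("person_id", "label")]))
    stop("more than one event per (person, label)")
  hd <- events[events$label == "HD", ]
  if (!all(subjects$person_id %in% hd$person_id))
    stop("every subject must have an HD event")
  if (any(events$date > subjects$end_date[match(events$person_id,
                                                subjects$person_id)]))
    stop("event dated after the subject's end of follow-up")

  pid <- subjects$person_id
  fup <- as.numeric(subjects$end_date - subjects$hd_date) / 365.25
  if (any(fup <= 0)) stop("non-positive follow-up time")
  death <- subjects$end_status == "death"

  age_hd <- as.numeric(subjects$hd_date - subjects$birth_date) / 365.25
  cal_hd <- 1970 + as.numeric(subjects$hd_date) / 365.25
  centering <- list(mean_age = mean(age_hd), mean_calendar = mean(cal_hd))

  ev <- events[events$label %in% diseases, ]
  ridx <- match(ev$person_id, pid)
  ev_t <- as.numeric(ev$date - subjects$hd_date[ridx]) / 365.25
  ev_fup <- fup[ridx]

  # interior breakpoints: strictly inside (0, follow-up)
  br <- data.table::data.table(pid = ev$person_id,
                               t = ev_t)[ev_t > 0 & ev_t < ev_fup]
  sdt <- data.table::data.table(pid = pid, fup = fup)
  m <- merge(sdt, br, by = "pid", all.x = TRUE)
  data.table::setorder(m, pid, t)
  t_ <- NULL # appease checks
  iv <- m[, {
    tt <- unique(t[!is.na(t)])
    list(start = c(0, tt), stop = c(tt, fup[1L]))
  }, by = "pid"]

  ord <- match(iv$pid, pid)
  terminal <- iv$stop == fup[ord]
  out <- data.frame(person_id = iv$pid, start = iv$start, stop = iv$stop,
                    event = terminal & death[ord])

  # disease indicators: on when onset <= interval start, or on the terminal
  # interval when the diagnosis falls on the final day
  for (d in diseases) {
    sel <- ev$label == d
    td <- rep(NA_real_, length(pid))
    td[ridx[sel]] <- ev_t[sel]
    tdi <- td[ord]
    out[[d]] <- as.numeric(!is.na(tdi) &
                             (tdi <= iv$start | (terminal & tdi >= iv$stop)))
  }

  out$sex_female <- as.numeric(subjects$sex[ord] == "female")
  for (lev in education_levels()[-1])
    out[[paste0("edu_", lev)]] <- as.numeric(subjects$education[ord] == lev)
  a <- age_hd[ord] - centering$mean_age
  cc <- cal_hd[ord] - centering$mean_calendar
  out$age <- a; out$age2 <- a^2; out$age3 <- a^3
  out$cal <- cc; out$cal2 <- cc^2; out$cal3 <- cc^3

  attr(out, "diseases") <- diseases
  attr(out, "centering") <- centering
  list(intervals = out, centering = centering)
}

#' Write encoded intervals as delimited text
#' @param intervals Interval data.frame from [build_intervals()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Disease prevalence at HD diagnosis and over the full trajectory
#'
#' For each disease and sex stratum, the share of subjects already
#' diagnosed at the time of HD diagnosis (`at_t0`: diagnosis dated on or
#' before the HD date) and the share ever diagnosed during observation
#' (`lifetime`). A `multimorbid` row counts subjects with at least one
#' co-occurring disease. Lifetime prevalence is always >= prevalence at
#' t = 0.
#'
#' @param subjects,events Registry tables.
#' @param diseases Disease labels; default: observed labels.
#' @return data.frame: disease, sex (`male`/`female`/`all`), n, at_t0,
#'   lifetime (proportions).
#' @export
prevalence_summary <- function(subjects, events, diseases = NULL) {
  admin <- c("HD", "death", "emigration")
  if (is.null(diseases))
    diseases <- sort(setdiff(unique(events$label), admin))
  ev <- events[events$label %in% diseases, ]
  idx <- match(ev$person_id, subjects$person_id)
  pre <- ev$date <= subjects$hd_date[idx]
  res <- list()
  for (sx in c("male", "female", "all")) {
    keep <- if (sx == "all") rep(TRUE, nrow(subjects)) else subjects$sex == sx
    ids <- subjects$person_id[keep]
    n <- length(ids)
    if (!n) next
    in_stratum <- ev$person_id %in% ids
    for (d in c(diseases, "multimorbid")) {
      if (d == "multimorbid") {
        life <- length(unique(ev$person_id[in_stratum]))
        t0 <- length(unique(ev$person_id[in_stratum & pre]))
      } else {
        sel <- in_stratum & ev$label == d
        life <- sum(sel)
        t0 <- sum(sel & pre)
      }
      res[[length(res) + 1L]] <- data.frame(
        disease = d, sex = sx, n = n, at_t0 = t0 / n, lifetime = life / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
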