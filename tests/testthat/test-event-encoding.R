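test_that("a three-diagnosis trajectory encodes into four cumulative intervals", {
  # schizophrenia at 2.6 y, cancer at 5.6 y, dementia at 7.5 y, death at 9 y
  reg <- manual_registry(list(list(
    end = 9, diagnoses = c(SCH = 2.6, CAN = 5.6, DEM = 7.5))))
  iv <- build_intervals(reg$subjects, reg$events,
                        diseases = c("CAN", "DEM", "SCH"))$intervals
  expect_identical(nrow(iv), 4L)
  expect_equal(iv$start, c(0, 2.6, 5.6, 7.5), tolerance = 0.01)
  expect_equal(iv$stop, c(2.6, 5.6, 7.5, 9.0), tolerance = 0.01)
  expect_equal(iv$SCH, c(0, 1, 1, 1))
  expect_equal(iv$CAN, c(0, 0, 1, 1))
  expect_equal(iv$DEM, c(0, 0, 0, 1))
  expect_equal(iv$event, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("pre-existing and absent diagnoses produce single intervals", {
  reg <- manual_registry(list(
    list(end = 4, status = "censored"),              # no post-HD diagnoses
    list(end = 3, diagnoses = c(HT = -2))))          # hypertension before HD
  iv <- build_intervals(reg$subjects, reg$events, diseases = "HT")$intervals
  p1 <- iv[iv$person_id == 1, ]; p2 <- iv[iv$person_id == 2, ]
  expect_identical(nrow(p1), 1L)
  expect_false(p1$event)
  expect_equal(p1$stop, 4, tolerance = 0.01)
  expect_identical(nrow(p2), 1L)
  expect_equal(p2$HT, 1)
  expect_true(p2$event)
})

test_that("a diagnosis on the death day flips the terminal interval only", {
  reg <- manual_registry(list(list(end = 3, diagnoses = c(A = 1, B = 3))))
  iv <- build_intervals(reg$subjects, reg$events,
                        diseases = c("A", "B"))$intervals
  expect_identical(nrow(iv), 2L) # no zero-length interval for B
  expect_equal(iv$B, c(0, 1))    # on during the terminal interval
  expect_true(all(iv$stop > iv$start))
})

test_that("encoding validates its inputs", {
  reg <- manual_registry(list(list(end = 3, diagnoses = c(A = 1))))
  bad <- reg$events
  bad$date[bad$label == "A"] <- as.Date("2099-01-01")
  expect_error(build_intervals(reg$subjects, bad, diseases = "A"),
               "after the subject")
  expect_error(build_intervals(reg$subjects, reg$events, diseases = "B"),
               "unknown event label")
  no_hd <- reg$events[reg$events$label != "HD", ]
  expect_error(build_intervals(reg$subjects, no_hd, diseases = "A"),
               "HD event")
})

test_that("intervals partition follow-up exactly for simulated cohorts", {
  for (seed in 1:6) {
    tc <- planted_config(diseases = LETTERS[1:5], onset = 0.25,
                         beta = c(A = 0.5), pre = 0.4)
    cohort <- simulate_cohort(tc, 200, seed = seed)
    iv <- build_intervals(cohort$subjects, cohort$events)$intervals
    s <- cohort$subjects
    fup <- as.numeric(s$end_date - s$hd_date) / 365.25
    iv <- iv[order(iv$person_id, iv$start), ]
    expect_identical(length(unique(iv$person_id)), nrow(s))
    expect_true(all(iv$start < iv$stop))
    first <- !duplicated(iv$person_id)
    last <- !duplicated(iv$person_id, fromLast = TRUE)
    expect_true(all(iv$start[first] == 0))
    # consecutive intervals within a person abut: no gaps, no overlaps
    same_p <- iv$person_id[-1] == iv$person_id[-nrow(iv)]
    expect_true(all(iv$start[-1][same_p] == iv$stop[-nrow(iv)][same_p]))
    # indicators never switch off within a person
    for (d in attr(iv, "diseases"))
      expect_true(all(diff(iv[[d]])[same_p] >= 0))
    # event only on a person's last interval and only for deaths
    expect_true(all(!iv$event[!last]))
    expect_identical(iv$event[last],
                     (s$end_status == "death")[match(iv$person_id[last],
                                                     s$person_id)])
    # person-years identity
    expect_equal(sum(iv$stop - iv$start), sum(fup))
  }
})

test_that("encoding is invariant to event-row order", {
  tc <- planted_config(diseases = LETTERS[1:4], onset = 0.3)
  cohort <- simulate_cohort(tc, 150, seed = 8)
  iv1 <- build_intervals(cohort$subjects, cohort$events)$intervals
  set.seed(1)
  shuffled <- cohort$events[sample(nrow(cohort$events)), ]
  iv2 <- build_intervals(cohort$subjects, shuffled)$intervals
  expect_equal(iv1, iv2, ignore_attr = TRUE)
})

test_that("centering and polynomial covariates are consistent", {
  tc <- planted_config()
  cohort <- simulate_cohort(tc, 300, seed = 12)
  enc <- build_intervals(cohort$subjects, cohort$events)
  iv <- enc$intervals
  first <- iv[!duplicated(iv$person_id), ]
  expect_equal(mean(first$age), 0, tolerance = 1e-9)
  expect_equal(mean(first$cal), 0, tolerance = 1e-9)
  expect_equal(iv$age2, iv$age^2)
  expect_equal(iv$cal3, iv$cal^3)
  expect_identical(enc$centering, attr(iv, "centering"))
})

test_that("prevalence distinguishes time-zero from lifetime", {
  reg <- manual_registry(list(
    list(end = 5, diagnoses = c(DIA = -1)),   # diabetes before HD
    list(end = 6, diagnoses = c(CAN = 2)),    # cancer after HD
    list(end = 4)))
  pv <- prevalence_summary(reg$subjects, reg$events,
                           diseases = c("CAN", "DIA"))
  all_s <- pv[pv$sex == "all", ]
  dia <- all_s[all_s$disease == "DIA", ]
  expect_equal(dia$at_t0, 1 / 3)
  expect_equal(dia$lifetime, 1 / 3)
  can <- all_s[all_s$disease == "CAN", ]
  expect_equal(can$at_t0, 0)       # post-HD: lifetime only
  expect_equal(can$lifetime, 1 / 3)
  mm <- all_s[all_s$disease == "multimorbid", ]
  expect_equal(mm$lifetime, 2 / 3)
  expect_true(all(pv$lifetime >= pv$at_t0))
})
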