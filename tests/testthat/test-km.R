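test_that("product-limit estimate matches a hand computation", {
  # deaths at 10, 20; censored at 30, 40: S = (3/4)(2/3) = 1/2
  expect_warning(
    res <- km_mortality(c(10, 20, 30, 40), c(1, 1, 0, 0), horizon_days = 50),
    "carried forward")
  expect_equal(res$cumulative_mortality, 0.5, tolerance = 1e-12)
  expect_equal(res$n_events, 2L)
  expect_equal(res$n_at_risk_start, 4L)
  expect_true(res$extrapolated)  # horizon beyond last observed time
  expect_true(res$ci_lo <= 0.5 && res$ci_hi >= 0.5)
  expect_gt(res$variance, 0)
})

test_that("KM equals the empirical proportion when nothing is censored early", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    t_death <- sample(1:364, n, replace = TRUE)
    dead <- runif(n) < 0.3
    time <- ifelse(dead, t_death, 400)  # survivors observed past the horizon
    res <- suppressWarnings(km_mortality(time, as.integer(dead), 365))
    expect_equal(res$cumulative_mortality, mean(dead), tolerance = 1e-12)
  }
})

test_that("KM output is invariant to record order and post-horizon changes", {
  set.seed(21)
  time <- c(sample(1:700, 60), rep(400, 20))
  event <- rbinom(80, 1, 0.4)
  res <- km_mortality(time, event, 365)
  perm <- sample(80)
  expect_equal(km_mortality(time[perm], event[perm], 365), res)
  # what happens after the horizon cannot change the estimate at the horizon
  time2 <- ifelse(time > 365, time + sample(1:100, 80, replace = TRUE), time)
  res2 <- km_mortality(time2, event, 365)
  expect_equal(res2$cumulative_mortality, res$cumulative_mortality,
               tolerance = 1e-12)
})

test_that("degenerate follow-up is flagged rather than invented", {
  expect_warning(res <- km_mortality(rep(1, 10), rep(0L, 10), 365),
                 "degenerate|no deaths")
  expect_equal(res$cumulative_mortality, 0)
  expect_equal(res$ci_lo, 0)
  expect_error(km_mortality(numeric(0), integer(0), 365),
               class = "ltfu_validation_error")
  expect_error(km_mortality(c(1, -2), c(0, 1), 365),
               class = "ltfu_validation_error")
  expect_error(km_mortality(c(1, 2), c(0, 2), 365),
               class = "ltfu_validation_error")
})

test_that("nine-month rule classifies the toy cohort by hand", {
  cls <- classify_ltfu(toy_cohort())
  expect_equal(as.character(cls$ltfu_status),
               c("lost", "lost", "retained", "retained", "retained"))
  s <- summarize_ltfu(cls)
  expect_equal(s$r, 2 / 5)
  expect_equal(s$n_eligible, 5L)
  # idempotent and count-conserving
  cls2 <- classify_ltfu(cls)
  expect_equal(cls2$ltfu_status, cls$ltfu_status)
  expect_equal(s$n_lost + s$n_retained, s$n_eligible)
})

test_that("classification edge cases behave", {
  closure <- as.Date("2007-01-31")
  # everyone seen on closure day: nobody lost
  seen <- toy_cohort()
  seen$last_visit <- closure
  expect_equal(summarize_ltfu(classify_ltfu(seen))$r, 0)
  # recent starters are ineligible
  late <- tibble::tibble(patient_id = "L1", art_start = closure - 100,
                         last_visit = closure - 50,
                         death_date = as.Date(NA))
  both <- dplyr::bind_rows(toy_cohort(), late)
  cls <- classify_ltfu(both)
  expect_equal(as.character(cls$ltfu_status[6]), "ineligible")
  # an all-ineligible cohort has no defined r
  expect_warning(s <- summarize_ltfu(classify_ltfu(late)), "undefined|eligible")
  expect_true(is.na(s$r))
  # a programme-ascertained death is a known outcome, not loss to follow-up
  dead <- toy_cohort()
  dead$death_date[1] <- dead$art_start[1] + 50
  cls <- classify_ltfu(dead)
  expect_equal(as.character(cls$ltfu_status[1]), "retained")
  expect_error(classify_ltfu(toy_cohort()[0, ]),
               class = "ltfu_validation_error")
})

test_that("traced mortality equals the crude proportion absent censoring", {
  # 124 deaths among 621 traced, all with the full horizon observable
  sm <- summarize_programme(traced_cohort(621, 124))
  expect_equal(sm$m_l, 124 / 621, tolerance = 1e-12)
  expect_equal(sm$m_l_source, "traced")
  expect_equal(sm$n_traced, 621L)
  expect_equal(sm$n_traced_dead, 124L)
})

test_that("zero-loss cohorts collapse the naive and retained estimates", {
  closure <- as.Date("2007-01-31")
  n <- 40
  set.seed(5)
  start <- closure - sample(700:900, n, replace = TRUE)
  death <- rep(as.Date(NA), n)
  death[1:6] <- start[1:6] + sample(30:300, 6)
  coh <- tibble::tibble(patient_id = as.character(1:n), art_start = start,
                        last_visit = closure - sample(0:60, n, replace = TRUE),
                        death_date = death)
  sm <- summarize_programme(coh)
  expect_equal(sm$n_lost, 0L)
  expect_equal(sm$m_u, sm$m_nl, tolerance = 1e-12)
})

test_that("the naive estimate sits below the corrected one when the lost die more", {
  sim <- simulate_cohort(4000, true_r = 0.3, true_m_nl = 0.03,
                         true_m_l = 0.25, seed = 3)
  sm <- summarize_programme(sim$cohort)
  res <- correct_mortality(sm)
  expect_lt(sm$m_u, res$m_c)
})

test_that("cohort CSV round-trips and rejects malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  coh <- traced_cohort(20, 5, n_retained = 0)
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$art_start, coh$art_start)
  expect_equal(back$traced_vital_status, coh$traced_vital_status)
  # a visit before ART start is invalid
  bad <- coh
  bad$last_visit[3] <- bad$art_start[3] - 10
  write_cohort(bad, path)
  expect_error(read_cohort(path), class = "ltfu_validation_error")
  expect_warning(ok <- read_cohort(path, skip_bad = TRUE), "dropped")
  expect_equal(nrow(ok), 19)
})
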