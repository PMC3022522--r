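#' Simulate a patient-level ART cohort with known ground truth
#'
#' Generates programme-visible patient records (ART start, last visit,
#' ascertained death date, traced vital status) from known true values of
#' the LTFU proportion, mortality among retained patients and mortality
#' among lost patients, so the whole pipeline — classification,
#' Kaplan-Meier estimation, correction, Monte-Carlo intervals — can be
#' validated end to end against truth.
#'
#' Mechanics: each patient is lost with probability `true_r`; death times
#' follow a constant-hazard exponential law calibrated so that
#' `P(T <= horizon) ` equals the group's true mortality (an optional
#' `early_death_multiplier` concentrates hazard in the first 90 days while
#' preserving that calibration, reflecting that patients who disengage
#' often die soon after). Lost patients stop visiting early enough to
#' satisfy the nine-month rule and their deaths are invisible to the
#' programme — tracing alone (a `tracing_fraction` subsample) reveals vital
#' status at the horizon. Retained patients keep visiting until closure;
#' their deaths within follow-up are ascertained. Enrolment is uniform over
#' `enrolment_span_days` ending `window_days + horizon_days` before
#' closure, so every patient is LTFU-eligible with a fully observable
#' horizon.
#'
#' @param n_patients Cohort size.
#' @param true_r True proportion lost to follow-up.
#' @param true_m_nl,true_m_l True cumulative mortality at the horizon among
#'   retained and lost patients.
#' @param horizon_days Analysis horizon (default 365).
#' @param window_days LTFU window used to place visit dates (default 274).
#' @param enrolment_span_days Length of the enrolment period (default
#'   1095).
#' @param tracing_fraction Fraction of lost patients whose vital status is
#'   ascertained (default 0.17, the order seen in outreach programmes).
#' @param early_death_multiplier Hazard multiplier for days 0-90 (default 1
#'   = constant hazard).
#' @param closure_date Database closure date (default `"2007-01-31"`).
#' @param seed Integer seed; the same seed yields a byte-identical cohort.
#' @return A list of class `ltfu_sim`: `cohort` (programme-visible tibble
#'   in the [read_cohort()] dialect), `truth` (per-patient tibble with
#'   `true_lost`, `true_death_day`) and `params`.
#' @examples
#' sim <- simulate_cohort(2000, true_r = 0.4, true_m_nl = 0.02,
#'                        true_m_l = 0.2, seed = 7)
#' summarize_programme(sim$cohort)
#' @export
simulate_cohort <- function(n_patients,
                            true_r = 0.405,
                            true_m_nl = 0.022,
                            true_m_l = 0.20,
                            horizon_days = 365,
                            window_days = 274,
                            enrolment_span_days = 1095,
                            tracing_fraction = 0.17,
                            early_death_multiplier = 1,
                            closure_date = as.Date("2007-01-31"),
                            seed = NULL) {
  if (n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "ltfu_validation_error")
  }
  assert_prob(true_r, "true_r")
  assert_prob(true_m_nl, "true_m_nl")
  assert_prob(true_m_l, "true_m_l")
  assert_prob(tracing_fraction, "tracing_fraction")
  assert_positive(horizon_days, "horizon_days")
  assert_positive(window_days, "window_days")
  if (enrolment_span_days < 1) {
    abort(paste("`enrolment_span_days` must be at least 1 day for anyone",
                "to be enrolled and LTFU-eligible."),
          class = "ltfu_validation_error")
  }
  closure_date <- as.Date(closure_date)
  gen <- function() {
    last_enrol <- closure_date - window_days - horizon_days
    start <- last_enrol - floor(runif(n_patients, 0, enrolment_span_days))
    lost <- runif(n_patients) < true_r
    # draw per group so the calibration applies to each group's mortality
    death_day <- rep(NA_real_, n_patients)
    death_day[lost] <- draw_death_day(sum(lost), true_m_l, horizon_days,
                                      early_death_multiplier)
    death_day[!lost] <- draw_death_day(sum(!lost), true_m_nl, horizon_days,
                                       early_death_multiplier)
    follow_to_closure <- as.numeric(closure_date - start)

    last_visit <- rep(closure_date, n_patients)
    death_date <- rep(as.Date(NA), n_patients)
    # Lost: last visit well before closure (gap > window); deaths invisible.
    gap <- window_days + 1 + floor(runif(n_patients, 0, horizon_days / 2))
    lv_lost <- closure_date - pmin(gap, follow_to_closure)
    # a lost patient who died early stopped visiting before dying
    died_early <- lost & death_day < as.numeric(lv_lost - start)
    lv_lost[died_early] <- start[died_early] +
      pmax(floor(death_day[died_early]) - 1, 0)
    last_visit[lost] <- lv_lost[lost]
    # Retained: visits continue to (near) closure; deaths within follow-up
    # are ascertained by the programme.
    ret <- !lost
    died_obs <- ret & death_day <= follow_to_closure
    jitter <- floor(runif(n_patients, 0, min(window_days - 1, 60)))
    last_visit[ret] <- closure_date - jitter[ret]
    dd <- start + floor(death_day)
    death_date[died_obs] <- dd[died_obs]
    last_visit[died_obs] <- pmax(start[died_obs],
                                 dd[died_obs] - floor(runif(sum(died_obs),
                                                            0, 30)))
    # Tracing subsample of lost patients: vital status at the horizon.
    traced <- lost & runif(n_patients) < tracing_fraction
    status <- rep(NA_character_, n_patients)
    status[traced] <- ifelse(death_day[traced] <= horizon_days,
                             "dead", "alive")
    cohort <- tibble(
      patient_id = sprintf("P%06d", seq_len(n_patients)),
      art_start = start,
      last_visit = as.Date(last_visit),
      death_date = death_date,
      traced_vital_status = status
    )
    truth <- tibble(
      patient_id = cohort$patient_id,
      true_lost = lost,
      true_death_day = death_day,
      died_by_horizon = death_day <= horizon_days
    )
    list(cohort = cohort, truth = truth)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out$params <- list(n_patients = n_patients, true_r = true_r,
                     true_m_nl = true_m_nl, true_m_l = true_m_l,
                     true_m_c = (1 - true_r) * true_m_nl + true_r * true_m_l,
                     horizon_days = horizon_days, window_days = window_days,
                     enrolment_span_days = enrolment_span_days,
                     tracing_fraction = tracing_fraction,
                     early_death_multiplier = early_death_multiplier,
                     closure_date = as.character(closure_date), seed = seed)
  structure(out, class = "ltfu_sim")
}

# Death times (days) from a piecewise-constant-hazard law calibrated so
# P(T <= horizon) = m. With multiplier k the hazard is k*h on (0, 90] and
# h on (90, horizon]; h solves k*h*90 + h*(horizon - 90) = -log(1 - m).
draw_death_day <- function(n, m, horizon, multiplier = 1, ...) {
  if (n == 0) return(numeric(0))
  if (m == 0) return(rep(Inf, n))
  if (m == 1) return(runif(n, 0, horizon))
  total_h <- -log(1 - m)
  if (multiplier == 1) {
    return(rexp(n, rate = total_h / horizon))
  }
  brk <- min(90, horizon)
  h <- total_h / (multiplier * brk + (horizon - brk))
  u <- runif(n)
  cum_brk <- multiplier * h * brk
  t <- ifelse(-log(1 - u) <= cum_brk,
              -log(1 - u) / (multiplier * h),
              brk + (-log(1 - u) - cum_brk) / h)
  t
}

#' @export
print.ltfu_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic ART cohort: %d patients ",
                     "(true r = %.3f, M_NL = %.3f, M_L = %.3f, ",
                     "true M_C = %.4f)\n"),
              p$n_patients, p$true_r, p$true_m_nl, p$true_m_l, p$true_m_c))
  invisible(x)
}

#' Write a simulated cohort with its ground-truth sidecar
#'
#' Emits `cohort.csv` in the [read_cohort()] dialect plus `truth.json`
#' holding the generator parameters and true values.
#'
#' @param sim An `ltfu_sim` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ltfu_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(sim$params, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
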