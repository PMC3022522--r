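#' Read and write patient-level cohort tables
#'
#' The cohort CSV dialect has columns `patient_id`, `art_start`,
#' `last_visit`, `death_date` (empty allowed) and optionally
#' `traced_vital_status` (`alive`, `dead` or `unknown`, for tracing-study
#' data), with ISO 8601 dates. Invariants (`last_visit >= art_start`,
#' `death_date >= art_start`) are checked on read and violations reported
#' with their row numbers.
#'
#' @param path File path.
#' @param data A cohort tibble.
#' @param skip_bad Drop invalid rows with a warning instead of erroring.
#' @return `read_cohort()` returns a tibble with `Date` columns;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, skip_bad = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ltfu_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          art_start = readr::col_date(),
                          last_visit = readr::col_date(),
                          death_date = readr::col_date(),
                          .default = readr::col_character()
                        ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    msg <- paste0("unparseable cohort rows (line, issue): ",
                  paste(sprintf("%d: %s", probs$row, probs$expected),
                        collapse = "; "))
    if (skip_bad) warn(msg) else abort(msg, class = "ltfu_io_error")
  }
  validate_cohort(df, skip_bad = skip_bad)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  cols <- intersect(c("patient_id", "art_start", "last_visit", "death_date",
                      "traced_vital_status"), names(data))
  readr::write_csv(dplyr::select(as_tibble(data), dplyr::all_of(cols)), path,
                   na = "")
  invisible(path)
}

validate_cohort <- function(data, skip_bad = FALSE) {
  df <- as_tibble(data)
  need <- setdiff(c("patient_id", "art_start", "last_visit"), names(df))
  if (length(need)) {
    abort(paste0("cohort is missing column(s): ", paste(need, collapse = ", ")),
          class = "ltfu_validation_error")
  }
  if (!"death_date" %in% names(df)) df$death_date <- as.Date(NA)
  bad <- which(df$last_visit < df$art_start |
                 (!is.na(df$death_date) & df$death_date < df$art_start) |
                 is.na(df$art_start) | is.na(df$last_visit))
  if (length(bad)) {
    msg <- paste0("invalid patient records at row(s): ",
                  paste(head(bad, 20), collapse = ", "))
    if (skip_bad) {
      warn(paste0(msg, " (dropped)"))
      df <- df[-bad, ]
    } else {
      abort(msg, class = "ltfu_validation_error")
    }
  }
  df
}

#' Classify patients as lost to follow-up
#'
#' Applies the nine-month rule: relative to the database closure date
#' (by default the most recent visit recorded in the cohort), a patient is
#'
#' * `ineligible` if ART started less than `window_days` before closure
#'   (they never had the chance to be classified lost);
#' * `retained` if their death was ascertained by the programme
#'   (`death_date` present) — a known outcome is not loss to follow-up —
#'   or if their last visit is within `window_days` of closure;
#' * `lost` otherwise (last visit more than `window_days` before closure).
#'
#' @param data A cohort tibble (see [read_cohort()]).
#' @param window_days LTFU window; default 274 days (nine months of 30.44
#'   days, rounded).
#' @param closure_date Database closure date; defaults to the latest
#'   `last_visit` in the cohort.
#' @return The cohort with an `ltfu_status` factor column added
#'   (`retained`, `lost`, `ineligible`). Classification is idempotent and
#'   conserves counts: every eligible patient is exactly one of
#'   lost/retained.
#' @seealso [summarize_ltfu()] for the proportion lost with its CI.
#' @export
classify_ltfu <- function(data, window_days = 274, closure_date = NULL) {
  assert_positive(window_days, "window_days")
  df <- validate_cohort(data)
  if (nrow(df) == 0) {
    abort("empty cohort.", class = "ltfu_validation_error")
  }
  closure_date <- as.Date(closure_date %||% max(df$last_visit))
  if (any(df$last_visit > closure_date)) {
    abort("closure_date precedes a recorded visit.",
          class = "ltfu_validation_error")
  }
  days_on_study <- as.numeric(closure_date - df$art_start)
  gap <- as.numeric(closure_date - df$last_visit)
  status <- dplyr::case_when(
    days_on_study < window_days ~ "ineligible",
    !is.na(df$death_date) ~ "retained",
    gap > window_days ~ "lost",
    TRUE ~ "retained"
  )
  df$ltfu_status <- factor(status, levels = c("retained", "lost", "ineligible"))
  attr(df, "closure_date") <- closure_date
  attr(df, "window_days") <- window_days
  df
}

#' Summarise loss to follow-up
#'
#' Counts eligible, lost and retained patients from a cohort classified by
#' [classify_ltfu()] and returns the proportion lost `r` with a Jeffreys
#' binomial 95% CI.
#'
#' @param data Output of [classify_ltfu()] (or a cohort, which is
#'   classified first with the `...` arguments).
#' @param ... Passed to [classify_ltfu()] when `data` lacks `ltfu_status`.
#' @return One-row tibble: `n`, `n_eligible`, `n_lost`, `n_retained`,
#'   `n_ineligible`, `r`, `r_lo`, `r_hi`. With no eligible patients `r` is
#'   `NA` with a warning.
#' @export
summarize_ltfu <- function(data, ...) {
  if (!"ltfu_status" %in% names(data)) data <- classify_ltfu(data, ...)
  n_lost <- sum(data$ltfu_status == "lost")
  n_ret <- sum(data$ltfu_status == "retained")
  n_inel <- sum(data$ltfu_status == "ineligible")
  n_elig <- n_lost + n_ret
  if (n_elig == 0) {
    warn("no patients eligible for LTFU classification; r undefined.")
    r <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    r <- n_lost / n_elig
    ci <- jeffreys_ci(n_lost, n_elig)
  }
  tibble(n = nrow(data), n_eligible = n_elig, n_lost = n_lost,
         n_retained = n_ret, n_ineligible = n_inel,
         r = r, r_lo = ci[1], r_hi = ci[2])
}

#' Kaplan-Meier cumulative mortality at a horizon
#'
#' Product-limit estimate of cumulative mortality `1 - S(horizon)` with
#' Greenwood variance and a confidence interval (complementary log-log
#' transform by default, which respects the `[0, 1]` boundary). Computed via
#' [survival::survfit()]. With no censoring before the horizon the estimate
#' equals the empirical proportion of deaths.
#'
#' @param time Follow-up durations in days (from ART start).
#' @param event Death indicator (0/1 or logical).
#' @param horizon_days Horizon at which mortality is evaluated.
#' @param conf_type CI transform: `"cloglog"` (default), `"log"` or
#'   `"linear"`.
#' @param level Confidence level, default 0.95.
#' @return One-row tibble: `horizon_days`, `cumulative_mortality`,
#'   `variance` (Greenwood, of the survival/mortality estimate), `ci_lo`,
#'   `ci_hi`, `n_at_risk_start`, `n_events` (events by the horizon), and
#'   `extrapolated` — `TRUE` when the risk set ran out before the horizon
#'   and the last estimate is carried forward.
#' @examples
#' km_mortality(c(10, 20, 30, 40), c(1, 1, 0, 0), horizon_days = 50)
#' @export
km_mortality <- function(time, event, horizon_days,
                         conf_type = c("cloglog", "log", "linear"),
                         level = 0.95) {
  conf_type <- match.arg(conf_type)
  assert_positive(horizon_days, "horizon_days")
  if (length(time) == 0) {
    abort("at least one subject is required.", class = "ltfu_validation_error")
  }
  if (anyNA(time) || any(time < 0)) {
    abort("`time` must be non-negative.", class = "ltfu_validation_error")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) {
    abort("`event` must be binary.", class = "ltfu_validation_error")
  }
  ct <- switch(conf_type, cloglog = "log-log", log = "log", linear = "plain")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = ct, conf.int = level)
  last_time <- max(time)
  extrapolated <- horizon_days > last_time
  sm <- summary(fit, times = min(horizon_days, last_time), extend = TRUE)
  surv <- sm$surv
  se <- sm$std.err  # Greenwood standard error of S(t)
  if (sum(event) == 0) {
    # no deaths: degenerate estimate at 0 with an honest warning when the
    # risk set vanished early
    if (extrapolated || all(time < horizon_days)) {
      warn("no deaths observed and follow-up ends before the horizon; mortality 0 with a degenerate CI.")
    }
    return(tibble(horizon_days = horizon_days, cumulative_mortality = 0,
                  variance = 0, ci_lo = 0, ci_hi = 0,
                  n_at_risk_start = length(time), n_events = 0L,
                  extrapolated = extrapolated))
  }
  if (extrapolated) {
    warn("horizon beyond last observed time; estimate carried forward.")
  }
  # mortality CI = complement of the survival CI, clipped to [0, 1]
  ci_lo <- max(0, 1 - sm$upper)
  ci_hi <- min(1, 1 - sm$lower)
  if (is.na(ci_lo)) ci_lo <- 0
  if (is.na(ci_hi)) ci_hi <- 1
  tibble(horizon_days = horizon_days,
         cumulative_mortality = 1 - surv,
         variance = se^2,
         ci_lo = ci_lo, ci_hi = ci_hi,
         n_at_risk_start = length(time),
         n_events = sum(event[time <= horizon_days]),
         extrapolated = extrapolated)
}

#' Derive a programme summary from patient-level records
#'
#' Runs the full patient-level pipeline: classify loss to follow-up
#' ([classify_ltfu()]), then Kaplan-Meier mortality at the horizon for
#'
#' * retained patients (`m_nl`), censored at last visit (or at closure with
#'   `censor_at = "closure"`), deaths ascertained by the programme counted;
#' * all eligible patients with lost patients censored at last visit and
#'   contributing no deaths (`m_u` — the naive estimate this package
#'   exists to correct);
#' * traced lost patients (`m_l`, `m_l_source = "traced"`) when the cohort
#'   carries `traced_vital_status`: a patient traced `dead` counts as a
#'   death (at `death_date` when recorded, otherwise at the horizon, so
#'   that with no earlier censoring the estimate equals the crude traced
#'   proportion); `alive` is censored at the horizon.
#'
#' When no tracing data exist `m_l` is `NA` with `m_l_source = "predicted"`
#' and the caller applies [predict_mortality_lost()].
#'
#' @param data Cohort tibble.
#' @param horizon_days Analysis horizon (default 365).
#' @param window_days LTFU window (default 274).
#' @param closure_date See [classify_ltfu()].
#' @param label Programme label for the summary row.
#' @param censor_at Censoring for retained patients: `"last_visit"`
#'   (default) or `"closure"`.
#' @return A one-row programme-summary tibble (see [programme_summary()])
#'   with naive-estimate columns `m_u`, `m_u_lo`, `m_u_hi` appended.
#' @export
summarize_programme <- function(data, horizon_days = 365, window_days = 274,
                                closure_date = NULL, label = "programme",
                                censor_at = c("last_visit", "closure")) {
  censor_at <- match.arg(censor_at)
  assert_positive(horizon_days, "horizon_days")
  df <- classify_ltfu(data, window_days = window_days,
                      closure_date = closure_date)
  closure <- attr(df, "closure_date")
  ltfu <- summarize_ltfu(df)

  start <- df$art_start
  censor_point <- if (censor_at == "last_visit") df$last_visit else closure
  death_t <- as.numeric(df$death_date - start)
  censor_t <- pmax(as.numeric(censor_point - start), 0)
  # programme-visible deaths: retained patients with a death date
  ret <- df$ltfu_status == "retained"
  lost <- df$ltfu_status == "lost"
  died <- ret & !is.na(death_t)
  p_time <- ifelse(died, death_t, censor_t)
  p_event <- as.integer(died)

  km_nl <- km_mortality(p_time[ret], p_event[ret], horizon_days)
  km_u <- km_mortality(p_time[ret | lost], p_event[ret | lost], horizon_days)

  m_l <- NA_real_; m_l_ci <- c(NA_real_, NA_real_)
  m_l_source <- "predicted"
  n_traced <- NA_integer_; n_traced_dead <- NA_integer_
  if ("traced_vital_status" %in% names(df)) {
    traced <- lost & !is.na(df$traced_vital_status) &
      df$traced_vital_status %in% c("alive", "dead")
    if (any(traced)) {
      t_dead <- df$traced_vital_status[traced] == "dead"
      t_time <- ifelse(t_dead & !is.na(death_t[traced]),
                       pmin(death_t[traced], horizon_days), horizon_days)
      km_l <- km_mortality(t_time, as.integer(t_dead), horizon_days)
      m_l <- km_l$cumulative_mortality
      m_l_ci <- c(km_l$ci_lo, km_l$ci_hi)
      m_l_source <- "traced"
      n_traced <- sum(traced)
      n_traced_dead <- sum(t_dead)
    }
  }

  out <- programme_summary(
    label = label,
    n_eligible = ltfu$n_eligible,
    n_lost = ltfu$n_lost,
    r = ltfu$r,
    m_nl = km_nl$cumulative_mortality,
    m_nl_ci = if (km_nl$ci_lo <= km_nl$cumulative_mortality &&
                  km_nl$ci_hi >= km_nl$cumulative_mortality)
      c(km_nl$ci_lo, km_nl$ci_hi) else NULL,
    m_l = m_l,
    m_l_ci = if (!anyNA(m_l_ci)) m_l_ci else NULL,
    m_l_source = m_l_source,
    horizon_days = horizon_days,
    n_deaths_retained = km_nl$n_events,
    n_traced = n_traced,
    n_traced_dead = n_traced_dead
  )
  out$m_u <- km_u$cumulative_mortality
  out$m_u_lo <- km_u$ci_lo
  out$m_u_hi <- km_u$ci_hi
  out$r_lo <- ltfu$r_lo
  out$r_hi <- ltfu$r_hi
  out
}
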