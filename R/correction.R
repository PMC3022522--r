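#' Assemble a programme-level summary row
#'
#' A programme summary is the unit of analysis for the loss-to-follow-up
#' (LTFU) correction: the proportion of patients lost (`r`), cumulative
#' mortality among patients retained in care (`m_nl`) and — observed via
#' tracing, predicted from the meta-regression, or assumed — cumulative
#' mortality among patients lost (`m_l`), all over the same analysis horizon.
#'
#' All proportions are stored as fractions in `[0, 1]`; percentages appear
#' only at input (with `units = "percent"`) and in printed output.
#'
#' @param label Short programme identifier.
#' @param m_nl Mortality among patients retained in care, a proportion.
#' @param m_l Mortality among patients lost to follow-up, a proportion, or
#'   `NA` if it is to be predicted from the meta-regression.
#' @param r Proportion of patients lost to follow-up. If omitted it is
#'   computed as `n_lost / n_eligible`.
#' @param n_eligible,n_lost Counts behind `r`: patients at risk of LTFU
#'   classification and patients classified lost.
#' @param m_nl_ci,m_l_ci Optional length-2 vectors `(low, high)` of 95% CI
#'   bounds for `m_nl` and `m_l`.
#' @param m_l_source One of `"traced"`, `"predicted"`, `"assumed"`.
#' @param horizon_days Analysis horizon in days (e.g. 365 for 1-year
#'   mortality).
#' @param n_deaths_retained,n_traced,n_traced_dead Optional counts used by
#'   the binomial Monte-Carlo modes: deaths among retained patients, lost
#'   patients whose vital status was ascertained by tracing, and deaths among
#'   those traced.
#' @param units `"fraction"` (default) or `"percent"`; with `"percent"` all
#'   proportions and CI bounds are divided by 100 on input.
#'
#' @return A one-row tibble with columns `label`, `n_eligible`, `n_lost`,
#'   `r`, `m_nl`, `m_nl_lo`, `m_nl_hi`, `m_l`, `m_l_lo`, `m_l_hi`,
#'   `m_l_source`, `horizon_days`, `n_deaths_retained`, `n_traced`,
#'   `n_traced_dead`.
#' @examples
#' # The western-Kenya tracing case: 3,624 of 8,977 patients lost,
#' # 2.2% mortality among those retained, 20% among those traced.
#' programme_summary("AMPATH", m_nl = 0.022, m_l = 0.20, r = 0.405,
#'                   n_eligible = 8977, n_lost = 3624, m_l_source = "traced")
#' @export
programme_summary <- function(label,
                              m_nl,
                              m_l = NA_real_,
                              r = NULL,
                              n_eligible = NA_integer_,
                              n_lost = NA_integer_,
                              m_nl_ci = NULL,
                              m_l_ci = NULL,
                              m_l_source = c("traced", "predicted", "assumed"),
                              horizon_days = 365,
                              n_deaths_retained = NA_integer_,
                              n_traced = NA_integer_,
                              n_traced_dead = NA_integer_,
                              units = c("fraction", "percent")) {
  units <- match.arg(units)
  m_l_source <- match.arg(m_l_source)
  rescale <- function(x) {
    if (is.null(x)) NULL else if (units == "percent") x / 100 else x
  }
  m_nl <- rescale(m_nl)
  m_l <- rescale(m_l)
  m_nl_ci <- rescale(m_nl_ci)
  m_l_ci <- rescale(m_l_ci)
  if (is.null(r)) {
    if (is.na(n_eligible) || is.na(n_lost) || n_eligible <= 0) {
      abort("supply `r` directly or both `n_eligible` (> 0) and `n_lost`.",
            class = "ltfu_validation_error")
    }
    r <- n_lost / n_eligible
  } else {
    r <- rescale(r)
  }
  assert_prob(r, "r")
  assert_prob(m_nl, "m_nl")
  assert_prob(m_l, "m_l", allow_na = TRUE)
  assert_positive(horizon_days, "horizon_days")
  check_ci <- function(ci, point, name) {
    if (is.null(ci)) return(c(NA_real_, NA_real_))
    if (length(ci) != 2 || anyNA(ci) || ci[1] > ci[2]) {
      abort(sprintf("`%s` must be an ordered (low, high) pair.", name),
            class = "ltfu_validation_error")
    }
    assert_prob(ci, name)
    if (!is.na(point) && (point < ci[1] || point > ci[2])) {
      abort(sprintf("`%s` does not contain its point estimate.", name),
            class = "ltfu_validation_error")
    }
    ci
  }
  m_nl_ci <- check_ci(m_nl_ci, m_nl, "m_nl_ci")
  m_l_ci <- check_ci(m_l_ci, m_l, "m_l_ci")
  tibble(
    label = as.character(label),
    n_eligible = as.integer(n_eligible),
    n_lost = as.integer(n_lost),
    r = r,
    m_nl = m_nl,
    m_nl_lo = m_nl_ci[1], m_nl_hi = m_nl_ci[2],
    m_l = m_l,
    m_l_lo = m_l_ci[1], m_l_hi = m_l_ci[2],
    m_l_source = m_l_source,
    horizon_days = horizon_days,
    n_deaths_retained = as.integer(n_deaths_retained),
    n_traced = as.integer(n_traced),
    n_traced_dead = as.integer(n_traced_dead)
  )
}

#' Nomogram correction factor
#'
#' The correction factor that converts mortality observed among patients
#' retained in care into programme-level mortality:
#' `C = (1 - r) + r * ratio`, where `ratio = M_L / M_NL` is the mortality
#' ratio between patients lost and not lost to follow-up. This is the
#' quantity read off the nomogram; every nomogram line passes through
#' `(ratio = 1, C = 1)`.
#'
#' @param r Proportion lost to follow-up, in `[0, 1]`. Vectorised.
#' @param ratio Mortality ratio `M_L / M_NL`, positive. Vectorised.
#' @return Numeric vector of correction factors, `C >= 1 - r`.
#' @examples
#' correction_factor(r = 0.405, ratio = 20.0 / 2.2) # 4.28, prints as 4.3
#' @export
correction_factor <- function(r, ratio) {
  assert_prob(r, "r")
  assert_positive(ratio, "ratio")
  (1 - r) + r * ratio
}

#' Corrected programme-level mortality
#'
#' Programme-level mortality over a period is a weighted average of
#' mortality among patients retained and patients lost:
#' `M_C = (1 - r) * M_NL + r * M_L`. Equivalently `M_C = C * M_NL` with the
#' nomogram factor `C`; both routes are computed and agree to numerical
#' precision.
#'
#' @param data A data frame with columns `r`, `m_nl` and `m_l` (fractions),
#'   e.g. rows built by [programme_summary()]. Extra columns are carried
#'   through.
#' @return The input tibble with columns added: `ratio` (`m_l / m_nl`),
#'   `c` (correction factor; `NA` when `m_nl = 0` leaves it undefined),
#'   `m_c` (corrected mortality) and `m_c_minus_m_u` when a naive estimate
#'   column `m_u` is present.
#' @examples
#' library(tibble)
#' correct_mortality(tibble(r = 0.405, m_nl = 0.022, m_l = 0.20))
#' @export
correct_mortality <- function(data) {
  stopifnot(is.data.frame(data))
  need <- setdiff(c("r", "m_nl", "m_l"), names(data))
  if (length(need)) {
    abort(paste0("`data` is missing column(s): ", paste(need, collapse = ", ")),
          class = "ltfu_validation_error")
  }
  assert_prob(data$r, "r")
  assert_prob(data$m_nl, "m_nl")
  assert_prob(data$m_l, "m_l")
  if (any(data$r == 1)) {
    warn("r = 1: corrected mortality equals m_l; m_nl is then based on nobody.")
  }
  undef <- data$m_nl == 0 & data$m_l > 0
  if (any(undef)) {
    warn("m_nl = 0 with m_l > 0: correction factor undefined; m_c still reported.")
  }
  out <- as_tibble(data)
  out$ratio <- ifelse(out$m_nl > 0, out$m_l / out$m_nl, NA_real_)
  out$m_c <- (1 - out$r) * out$m_nl + out$r * out$m_l
  out$c <- ifelse(out$m_nl > 0, out$m_c / out$m_nl,
                  ifelse(out$m_l == 0, 1, NA_real_))
  if ("m_u" %in% names(out)) out$m_c_minus_m_u <- out$m_c - out$m_u
  out
}

#' Sensitivity analysis over assumed mortality among patients lost
#'
#' Recomputes corrected mortality for each value in a grid of assumed
#' `M_L` values, holding `r` and `M_NL` fixed — the sensitivity analysis
#' recommended when tracing is incomplete and true mortality among patients
#' lost may exceed the traced estimate.
#'
#' @param data A data frame with columns `r` and `m_nl` (one or more rows).
#' @param m_l_values Numeric vector of assumed `M_L` proportions.
#' @return A tibble with one row per input row per `m_l` value, with the
#'   columns added by [correct_mortality()]. `m_c` is non-decreasing in
#'   `m_l` within each input row.
#' @examples
#' library(tibble)
#' sensitivity_grid(tibble(r = 0.405, m_nl = 0.022),
#'                  m_l_values = c(0.20, 0.25, 0.30))
#' @export
sensitivity_grid <- function(data, m_l_values) {
  stopifnot(is.data.frame(data))
  if (length(m_l_values) == 0) {
    return(correct_mortality(dplyr::mutate(data[0, ], m_l = numeric(0))))
  }
  assert_prob(m_l_values, "m_l_values")
  grid <- tidyr::expand_grid(
    dplyr::select(data, -dplyr::any_of(c("m_l", "m_l_lo", "m_l_hi"))),
    m_l = m_l_values
  )
  correct_mortality(grid)
}

# ---- programme-summary I/O -------------------------------------------------

summary_cols <- c("label", "n_eligible", "n_lost", "r", "m_nl", "m_nl_lo",
                  "m_nl_hi", "m_l", "m_l_lo", "m_l_hi", "m_l_source",
                  "horizon_days", "n_deaths_retained", "n_traced",
                  "n_traced_dead")

#' Read and write programme summaries
#'
#' Programme summaries travel as CSV (one row per programme) or JSON. The
#' files carry fractions by default; a file whose proportion columns contain
#' values above 1 is rejected unless its first line declares
#' `# units=percent`, in which case all proportions are divided by 100 on
#' input. Values are never silently rescaled.
#'
#' @param path File path.
#' @param data A programme-summary tibble (see [programme_summary()]).
#' @param units Units the file should declare when writing: `"fraction"`
#'   or `"percent"`.
#' @return `read_programme_summary()` returns a tibble; the writers return
#'   `path` invisibly.
#' @export
read_programme_summary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ltfu_io_error")
  }
  first <- readLines(path, n = 1L)
  percent <- grepl("^#\\s*units\\s*=\\s*percent\\s*$", first)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          label = readr::col_character(),
                          m_l_source = readr::col_character(),
                          .default = readr::col_double()
                        ))
  prop_cols <- intersect(c("r", "m_nl", "m_nl_lo", "m_nl_hi",
                           "m_l", "m_l_lo", "m_l_hi"), names(df))
  vals <- unlist(df[prop_cols])
  if (percent) {
    df[prop_cols] <- df[prop_cols] / 100
  } else if (any(vals > 1, na.rm = TRUE)) {
    abort(paste0("proportion values > 1 found in ", path,
                 " but the file does not declare `# units=percent`;",
                 " refusing to guess the scale."),
          class = "ltfu_validation_error")
  }
  for (col in setdiff(summary_cols, names(df))) df[[col]] <- NA
  purrr::walk(df$r, assert_prob, name = "r")
  purrr::walk(df$m_nl, assert_prob, name = "m_nl")
  dplyr::select(df, dplyr::all_of(summary_cols))
}

#' @rdname read_programme_summary
#' @export
write_programme_summary <- function(data, path,
                                    units = c("fraction", "percent")) {
  units <- match.arg(units)
  df <- dplyr::select(as_tibble(data), dplyr::any_of(summary_cols))
  if (units == "percent") {
    prop_cols <- intersect(c("r", "m_nl", "m_nl_lo", "m_nl_hi",
                             "m_l", "m_l_lo", "m_l_hi"), names(df))
    df[prop_cols] <- df[prop_cols] * 100
    writeLines("# units=percent", path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @rdname read_programme_summary
#' @export
write_programme_json <- function(data, path) {
  jsonlite::write_json(as.list(as_tibble(data)), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
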