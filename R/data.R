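#' Published summaries of 11 sub-Saharan African ART programmes
#'
#' One-year outcome summaries for eleven antiretroviral treatment programmes
#' (labelled A-K, ordered by increasing loss to follow-up) for which no
#' tracing data were available, so mortality among patients lost must be
#' predicted from the meta-regression. Columns carry the published values:
#' the naive (uncorrected) Kaplan-Meier mortality `m_u`, counts of patients
#' eligible for LTFU classification and patients lost, mortality among
#' patients retained `m_nl` with its 95% CI, the published predicted
#' mortality among patients lost `m_l_pub` with its 95% CI, the published
#' correction factor `c_pub` and corrected mortality `m_c_pub` with CI.
#' All proportions are fractions.
#'
#' The published `(r, m_l CI)` pairs double as the calibration set for the
#' default prediction-interval spread of [meta_model()].
#'
#' @return An 11-row tibble.
#' @examples
#' ssa_programmes()
#' @export
ssa_programmes <- function() {
  tibble(
    label = LETTERS[1:11],
    m_u = c(2.7, 10.8, 6.0, 8.9, 9.1, 3.8, 11.0, 8.2, 3.0, 10.6, 1.3) / 100,
    m_u_lo = c(2.0, 8.0, 4.5, 8.0, 7.8, 2.6, 8.5, 7.2, 2.4, 9.6, 0.9) / 100,
    m_u_hi = c(3.7, 14.5, 7.8, 9.9, 10.7, 5.7, 14.1, 9.4, 3.6, 11.6, 1.8) / 100,
    n_eligible = c(1132L, 369L, 656L, 2827L, 1074L, 632L, 340L, 2212L,
                   3083L, 3194L, 1942L),
    n_lost = c(32L, 16L, 28L, 160L, 70L, 42L, 28L, 258L, 518L, 904L, 558L),
    m_nl = c(2.7, 11.1, 6.1, 9.1, 9.4, 4.0, 11.2, 8.8, 3.3, 12.0, 1.4) / 100,
    m_nl_lo = c(2.0, 8.2, 4.6, 8.2, 8.0, 2.7, 8.7, 7.7, 2.7, 11.0, 1.0) / 100,
    m_nl_hi = c(3.7, 14.8, 8.0, 10.2, 11.0, 5.9, 14.4, 10.0, 4.0, 13.2,
                1.9) / 100,
    m_l_pub = c(61.3, 59.8, 59.9, 58.5, 57.7, 57.5, 56.0, 52.5, 47.3, 36.1,
                35.7) / 100,
    m_l_lo = c(29.3, 28.3, 28.4, 27.5, 27.0, 26.9, 25.9, 23.7, 20.6, 13.8,
               13.6) / 100,
    m_l_hi = c(88.8, 84.8, 84.9, 84.0, 83.4, 83.3, 82.2, 79.7, 75.7, 66.5,
               66.2) / 100,
    c_pub = c(1.62, 1.20, 1.38, 1.31, 1.33, 1.89, 1.33, 1.58, 3.26, 1.59,
              8.30),
    m_c_pub = c(4.4, 13.3, 8.4, 11.9, 12.5, 7.6, 14.9, 13.9, 10.8, 19.1,
                11.6) / 100,
    m_c_lo = c(3.1, 10.0, 6.3, 9.9, 10.1, 5.1, 11.4, 10.4, 6.2, 12.5,
               4.9) / 100,
    m_c_hi = c(5.7, 17.1, 10.7, 13.7, 15.0, 10.3, 18.8, 17.3, 15.6, 27.4,
               20.0) / 100,
    horizon_days = 365
  )
}

#' The western-Kenya (AMPATH) tracing case study
#'
#' Inputs of the worked tracing-method example: 8,977 adult patients, of
#' whom 3,624 were lost to follow-up (reported as 40.5%); outreach
#' ascertained the vital status of 621 lost patients, 124 of whom had died
#' (Kaplan-Meier mortality 20.0%); 126 of the 5,353 patients remaining in
#' care died (Kaplan-Meier mortality 2.2%, 95% CI 1.8-2.6%); the naive
#' programme-level estimate was 1.7% (95% CI 1.3-2.0%).
#'
#' @param r_stated Use the reported `r = 0.405` (default) rather than the
#'   count ratio 3624/8977 = 0.4037.
#' @return A one-row programme-summary tibble (see [programme_summary()])
#'   with the naive estimate in column `m_u`.
#' @examples
#' kenya_case() |> correct_mortality()
#' @export
kenya_case <- function(r_stated = TRUE) {
  out <- programme_summary(
    label = "AMPATH (western Kenya)",
    n_eligible = 8977L,
    n_lost = 3624L,
    r = if (r_stated) 0.405 else 3624 / 8977,
    m_nl = 0.022,
    m_nl_ci = c(0.018, 0.026),
    m_l = 0.20,
    m_l_source = "traced",
    horizon_days = 365,
    n_deaths_retained = 126L,
    n_traced = 621L,
    n_traced_dead = 124L
  )
  out$m_u <- 0.017
  out$m_u_lo <- 0.013
  out$m_u_hi <- 0.020
  out
}
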