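# Small in-code fixtures shared across tests.

# Five patients starting 400 days before closure, with last visits at
# closure - (300, 280, 200, 100, 0): under the 274-day rule the first two
# are lost, so r = 2/5.
toy_cohort <- function(closure = as.Date("2007-01-31")) {
  start <- closure - 400
  tibble::tibble(
    patient_id = paste0("T", 1:5),
    art_start = rep(start, 5),
    last_visit = closure - c(300, 280, 200, 100, 0),
    death_date = as.Date(NA)
  )
}

# A tracing-study cohort shaped like the worked Kenya example: n_traced
# lost patients with ascertained vital status, n_dead of whom died, no
# censoring before the horizon, plus a block of retained patients.
traced_cohort <- function(n_traced = 621, n_dead = 124, n_retained = 100,
                          closure = as.Date("2007-01-31")) {
  start <- closure - 700
  lost <- tibble::tibble(
    patient_id = sprintf("TR%03d", seq_len(n_traced)),
    art_start = rep(start, n_traced),
    last_visit = rep(closure - 300, n_traced),
    death_date = as.Date(NA),
    traced_vital_status = c(rep("dead", n_dead),
                            rep("alive", n_traced - n_dead))
  )
  ret <- tibble::tibble(
    patient_id = sprintf("RE%03d", seq_len(n_retained)),
    art_start = rep(start, n_retained),
    last_visit = rep(closure, n_retained),
    death_date = as.Date(NA),
    traced_vital_status = NA_character_
  )
  dplyr::bind_rows(lost, ret)
}

expect_prop_equal <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.5f - %.5f| <= %.5f", object, expected, tol))
}
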