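kenya_spec <- function(iterations = 100000L, seed = 1L) {
  mc_spec(iterations = iterations, seed = seed,
          r_dist = "beta_jeffreys",
          m_nl_dist = "logit_normal_from_ci",
          m_l_dist = "binomial_counts")
}

test_that("all-fixed distributions give a degenerate interval at the point", {
  sm <- programme_summary("p", m_nl = 0.022, m_l = 0.20, r = 0.405)
  res <- monte_carlo_ci(sm, spec = mc_spec(iterations = 1000, seed = 1,
                                           r_dist = "fixed",
                                           m_nl_dist = "fixed",
                                           m_l_dist = "fixed"))
  expect_equal(res$m_c_lo, res$m_c)
  expect_equal(res$m_c_hi, res$m_c)
  expect_equal(round(100 * res$m_c, 1), 9.4)
})

test_that("the same seed reproduces the interval bit for bit", {
  k <- kenya_case()
  a <- monte_carlo_ci(k, spec = kenya_spec(iterations = 20000, seed = 99))
  b <- monte_carlo_ci(k, spec = kenya_spec(iterations = 20000, seed = 99))
  expect_identical(a$m_c_lo, b$m_c_lo)
  expect_identical(a$m_c_hi, b$m_c_hi)
})

test_that("Monte-Carlo error at 100,000 iterations is below 0.002 per bound", {
  k <- kenya_case()
  a <- monte_carlo_ci(k, spec = kenya_spec(seed = 1))
  b <- monte_carlo_ci(k, spec = kenya_spec(seed = 2))
  expect_lt(abs(a$m_c_lo - b$m_c_lo), 0.002)
  expect_lt(abs(a$m_c_hi - b$m_c_hi), 0.002)
  # the point estimate is the plug-in value, untouched by simulation
  expect_equal(a$m_c, correct_mortality(k)$m_c)
})

test_that("interval bounds are proportions and bracket the draw median", {
  k <- kenya_case()
  res <- monte_carlo_ci(k, spec = kenya_spec(iterations = 5000, seed = 4))
  expect_true(res$m_c_lo >= 0 && res$m_c_hi <= 1)
  expect_true(res$m_c_lo < res$m_c && res$m_c < res$m_c_hi)
})

test_that("missing inputs for a distribution mode fail with the field named", {
  sm <- programme_summary("p", m_nl = 0.022, m_l = 0.20, r = 0.405)
  expect_error(monte_carlo_ci(sm, spec = mc_spec(iterations = 10,
                                                 r_dist = "beta_jeffreys",
                                                 m_nl_dist = "fixed",
                                                 m_l_dist = "fixed")),
               "n_eligible")
  expect_error(monte_carlo_ci(sm, spec = mc_spec(iterations = 10,
                                                 r_dist = "fixed",
                                                 m_nl_dist = "logit_normal_from_ci",
                                                 m_l_dist = "fixed")),
               "m_nl_lo")
  expect_error(monte_carlo_ci(sm, spec = mc_spec(iterations = 10,
                                                 r_dist = "fixed",
                                                 m_nl_dist = "fixed",
                                                 m_l_dist = "binomial_counts")),
               "n_traced")
})

test_that("interval width shrinks with more data", {
  widths <- vapply(c(500, 2000, 8000, 32000), function(n_elig) {
    n_lost <- round(0.3 * n_elig)
    sm <- programme_summary("p", m_nl = 0.03, m_l = 0.25,
                            n_eligible = n_elig, n_lost = n_lost,
                            n_deaths_retained = round(0.03 * (n_elig - n_lost)),
                            n_traced = n_lost,
                            n_traced_dead = round(0.25 * n_lost))
    res <- monte_carlo_ci(sm, spec = mc_spec(iterations = 20000, seed = 8,
                                             m_nl_dist = "binomial_counts",
                                             m_l_dist = "binomial_counts"))
    res$m_c_hi - res$m_c_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("with nobody lost the corrected CI collapses onto the m_nl CI", {
  # r = 0 identically: m_c_i = m_nl_i draw for draw, so the interval must
  # reproduce the m_nl interval itself
  sm <- programme_summary("p", m_nl = 0.05, m_nl_ci = c(0.04, 0.062),
                          m_l = 0.05, m_l_ci = c(0.04, 0.062), r = 0)
  res <- monte_carlo_ci(sm, spec = mc_spec(iterations = 200000, seed = 10,
                                           r_dist = "fixed",
                                           m_nl_dist = "logit_normal_from_ci",
                                           m_l_dist = "fixed"))
  expect_equal(res$m_c_lo, 0.04, tolerance = 0.002)
  expect_equal(res$m_c_hi, 0.062, tolerance = 0.002)
  # with loss present but m_l drawn like m_nl (independently), averaging
  # two independent draws can only narrow the interval, never widen it
  sm2 <- programme_summary("p", m_nl = 0.05, m_nl_ci = c(0.04, 0.062),
                           m_l = 0.05, m_l_ci = c(0.04, 0.062), r = 0.3)
  res2 <- monte_carlo_ci(sm2, spec = mc_spec(iterations = 50000, seed = 11,
                                             r_dist = "fixed",
                                             m_nl_dist = "logit_normal_from_ci",
                                             m_l_dist = "logit_normal_from_ci"))
  expect_gte(res2$m_c_lo, res$m_c_lo - 0.002)
  expect_lte(res2$m_c_hi, res$m_c_hi + 0.002)
})

test_that("predicted m_l flows through the calibrated prediction interval", {
  sm <- programme_summary("p", m_nl = 0.014, r = 558 / 1942,
                          n_eligible = 1942, n_lost = 558,
                          m_l_source = "predicted")
  res <- monte_carlo_ci(sm, model = meta_model(),
                        spec = mc_spec(iterations = 20000, seed = 3,
                                       r_dist = "fixed",
                                       m_nl_dist = "fixed",
                                       m_l_dist = "prediction_interval"))
  expect_equal(res$method, "meta")
  expect_equal(round(100 * res$m_l, 1), 35.7)
  expect_true(res$m_c_lo < res$m_c && res$m_c < res$m_c_hi)
})

test_that("empirical coverage of the interval sits near nominal", {
  res <- coverage_check(true_r = 0.3, true_m_nl = 0.03, true_m_l = 0.25,
                        n_eligible = 2000, replications = 200,
                        spec = mc_spec(iterations = 1000, seed = 12))
  expect_gte(res$coverage, 0.90)
  expect_lte(res$coverage, 0.99)
  # doubling replications halves the standard error of the estimate
  expect_equal(coverage_check(0.3, 0.03, 0.25, replications = 400,
                              spec = mc_spec(iterations = 10, seed = 1))$se /
                 coverage_check(0.3, 0.03, 0.25, replications = 100,
                                spec = mc_spec(iterations = 10, seed = 1))$se,
               0.5, tolerance = 0.25)
})

test_that("spec validation rejects impossible settings", {
  expect_error(mc_spec(iterations = 0), class = "ltfu_validation_error")
  expect_error(mc_spec(level = 1), class = "ltfu_validation_error")
  expect_error(mc_spec(r_dist = "magic"))
})
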