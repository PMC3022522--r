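#' Monte-Carlo specification
#'
#' Settings for propagating uncertainty in `r`, `M_NL` and `M_L` into a
#' confidence interval for corrected programme-level mortality. Each input
#' is drawn independently per iteration from a boundary-respecting
#' distribution derivable from exactly what a programme reports:
#'
#' * `r`: `"beta_jeffreys"` — `Beta(n_lost + 1/2, n_retained + 1/2)` from
#'   the LTFU counts — or `"fixed"`.
#' * `m_nl`: `"logit_normal_from_ci"` — normal on the logit scale with the
#'   spread back-solved from the reported 95% CI — `"binomial_counts"`
#'   (Jeffreys Beta from deaths/patients) or `"fixed"`.
#' * `m_l`: the same options plus `"prediction_interval"` — normal on the
#'   logit scale around the meta-regression prediction with the calibrated
#'   spread `s(r)`.
#'
#' @param iterations Number of Monte-Carlo draws (default 100,000).
#' @param seed Integer seed; recorded in the result for reproducibility.
#' @param level Coverage probability of the reported interval (default
#'   0.95).
#' @param r_dist,m_nl_dist,m_l_dist Distribution modes as above.
#' @return A list of class `mc_spec`.
#' @export
mc_spec <- function(iterations = 100000L, seed = NULL, level = 0.95,
                    r_dist = c("beta_jeffreys", "fixed"),
                    m_nl_dist = c("logit_normal_from_ci", "binomial_counts",
                                  "fixed"),
                    m_l_dist = c("logit_normal_from_ci", "binomial_counts",
                                 "prediction_interval", "fixed")) {
  if (iterations < 1) {
    abort("`iterations` must be >= 1.", class = "ltfu_validation_error")
  }
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "ltfu_validation_error")
  }
  structure(list(iterations = as.integer(iterations), seed = seed,
                 level = level,
                 r_dist = match.arg(r_dist),
                 m_nl_dist = match.arg(m_nl_dist),
                 m_l_dist = match.arg(m_l_dist)),
            class = "mc_spec")
}

# Back-solve a logit-normal from a point estimate and 95% CI, then draw.
draw_logit_normal <- function(n, point, lo, hi) {
  mu <- logit(point)
  sd <- (logit(hi) - logit(lo)) / (2 * qnorm(0.975))
  invlogit(rnorm(n, mu, sd))
}

draw_beta_jeffreys <- function(n, x, size) {
  rbeta(n, x + 0.5, size - x + 0.5)
}

need_field <- function(ok, field, mode) {
  if (!ok) {
    abort(sprintf("Monte-Carlo mode \"%s\" needs `%s` in the summary.",
                  mode, field),
          class = "ltfu_validation_error")
  }
}

#' Monte-Carlo confidence interval for corrected mortality
#'
#' Draws `(r_i, m_nl_i, m_l_i)` independently per iteration under the modes
#' of an [mc_spec()], computes `m_c_i = (1 - r_i) m_nl_i + r_i m_l_i`, and
#' reports the percentile interval. The headline point estimate is the
#' deterministic plug-in value — simulation only supplies the interval —
#' and the same seed always reproduces the same interval bit for bit.
#'
#' @param data A one-row programme summary (see [programme_summary()] or
#'   [summarize_programme()]). Must carry the fields each chosen
#'   distribution needs (counts for binomial modes, CI bounds for CI-based
#'   modes).
#' @param model An [meta_model()]; required for
#'   `m_l_dist = "prediction_interval"` and used to fill in a missing
#'   `m_l` point prediction.
#' @param spec An [mc_spec()].
#' @return A one-row tibble: `label`, `r`, `m_nl`, `m_l`, `method`, `c`,
#'   `m_c`, `m_c_lo`, `m_c_hi`, `level`, `mc_iterations`, `seed`.
#' @examples
#' kenya_case() |> monte_carlo_ci(spec = mc_spec(m_l_dist = "binomial_counts",
#'                                               iterations = 10000,
#'                                               seed = 1))
#' @export
monte_carlo_ci <- function(data, model = NULL, spec = mc_spec()) {
  stopifnot(is.data.frame(data), inherits(spec, "mc_spec"))
  if (nrow(data) != 1) {
    abort("`data` must be a single programme-summary row.",
          class = "ltfu_validation_error")
  }
  s <- as.list(data)
  n <- spec$iterations
  # fill in a predicted m_l when absent
  method <- switch(s$m_l_source %||% "assumed",
                   traced = "tracing", predicted = "meta", "assumed")
  if (is.na(s$m_l) || identical(s$m_l_source, "predicted")) {
    if (is.null(model)) model <- meta_model()
    s$m_l <- predict_mortality_lost(s$r, model)
    method <- "meta"
  }
  draws <- function() {
    r_i <- switch(spec$r_dist,
      fixed = rep(s$r, n),
      beta_jeffreys = {
        need_field(!is.na(s$n_eligible) && !is.na(s$n_lost),
                   "n_eligible/n_lost", "beta_jeffreys")
        draw_beta_jeffreys(n, s$n_lost, s$n_eligible)
      })
    m_nl_i <- switch(spec$m_nl_dist,
      fixed = rep(s$m_nl, n),
      binomial_counts = {
        need_field(!is.na(s$n_deaths_retained) && !is.na(s$n_eligible) &&
                     !is.na(s$n_lost), "n_deaths_retained", "binomial_counts")
        draw_beta_jeffreys(n, s$n_deaths_retained, s$n_eligible - s$n_lost)
      },
      logit_normal_from_ci = {
        need_field(!is.na(s$m_nl_lo %||% NA) && !is.na(s$m_nl_hi %||% NA),
                   "m_nl_lo/m_nl_hi", "logit_normal_from_ci")
        draw_logit_normal(n, s$m_nl, s$m_nl_lo, s$m_nl_hi)
      })
    m_l_i <- switch(spec$m_l_dist,
      fixed = rep(s$m_l, n),
      binomial_counts = {
        need_field(!is.na(s$n_traced %||% NA) && !is.na(s$n_traced_dead %||% NA),
                   "n_traced/n_traced_dead", "binomial_counts")
        draw_beta_jeffreys(n, s$n_traced_dead, s$n_traced)
      },
      logit_normal_from_ci = {
        need_field(!is.na(s$m_l_lo %||% NA) && !is.na(s$m_l_hi %||% NA),
                   "m_l_lo/m_l_hi", "logit_normal_from_ci")
        draw_logit_normal(n, s$m_l, s$m_l_lo, s$m_l_hi)
      },
      prediction_interval = {
        if (is.null(model)) model <- meta_model()
        if (is.null(model$interval)) {
          abort("prediction_interval mode needs a calibrated meta model.",
                class = "ltfu_validation_error")
        }
        sp <- meta_spread(model, s$r)
        invlogit(rnorm(n, model$a + model$b * s$r, (sp$lo + sp$hi) / 2))
      })
    (1 - r_i) * m_nl_i + r_i * m_l_i
  }
  m_c_draws <- if (is.null(spec$seed)) draws() else
    withr::with_seed(spec$seed, draws())
  alpha <- (1 - spec$level) / 2
  ci <- unname(quantile(m_c_draws, c(alpha, 1 - alpha)))
  point <- correct_mortality(tibble(r = s$r, m_nl = s$m_nl, m_l = s$m_l))
  tibble(label = s$label %||% NA_character_,
         r = s$r, m_nl = s$m_nl, m_l = s$m_l,
         method = method,
         c = point$c, m_c = point$m_c,
         m_c_lo = ci[1], m_c_hi = ci[2],
         level = spec$level,
         mc_iterations = n,
         seed = spec$seed %||% NA_integer_)
}

#' Empirical coverage of the Monte-Carlo interval
#'
#' Validation harness: simulates programmes with known true corrected
#' mortality, forms the Monte-Carlo interval from each realised summary
#' (binomial-count modes throughout), and reports the fraction of intervals
#' containing the truth. With well-calibrated intervals this sits near the
#' nominal level; its Monte-Carlo standard error shrinks as
#' `1/sqrt(replications)`.
#'
#' @param true_r,true_m_nl,true_m_l True programme parameters (fractions).
#' @param n_eligible Patients eligible for LTFU classification per
#'   simulated programme.
#' @param replications Number of simulated programmes.
#' @param spec An [mc_spec()]; its `seed` drives the whole experiment and
#'   its distribution modes are forced to the binomial-count settings.
#' @return One-row tibble: `coverage`, `replications`, `se` (binomial
#'   standard error of the coverage estimate), `true_m_c`.
#' @export
coverage_check <- function(true_r, true_m_nl, true_m_l,
                           n_eligible = 2000L, replications = 500L,
                           spec = mc_spec(iterations = 2000L, seed = 1L)) {
  assert_prob(true_r, "true_r")
  assert_prob(true_m_nl, "true_m_nl")
  assert_prob(true_m_l, "true_m_l")
  if (replications < 1) {
    abort("`replications` must be >= 1.", class = "ltfu_validation_error")
  }
  true_m_c <- (1 - true_r) * true_m_nl + true_r * true_m_l
  run <- function() {
    hits <- logical(replications)
    for (i in seq_len(replications)) {
      n_lost <- rbinom(1, n_eligible, true_r)
      n_ret <- n_eligible - n_lost
      d_ret <- rbinom(1, n_ret, true_m_nl)
      d_lost <- rbinom(1, max(n_lost, 1L), true_m_l)
      sm <- programme_summary(
        label = "sim", n_eligible = n_eligible, n_lost = n_lost,
        m_nl = d_ret / max(n_ret, 1L), m_l = d_lost / max(n_lost, 1L),
        m_l_source = "traced",
        n_deaths_retained = d_ret, n_traced = max(n_lost, 1L),
        n_traced_dead = d_lost
      )
      res <- monte_carlo_ci(sm, spec = mc_spec(
        iterations = spec$iterations, seed = NULL, level = spec$level,
        r_dist = "beta_jeffreys", m_nl_dist = "binomial_counts",
        m_l_dist = "binomial_counts"))
      hits[i] <- res$m_c_lo <= true_m_c && true_m_c <= res$m_c_hi
    }
    mean(hits)
  }
  cov <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  tibble(coverage = cov, replications = as.integer(replications),
         se = sqrt(cov * (1 - cov) / replications),
         true_m_c = true_m_c)
}
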