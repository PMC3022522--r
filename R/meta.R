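#' Meta-regression model for mortality among patients lost to follow-up
#'
#' Across tracing studies in sub-Saharan African ART programmes, mortality
#' among patients lost to follow-up falls as the programme's LTFU proportion
#' rises (programmes losing many patients lose many low-risk
#' self-transfers). The published meta-regression captures this on the logit
#' scale: `M_L = plogis(a + b * r)` with `a = 0.57287` and `b = -4.04409`,
#' `r` the proportion lost as a fraction.
#'
#' The published source does not report the variance terms behind its 95%
#' band, so the band is calibrated here to the eleven published prediction
#' intervals (see [calibrate_interval()]); by default the model ships with
#' that calibration already applied.
#'
#' @param a,b Intercept and slope on the logit scale.
#' @param calibration `"default"` calibrates the interval spread on the
#'   published programme intervals of [ssa_programmes()]; `"none"` leaves
#'   the model uncalibrated (interval requests then error); or a data frame
#'   of calibration points passed to [calibrate_interval()].
#' @param mode Interval calibration mode, see [calibrate_interval()].
#' @return An object of class `ltfu_meta` with elements `a`, `b`, `link`,
#'   `interval` (calibrated spread parameters) and `calibration`
#'   (points and residuals).
#' @examples
#' m <- meta_model()
#' predict_mortality_lost(c(0.05, 0.5), m)
#' @export
meta_model <- function(a = 0.57287, b = -4.04409,
                       calibration = "default",
                       mode = c("leverage", "constant", "asymmetric")) {
  mode <- match.arg(mode)
  model <- structure(
    list(a = a, b = b, link = "logit", interval = NULL, calibration = NULL),
    class = "ltfu_meta"
  )
  if (is.data.frame(calibration)) {
    model <- calibrate_interval(model, calibration, mode = mode)
  } else if (identical(calibration, "default")) {
    pub <- ssa_programmes()
    pts <- tibble(r = pub$n_lost / pub$n_eligible,
                  lo = pub$m_l_lo, hi = pub$m_l_hi)
    model <- calibrate_interval(model, pts, mode = mode)
  } else if (!identical(calibration, "none")) {
    abort("`calibration` must be \"default\", \"none\" or a data frame.",
          class = "ltfu_validation_error")
  }
  model
}

#' Predict mortality among patients lost to follow-up
#'
#' Evaluates the meta-regression `plogis(a + b * r)` at the programme's LTFU
#' proportion — the "meta method" used when no tracing data exist. The
#' underlying studies concern loss to follow-up in the first year of ART;
#' a warning is issued when `horizon_days` exceeds 550 because the
#' prediction should not be extrapolated to later treatment years.
#'
#' @param r Proportion lost to follow-up, fraction in `[0, 1]`. Vectorised.
#' @param model An [meta_model()] object.
#' @param horizon_days Optional analysis horizon used only for the
#'   applicability check.
#' @return Numeric vector of predicted `M_L` in `(0, 1)`, strictly
#'   decreasing in `r` for the default (negative-slope) coefficients.
#' @examples
#' predict_mortality_lost(32 / 1132)  # 0.613: programme losing 2.8%
#' @export
predict_mortality_lost <- function(r, model = meta_model(),
                                   horizon_days = NULL) {
  stopifnot(inherits(model, "ltfu_meta"))
  assert_prob(r, "r")
  if (!is.null(horizon_days) && any(horizon_days > 550)) {
    warn(paste("the meta-regression was fitted to first-year-of-ART tracing",
               "studies; predictions at horizons beyond ~18 months are",
               "extrapolations."))
  }
  invlogit(model$a + model$b * r)
}

#' Prediction interval for mortality among patients lost
#'
#' Back-transforms `a + b*r +/- z * s(r)` from the logit scale, where the
#' spread `s(r)` comes from the model's calibration (see
#' [calibrate_interval()]). As `level` tends to 0 the interval collapses to
#' the point prediction.
#'
#' @inheritParams predict_mortality_lost
#' @param level Coverage probability, default 0.95.
#' @return A tibble with columns `r`, `fit`, `lwr`, `upr`, all proportions,
#'   with `lwr < fit < upr`.
#' @export
prediction_interval_lost <- function(r, model = meta_model(), level = 0.95) {
  stopifnot(inherits(model, "ltfu_meta"))
  assert_prob(r, "r")
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "ltfu_validation_error")
  }
  if (is.null(model$interval)) {
    abort(paste("model has no calibrated interval spread; run",
                "calibrate_interval() (or use meta_model(calibration =",
                "\"default\"))."),
          class = "ltfu_validation_error")
  }
  eta <- model$a + model$b * r
  z <- qnorm(1 - (1 - level) / 2)
  s <- meta_spread(model, r)
  tibble(r = r,
         fit = invlogit(eta),
         lwr = invlogit(eta - z * s$lo),
         upr = invlogit(eta + z * s$hi))
}

# Half-width standard deviations on the logit scale at covariate r.
# Returns list(lo, hi) so the asymmetric mode can differ by side.
meta_spread <- function(model, r) {
  iv <- model$interval
  switch(iv$mode,
    constant = list(lo = rep(iv$sd, length(r)), hi = rep(iv$sd, length(r))),
    asymmetric = list(lo = rep(iv$sd_lo, length(r)),
                      hi = rep(iv$sd_hi, length(r))),
    leverage = {
      v <- iv$v[1] + iv$v[2] * r + iv$v[3] * r^2
      s <- sqrt(pmax(v, 1e-12))
      list(lo = s, hi = s)
    }
  )
}

#' Calibrate the prediction-interval spread of a meta-regression model
#'
#' The meta-regression's variance components were never published; the only
#' recoverable evidence about its uncertainty is the set of printed 95%
#' intervals. This fits a spread on the logit scale that best reproduces a
#' supplied set of `(r, low, high)` interval bounds, by least squares on the
#' logit scale:
#'
#' * `"constant"` — a single symmetric spread `s`; closed form
#'   `s = mean(logit(hi) - logit(lo)) / (2 z)`.
#' * `"asymmetric"` — separate spreads below and above the fitted curve.
#' * `"leverage"` (default) — a symmetric spread whose *variance* is
#'   quadratic in `r`, `s(r)^2 = v0 + v1 r + v2 r^2`: the form a regression
#'   prediction variance takes (`var(a) + 2 r cov(a,b) + r^2 var(b) + tau^2`),
#'   so the band widens away from the covariate mean of the calibration
#'   studies. Needs at least 3 distinct `r` values.
#'
#' @param model An [meta_model()] object.
#' @param points Data frame with columns `r`, `lo`, `hi` (fractions;
#'   `m_l_lo`/`m_l_hi` accepted as aliases). At least 2 rows (3 for
#'   `"leverage"`), ordered non-degenerate bounds.
#' @param mode Calibration mode, see above.
#' @return The model with `interval` set and `calibration` holding the
#'   points, the reproduced bounds and their residuals (proportion scale).
#' @examples
#' m <- calibrate_interval(meta_model(calibration = "none"),
#'                         data.frame(r = c(0.05, 0.3),
#'                                    lo = c(0.3, 0.14), hi = c(0.85, 0.65)),
#'                         mode = "constant")
#' glance(m)
#' @export
calibrate_interval <- function(model, points,
                               mode = c("leverage", "constant", "asymmetric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ltfu_meta"), is.data.frame(points))
  pts <- as_tibble(points)
  if (!"lo" %in% names(pts) && "m_l_lo" %in% names(pts)) pts$lo <- pts$m_l_lo
  if (!"hi" %in% names(pts) && "m_l_hi" %in% names(pts)) pts$hi <- pts$m_l_hi
  need <- setdiff(c("r", "lo", "hi"), names(pts))
  if (length(need)) {
    abort(paste0("calibration points need column(s): ",
                 paste(need, collapse = ", ")),
          class = "ltfu_validation_error")
  }
  min_pts <- if (mode == "leverage") 3L else 2L
  if (nrow(pts) < min_pts ||
      (mode == "leverage" && length(unique(pts$r)) < 3L)) {
    abort(sprintf("mode \"%s\" needs at least %d calibration points%s.",
                  mode, min_pts,
                  if (mode == "leverage") " with distinct r" else ""),
          class = "ltfu_validation_error")
  }
  assert_prob(pts$r, "r")
  assert_prob(pts$lo, "lo")
  assert_prob(pts$hi, "hi")
  if (any(pts$lo >= pts$hi)) {
    abort("degenerate calibration points: every `lo` must be < `hi`.",
          class = "ltfu_validation_error")
  }
  z <- qnorm(0.975)
  eta <- model$a + model$b * pts$r
  llo <- logit(pts$lo)
  lhi <- logit(pts$hi)
  iv <- switch(mode,
    constant = list(mode = "constant", sd = mean(lhi - llo) / (2 * z)),
    asymmetric = list(mode = "asymmetric",
                      sd_lo = max(mean(eta - llo) / z, 0),
                      sd_hi = max(mean(lhi - eta) / z, 0)),
    leverage = {
      w2 <- ((lhi - llo) / (2 * z))^2
      fit <- lm(w2 ~ pts$r + I(pts$r^2))
      v <- unname(coef(fit))
      grid <- seq(0, 1, by = 0.01)
      if (min(v[1] + v[2] * grid + v[3] * grid^2) <= 0) {
        warn("leverage-form variance not positive over [0, 1]; falling back to a constant spread.")
        list(mode = "constant", sd = mean(lhi - llo) / (2 * z))
      } else {
        list(mode = "leverage", v = v)
      }
    }
  )
  model$interval <- iv
  s <- {
    model_tmp <- model
    meta_spread(model_tmp, pts$r)
  }
  repro <- tibble(
    r = pts$r, lo = pts$lo, hi = pts$hi,
    fit_lo = invlogit(eta - z * s$lo),
    fit_hi = invlogit(eta + z * s$hi)
  )
  repro$resid_lo <- repro$fit_lo - repro$lo
  repro$resid_hi <- repro$fit_hi - repro$hi
  model$calibration <- repro
  model
}

#' @export
print.ltfu_meta <- function(x, ...) {
  cat("Meta-regression for mortality among patients lost to follow-up\n")
  cat(sprintf("  logit(M_L) = %.5f %+.5f * r\n", x$a, x$b))
  if (is.null(x$interval)) {
    cat("  interval spread: uncalibrated\n")
  } else {
    cat(sprintf("  interval spread: %s mode, calibrated on %d intervals",
                x$interval$mode,
                if (is.null(x$calibration)) 0L else nrow(x$calibration)),
        "\n")
    if (!is.null(x$calibration)) {
      cat(sprintf("  max |bound residual|: %.2f percentage points\n",
                  100 * max(abs(c(x$calibration$resid_lo,
                                  x$calibration$resid_hi)))))
    }
  }
  invisible(x)
}

#' Tidy and summarise a meta-regression model
#'
#' `tidy()` returns the logit-scale coefficients; `glance()` returns a
#' one-row model summary including the calibrated interval mode and the
#' largest absolute discrepancy between reproduced and supplied calibration
#' bounds (proportion scale).
#'
#' @param x An `ltfu_meta` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ltfu_meta
#' @export
tidy.ltfu_meta <- function(x, ...) {
  tibble(term = c("(Intercept)", "r"), estimate = c(x$a, x$b),
         scale = "logit")
}

#' @rdname tidy.ltfu_meta
#' @method glance ltfu_meta
#' @export
glance.ltfu_meta <- function(x, ...) {
  tibble(
    link = x$link,
    interval_mode = if (is.null(x$interval)) NA_character_ else x$interval$mode,
    n_calibration = if (is.null(x$calibration)) 0L else nrow(x$calibration),
    max_abs_bound_residual = if (is.null(x$calibration)) NA_real_ else
      max(abs(c(x$calibration$resid_lo, x$calibration$resid_hi)))
  )
}

#' Serialize a meta-regression model to JSON and back
#'
#' @param model An `ltfu_meta` model.
#' @param path File path.
#' @return `write_meta_model()` returns `path` invisibly;
#'   `read_meta_model()` returns the model.
#' @export
write_meta_model <- function(model, path) {
  stopifnot(inherits(model, "ltfu_meta"))
  payload <- list(a = model$a, b = model$b, link = model$link,
                  interval = model$interval,
                  calibration = model$calibration)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_meta_model
#' @export
read_meta_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ltfu_io_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(a = p$a, b = p$b, link = p$link %||% "logit",
                          interval = p$interval,
                          calibration = if (!is.null(p$calibration))
                            as_tibble(p$calibration)),
                     class = "ltfu_meta")
  model
}
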