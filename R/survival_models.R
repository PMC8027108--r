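#' @keywords internal
"_PACKAGE"

# Time conventions: all survival times in months; 1 month = 365.25/12 days.
DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25

#' Weibull survival parameters
#'
#' Constructs the scale/shape pair (lambda, gamma) of a Weibull survival
#' model S(t) = exp(-lambda * t^gamma). With `shape = 1` the model reduces
#' to an exponential with rate `scale`.
#'
#' @param scale Positive scale parameter lambda, units month^(-shape).
#' @param shape Positive dimensionless shape parameter gamma.
#' @return An object of class `weibull_params`.
#' @export
#' @examples
#' weibull_params(log(2) / 19.8, 1)
weibull_params <- function(scale, shape = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("`scale` must be positive, got ", scale)
  if (shape <= 0) stop("`shape` must be positive, got ", shape)
  structure(list(scale = scale, shape = shape), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull survival parameters: scale = %.6g, shape = %.6g\n",
              x$scale, x$shape))
  cat(sprintf("  median = %.4g months\n", (log(2) / x$scale)^(1 / x$shape)))
  invisible(x)
}

#' Weibull survival function
#'
#' S(t) = exp(-scale * t^shape). Equals 1 at t = 0 and is strictly
#' decreasing in t.
#'
#' @param params A [weibull_params()] object.
#' @param t Time(s) in months, nonnegative; vectorized.
#' @return Survival probabilities in (0, 1].
#' @export
weibull_survival <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be nonnegative")
  exp(-params$scale * t^params$shape)
}

#' Cumulative event probability under a constant rate
#'
#' P(event by t) = 1 - exp(-rate * t) for a constant per-month event rate.
#'
#' @param rate Nonnegative per-month event rate.
#' @param t Time(s) in months, nonnegative; vectorized.
#' @return Probabilities in [0, 1).
#' @export
cumulative_event_probability <- function(rate, t) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.numeric(t))
  if (rate < 0) stop("`rate` must be nonnegative")
  if (any(t < 0)) stop("`t` must be nonnegative")
  -expm1(-rate * t)
}

#' Per-cycle conditional transition probability from a Weibull fit
#'
#' The probability of the event during the cycle ending at time `t`, given
#' event-free survival to the cycle start `t - u`:
#' `1 - exp(scale * (t - u)^shape - scale * t^shape)`,
#' i.e. `1 - S(t)/S(t - u)`. For `shape = 1` this is constant in `t`
#' (memorylessness) and equals `1 - exp(-scale * u)`.
#'
#' @param params A [weibull_params()] object.
#' @param t Cycle-end time(s) in months; vectorized.
#' @param u Cycle length in months, `0 < u <= min(t)`.
#' @return Conditional event probabilities in [0, 1).
#' @export
transition_probability <- function(params, t, u) {
  stopifnot(inherits(params, "weibull_params"),
            is.numeric(t), is.numeric(u), length(u) == 1L)
  if (u <= 0) stop("cycle length `u` must be positive")
  if (any(t < u)) stop("`t` must be >= cycle length `u`")
  -expm1(params$scale * (t - u)^params$shape - params$scale * t^params$shape)
}

#' Calibrate Weibull parameters to a printed median survival
#'
#' Given the median survival time and a shape, returns the scale for which
#' S(median) = 0.5 exactly: `scale = log(2) / median^shape`. Used to
#' calibrate the model to published medians when digitized curves are
#' unavailable.
#'
#' @param median Median survival in months, positive.
#' @param shape Positive shape parameter; `1` gives an exponential.
#' @return A [weibull_params()] object.
#' @export
#' @examples
#' params_from_median(30.8)  # gefitinib median DFS
params_from_median <- function(median, shape = 1) {
  stopifnot(is.numeric(median), length(median) == 1L)
  if (median <= 0) stop("`median` must be positive")
  if (shape <= 0) stop("`shape` must be positive")
  weibull_params(scale = log(2) / median^shape, shape = shape)
}

#' Kaplan-Meier curve coordinates
#'
#' Container for (digitized or estimated) Kaplan-Meier coordinates.
#' Duplicate time points are resolved by keeping the last (lowest) survival
#' value, matching how step curves are digitized.
#'
#' @param times Nondecreasing nonnegative times in months.
#' @param survival Survival probabilities in (0, 1], nonincreasing, same
#'   length as `times`.
#' @param at_risk Optional nonnegative at-risk counts, same length.
#' @return An object of class `km_curve` (also a data.frame with columns
#'   `time_months`, `survival` and optionally `at_risk`).
#' @export
km_curve <- function(times, survival, at_risk = NULL) {
  stopifnot(is.numeric(times), is.numeric(survival),
            length(times) == length(survival))
  if (length(times) == 0L) stop("empty curve")
  if (any(times < 0)) stop("times must be nonnegative")
  if (is.unsorted(times)) stop("times must be nondecreasing")
  if (any(survival <= 0) || any(survival > 1))
    stop("survival values must lie in (0, 1]")
  if (!is.null(at_risk)) {
    stopifnot(length(at_risk) == length(times))
    if (any(at_risk < 0)) stop("at-risk counts must be nonnegative")
  }
  # deduplicate: keep the last value recorded at each time point
  keep <- !duplicated(times, fromLast = TRUE)
  times <- times[keep]; survival <- survival[keep]
  if (!is.null(at_risk)) at_risk <- at_risk[keep]
  if (is.unsorted(rev(survival), strictly = FALSE) && any(diff(survival) > 1e-12))
    stop("survival must be nonincreasing in time")
  df <- data.frame(time_months = times, survival = survival)
  if (!is.null(at_risk)) df$at_risk <- at_risk
  structure(df, class = c("km_curve", "data.frame"))
}

#' Read Kaplan-Meier coordinates from CSV
#'
#' Expects the dialect `time_months,survival,at_risk` with `at_risk`
#' optional (blank allowed), '.' decimal separator, UTF-8.
#'
#' @param path Path to the CSV file.
#' @return A [km_curve()].
#' @export
read_km_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time_months", "survival") %in% names(df)))
    stop("KM CSV must have columns `time_months` and `survival`")
  at_risk <- if ("at_risk" %in% names(df) && !all(is.na(df$at_risk)))
    df$at_risk else NULL
  km_curve(df$time_months, df$survival, at_risk)
}

#' Write Kaplan-Meier coordinates to CSV
#'
#' @param curve A [km_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  df <- as.data.frame(curve)
  if (!"at_risk" %in% names(df)) df$at_risk <- NA
  utils::write.csv(df[, c("time_months", "survival", "at_risk")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fit a Weibull model to Kaplan-Meier coordinates
#'
#' Least-squares fit of the linearized Weibull relation
#' `log(-log S(t)) = log(scale) + shape * log(t)` over curve points with
#' survival strictly inside (0, 1) and t > 0; points at S = 1 or t = 0 are
#' dropped (the transform is undefined there). When at-risk counts are
#' present they are used as regression weights.
#'
#' @param curve A [km_curve()] with at least 3 usable points.
#' @return A list with `params` ([weibull_params()]), `r_squared` and
#'   `n_points`, class `weibull_km_fit`.
#' @export
fit_weibull_to_km <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  use <- curve$survival > 0 & curve$survival < 1 & curve$time_months > 0
  n <- sum(use)
  if (n < 3L)
    stop("need at least 3 points with 0 < survival < 1 and t > 0; got ", n)
  x <- log(curve$time_months[use])
  y <- log(-log(curve$survival[use]))
  w <- if ("at_risk" %in% names(curve)) curve$at_risk[use] else NULL
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  params <- weibull_params(scale = exp(unname(co[1])), shape = unname(co[2]))
  ww <- if (is.null(w)) rep(1, n) else w
  ss_tot <- sum(ww * (y - stats::weighted.mean(y, ww))^2)
  ss_res <- sum(ww * stats::residuals(fit)^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(params = params,
                 r_squared = r_squared,
                 n_points = n),
            class = "weibull_km_fit")
}

#' @export
print.weibull_km_fit <- function(x, ...) {
  cat(sprintf("Weibull log-log fit over %d KM points (R^2 = %.5f)\n",
              x$n_points, x$r_squared))
  print(x$params)
  invisible(x)
}

#' Cycle structure of the Markov model
#'
#' A 21-day cycle over a 10-year horizon gives
#' `n_cycles = ceiling(3652.5 / 21) = 174`.
#'
#' @param cycle_length_days Cycle length in days (default 21).
#' @param horizon_years Model horizon in years (default 10).
#' @return An object of class `cycle_spec` with fields `cycle_length_days`,
#'   `horizon_years`, `n_cycles` and `u_months` (cycle length in months).
#' @export
cycle_spec <- function(cycle_length_days = 21, horizon_years = 10) {
  stopifnot(is.numeric(cycle_length_days), cycle_length_days > 0,
            is.numeric(horizon_years), horizon_years > 0)
  structure(list(
    cycle_length_days = cycle_length_days,
    horizon_years = horizon_years,
    n_cycles = as.integer(ceiling(horizon_years * DAYS_PER_YEAR /
                                    cycle_length_days)),
    u_months = cycle_length_days / DAYS_PER_MONTH
  ), class = "cycle_spec")
}
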