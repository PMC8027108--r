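# One-way deterministic (tornado) and probabilistic (Monte Carlo)
# sensitivity analyses.

#' Sensitivity-analysis parameter specification
#'
#' Default ranges follow the published convention: costs vary by +/-30% of
#' the base value; utilities and probabilities by +/-20%, clamped to
#' [0, 1]. Survival parameters enter as multiplicative factors (role
#' `"multiplier"`, base 1) on the per-cycle event probabilities, +/-20%
#' with the resulting probabilities clamped to [0, 1] inside the model.
#' The probabilistic standard error defaults to interpreting the range as
#' a 95% central interval: `se = (high - low) / (2 * 1.96)`.
#'
#' @param name Parameter label; must match a model override name (see
#'   [cea_model()]).
#' @param role One of `"cost"`, `"utility"`, `"probability"`,
#'   `"multiplier"`.
#' @param base Base-case value.
#' @param low,high Range bounds; defaults derived from `role`.
#' @param se Standard error for probabilistic sampling; default
#'   `(high - low) / (2 * 1.96)`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, role, base, low = NULL, high = NULL, se = NULL) {
  role <- match.arg(role, c("cost", "utility", "probability", "multiplier"))
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  if (base < 0) stop("`base` must be nonnegative")
  if (is.null(low) || is.null(high)) {
    span <- if (role == "cost") 0.3 else 0.2
    if (is.null(low)) low <- base * (1 - span)
    if (is.null(high)) high <- base * (1 + span)
    if (role %in% c("utility", "probability")) {
      low <- max(0, low); high <- min(1, high)
    }
  }
  if (low > base || base > high) stop("need low <= base <= high for ", name)
  if (is.null(se)) se <- (high - low) / (2 * stats::qnorm(0.975))
  structure(list(name = name, role = role, base = base,
                 low = low, high = high, se = se),
            class = "param_spec")
}

incremental_nmb <- function(arms, wtp) {
  net_benefit(arms$intervention, wtp) - net_benefit(arms$comparator, wtp)
}

#' One-way sensitivity analysis (tornado)
#'
#' Reruns both arms with each parameter at its low and high bound, holding
#' all others at base, and records the incremental net monetary benefit
#' (intervention minus comparator) at each bound. Entries are sorted by
#' spread descending, ties broken by parameter name.
#'
#' @param model_fn A model closure from [cea_model()]: called with a named
#'   list of overrides, returns `list(intervention =, comparator =)` of
#'   [arm_result()]s.
#' @param params List of [param_spec()]s.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A data.frame of class `tornado` with columns `param`,
#'   `low_outcome`, `high_outcome`, `spread`, plus attributes `base_nmb`
#'   and `wtp`.
#' @export
owsa <- function(model_fn, params, wtp = DEFAULT_WTP) {
  stopifnot(is.function(model_fn), length(params) >= 1)
  base_nmb <- incremental_nmb(model_fn(list()), wtp)
  rows <- lapply(params, function(p) {
    stopifnot(inherits(p, "param_spec"))
    lo <- incremental_nmb(model_fn(stats::setNames(list(p$low), p$name)), wtp)
    hi <- incremental_nmb(model_fn(stats::setNames(list(p$high), p$name)), wtp)
    data.frame(param = p$name, low_outcome = lo, high_outcome = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$param), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_nmb") <- base_nmb
  attr(out, "wtp") <- wtp
  class(out) <- c("tornado", "data.frame")
  out
}

#' Gamma distribution from mean and standard error
#'
#' Method-of-moments parameterization used for cost parameters:
#' `shape = mean^2/se^2`, `rate = mean/se^2`.
#'
#' @param mean,se Positive mean and standard error.
#' @return Named numeric vector `c(shape =, rate =)`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("`mean` and `se` must be positive")
  c(shape = mean^2 / se^2, rate = mean / se^2)
}

#' Beta distribution from mean and standard error
#'
#' Method-of-moments parameterization used for utility and probability
#' parameters: with `nu = mean*(1-mean)/se^2 - 1`, `alpha = mean*nu` and
#' `beta = (1-mean)*nu`. A standard error so small that `nu` would exceed
#' 1e9 is capped there with a warning (near point mass).
#'
#' @param mean Mean in (0, 1).
#' @param se Positive standard error with `se^2 < mean*(1-mean)`.
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @export
beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("`mean` must lie strictly in (0, 1)")
  if (se <= 0) stop("`se` must be positive")
  if (se^2 >= mean * (1 - mean))
    stop("`se` too large for a beta distribution with this mean")
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu > 1e9) {
    warning("standard error near zero; capping beta concentration at 1e9")
    nu <- 1e9
  }
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

# One Monte-Carlo realization of a parameter. Costs are gamma; utilities
# and probabilities beta; multipliers 2 x beta (support [0, 2], so a mean
# of 1 is representable). se = 0 or base = 0 degenerate to the base value.
sample_param <- function(p) {
  if (p$se == 0 || p$base == 0) return(p$base)
  switch(p$role,
    cost = {
      g <- gamma_from_moments(p$base, p$se)
      stats::rgamma(1, shape = g[["shape"]], rate = g[["rate"]])
    },
    utility = ,
    probability = {
      b <- beta_from_moments(p$base, p$se)
      stats::rbeta(1, b[["alpha"]], b[["beta"]])
    },
    multiplier = {
      b <- beta_from_moments(p$base / 2, p$se / 2)
      2 * stats::rbeta(1, b[["alpha"]], b[["beta"]])
    }
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration samples every parameter from its
#' assigned distribution (costs: gamma; utilities/probabilities: beta; the
#' adverse-event disutility is sampled as a beta on its magnitude and
#' applied as a decrement; survival multipliers as scaled betas), reruns
#' both arms and records costs and QALYs. Parameters are sampled in sorted
#' name order from a single seeded generator, so draws are stable under
#' configuration reordering. A sampled parameter set that makes the model
#' fail is resampled, up to 100 attempts per iteration.
#'
#' @param model_fn A model closure from [cea_model()].
#' @param params List of [param_spec()]s.
#' @param n Number of iterations (the published analysis used 1,000).
#' @param seed Integer RNG seed.
#' @return A data.frame of class `psa_draws`: columns `draw`, one column
#'   per parameter, `cost_int`, `qaly_int`, `cost_comp`, `qaly_comp`.
#'   Attribute `resamples` counts discarded invalid draws.
#' @export
run_psa <- function(model_fn, params, n = 1000, seed = 42L) {
  stopifnot(is.function(model_fn), n >= 1, length(params) >= 1)
  params <- params[order(vapply(params, `[[`, "", "name"))]
  pnames <- vapply(params, `[[`, "", "name")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)
  resamples <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(100L)) {
      draw <- vapply(params, sample_param, numeric(1))
      names(draw) <- pnames
      arms <- tryCatch(model_fn(as.list(draw)), error = function(e) NULL)
      if (!is.null(arms)) break
      resamples <- resamples + 1L
      if (attempt == 100L) stop("100 consecutive invalid draws at iteration ", i)
    }
    rows[[i]] <- c(draw = i, draw,
                   cost_int = arms$intervention$cost,
                   qaly_int = arms$intervention$qaly,
                   cost_comp = arms$comparator$cost,
                   qaly_comp = arms$comparator$qaly)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("draw", pnames, "cost_int", "qaly_int",
                  "cost_comp", "qaly_comp")
  attr(out, "resamples") <- resamples
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Default willingness-to-pay grid for acceptability curves
#'
#' 0 to twice the default threshold in 100 steps, always including $1,500
#' and $30,828.
#'
#' @param wtp Central willingness-to-pay threshold.
#' @return Ascending numeric vector.
#' @export
default_wtp_grid <- function(wtp = DEFAULT_WTP) {
  # round before deduplicating so inserted anchors merge with coincident
  # grid points instead of leaving near-duplicate values
  sort(unique(round(c(seq(0, 2 * wtp, length.out = 101), 1500, DEFAULT_WTP),
                    6)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic draws
#' in which the intervention has the higher net monetary benefit, together
#' with the mean incremental net monetary benefit (the NMB-acceptability
#' series).
#'
#' @param draws A `psa_draws` data.frame from [run_psa()].
#' @param wtp_grid Nonnegative ascending willingness-to-pay values.
#' @return A data.frame of class `ceac_curve` with columns `wtp`,
#'   `prob_cost_effective`, `mean_inc_nmb`.
#' @export
ceac <- function(draws, wtp_grid = default_wtp_grid()) {
  stopifnot(inherits(draws, "psa_draws"), nrow(draws) >= 1,
            all(wtp_grid >= 0), !is.unsorted(wtp_grid))
  ic <- draws$cost_int - draws$cost_comp
  ie <- draws$qaly_int - draws$qaly_comp
  out <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid,
      function(w) mean(w * ie - ic > 0), numeric(1)),
    mean_inc_nmb = vapply(wtp_grid,
      function(w) mean(w * ie - ic), numeric(1))
  )
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Write tornado results to CSV
#'
#' Columns `param,low_outcome,high_outcome,spread`.
#' @param tornado A `tornado` data.frame from [owsa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  df <- as.data.frame(tornado)
  for (col in c("low_outcome", "high_outcome", "spread"))
    df[[col]] <- round(df[[col]], 2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write probabilistic draws to CSV
#'
#' Columns `draw,<param...>,cost_int,qaly_int,cost_comp,qaly_comp`.
#' @param draws A `psa_draws` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(draws, path) {
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an acceptability curve to CSV
#'
#' Columns `wtp,prob_cost_effective,mean_inc_nmb`.
#' @param curve A `ceac_curve` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Tornado diagram
#'
#' Horizontal bars of incremental net monetary benefit at each parameter's
#' low and high bound, widest spread on top.
#'
#' @param tornado A `tornado` data.frame from [owsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- as.data.frame(tornado)
  df$param <- factor(df$param, levels = rev(df$param))
  base_nmb <- attr(tornado, "base_nmb")
  long <- rbind(
    data.frame(param = df$param, bound = "low", outcome = df$low_outcome),
    data.frame(param = df$param, bound = "high", outcome = df$high_outcome)
  )
  ggplot2::ggplot(long, ggplot2::aes(y = .data$param)) +
    ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$low_outcome, xend = .data$high_outcome,
                   y = .data$param, yend = .data$param),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = 2) +
    ggplot2::labs(x = "Incremental net monetary benefit (USD)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `ceac_curve` data.frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(.data$wtp, .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness-to-pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
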