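# Three-state Markov cohort model: DFS, PD, Death.
# State indices used throughout:
STATE_DFS <- 1L
STATE_PD <- 2L
STATE_DEATH <- 3L

#' Reference patient profile for dose calculation
#'
#' The typical patient used for body-surface-area dosing of intravenous
#' chemotherapy: 1.64 m, 65 kg, BSA 1.72 m^2.
#'
#' @param height Height in metres.
#' @param weight Weight in kilograms.
#' @param bsa Body surface area in square metres, positive.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(height = 1.64, weight = 65, bsa = 1.72) {
  stopifnot(is.numeric(bsa), length(bsa) == 1L)
  if (bsa <= 0) stop("`bsa` must be positive")
  structure(list(height = height, weight = weight, bsa = bsa),
            class = "patient_profile")
}

#' Annual discount rate
#'
#' @param annual_rate Nonnegative fraction per year; 0.03 is the base case.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03) {
  stopifnot(is.numeric(annual_rate), length(annual_rate) == 1L)
  if (annual_rate < 0) stop("`annual_rate` must be nonnegative")
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-(cycle * cycle_length_days) / 365.25)`; equals 1 at
#' cycle 0 and is strictly decreasing in the cycle index.
#'
#' @param cycle Cycle index (0-based time point); vectorized.
#' @param discount A [discount_spec()].
#' @param cycle_length_days Cycle length in days.
#' @return Multipliers in (0, 1].
#' @export
discount_factor <- function(cycle, discount, cycle_length_days = 21) {
  stopifnot(inherits(discount, "discount_spec"), is.numeric(cycle))
  if (any(cycle < 0)) stop("`cycle` must be nonnegative")
  (1 + discount$annual_rate)^(-(cycle * cycle_length_days) / DAYS_PER_YEAR)
}

#' Per-cycle drug acquisition cost schedule
#'
#' Gefitinib: one 250 mg tablet daily at $23.33/tablet, 21 tablets per
#' cycle, for a 24-month course (34 full cycles plus a prorated final
#' partial cycle). Chemotherapy: vinorelbine 25 mg/m^2 on days 1 and 8
#' (10 mg vials at $8.16, rounded up to whole vials per administration)
#' plus cisplatin 75 mg/m^2 on day 1 (30 mg vials at $2.80), for 4 cycles.
#'
#' @param profile A [patient_profile()] for BSA-based dosing.
#' @param arm `"gefitinib"` or `"chemotherapy"`.
#' @param n_cycles Length of the returned schedule.
#' @param unit_costs Named list of unit prices (USD): `gefitinib_tablet`,
#'   `vinorelbine_vial`, `cisplatin_vial`.
#' @return A list with `cost_per_full_cycle` (USD), `fraction` (per-cycle
#'   treatment fraction, length `n_cycles`) and `treatment_cycles` (last
#'   cycle with any treatment).
#' @export
drug_schedule <- function(profile, arm, n_cycles = 174,
                          unit_costs = list(gefitinib_tablet = 23.33,
                                            vinorelbine_vial = 8.16,
                                            cisplatin_vial = 2.80)) {
  stopifnot(inherits(profile, "patient_profile"))
  fraction <- numeric(n_cycles)
  if (identical(arm, "gefitinib")) {
    # 24 months of daily dosing = 730.5 days = 34.786 cycles of 21 days
    cycles_exact <- 24 * DAYS_PER_MONTH / 21
    full <- floor(cycles_exact)
    fraction[seq_len(full)] <- 1
    if (cycles_exact > full && full + 1 <= n_cycles)
      fraction[full + 1] <- cycles_exact - full
    cost <- 21 * unit_costs$gefitinib_tablet
  } else if (identical(arm, "chemotherapy")) {
    fraction[1:4] <- 1
    vino_mg <- 25 * profile$bsa
    cis_mg <- 75 * profile$bsa
    cost <- ceiling(vino_mg / 10) * unit_costs$vinorelbine_vial * 2 +
      ceiling(cis_mg / 30) * unit_costs$cisplatin_vial
  } else {
    stop("unknown arm label: ", arm)
  }
  list(cost_per_full_cycle = cost, fraction = fraction,
       treatment_cycles = max(which(fraction > 0)))
}

#' Arm-specific model strategy
#'
#' Everything that differs (or may differ) between the two comparator
#' arms: the drug-cost schedule, state costs, utilities, adverse-event
#' burden and the fitted DFS/OS survival parameters.
#'
#' @param name Arm label.
#' @param dfs_params,os_params [weibull_params()] fitted to the arm's
#'   disease-free-survival and overall-survival curves.
#' @param drug_cost_per_full_cycle Drug acquisition cost (USD) for one full
#'   treatment cycle.
#' @param treatment_fraction Numeric vector, per-cycle fraction of a full
#'   treatment cycle delivered (1 on treatment, 0 off, fractional for a
#'   prorated final cycle).
#' @param followup_cost Surveillance cost (USD) per cycle, DFS state.
#' @param supportive_cost Supportive-care cost (USD) per cycle, PD state.
#' @param pd_entry_cost One-off cost (USD) charged on entry into PD.
#' @param ae_cost Grade 3-4 adverse-event management cost (USD) per
#'   treatment cycle, applied in expectation.
#' @param ae_incidence Grade 3-4 adverse-event incidence, in [0, 1].
#' @param ae_disutility Utility decrement for grade 3-4 adverse events,
#'   applied in expectation during treatment cycles.
#' @param dfs_utility,pd_utility Health-state utilities in [0, 1];
#'   death is 0.
#' @param dfs_event_multiplier,os_event_multiplier Multiplicative factors
#'   on the per-cycle DFS-event and death probabilities (sensitivity
#'   analyses); resulting probabilities are clamped to [0, 1].
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, dfs_params, os_params,
                          drug_cost_per_full_cycle, treatment_fraction,
                          followup_cost = 55.60, supportive_cost = 337.50,
                          pd_entry_cost = 1877.25, ae_cost = 507.40,
                          ae_incidence, ae_disutility = 0.0731,
                          dfs_utility, pd_utility = 0.70,
                          dfs_event_multiplier = 1, os_event_multiplier = 1) {
  stopifnot(inherits(dfs_params, "weibull_params"),
            inherits(os_params, "weibull_params"),
            is.numeric(treatment_fraction))
  costs <- c(drug_cost_per_full_cycle, followup_cost, supportive_cost,
             pd_entry_cost, ae_cost)
  if (any(costs < 0)) stop("costs must be nonnegative")
  if (ae_incidence < 0 || ae_incidence > 1)
    stop("`ae_incidence` must lie in [0, 1]")
  for (u in c(dfs_utility, pd_utility))
    if (u < 0 || u > 1) stop("utilities must lie in [0, 1]")
  if (ae_disutility < 0) stop("`ae_disutility` is a nonnegative decrement")
  if (any(treatment_fraction < 0) || any(treatment_fraction > 1))
    stop("`treatment_fraction` entries must lie in [0, 1]")
  if (dfs_event_multiplier < 0 || os_event_multiplier < 0)
    stop("event multipliers must be nonnegative")
  treatment_cycles <- if (any(treatment_fraction > 0))
    max(which(treatment_fraction > 0)) else 0L
  structure(list(
    name = name, dfs_params = dfs_params, os_params = os_params,
    drug_cost_per_full_cycle = drug_cost_per_full_cycle,
    treatment_fraction = treatment_fraction,
    treatment_cycles = as.integer(treatment_cycles),
    followup_cost = followup_cost, supportive_cost = supportive_cost,
    pd_entry_cost = pd_entry_cost, ae_cost = ae_cost,
    ae_incidence = ae_incidence, ae_disutility = ae_disutility,
    dfs_utility = dfs_utility, pd_utility = pd_utility,
    dfs_event_multiplier = dfs_event_multiplier,
    os_event_multiplier = os_event_multiplier
  ), class = "strategy_spec")
}

# Per-cycle event probabilities for cycles 1..n, with sensitivity
# multipliers applied and clamped to [0, 1].
cycle_event_probs <- function(strategy, cycles) {
  k <- seq_len(cycles$n_cycles)
  t_end <- k * cycles$u_months
  e_dfs <- transition_probability(strategy$dfs_params, t_end, cycles$u_months)
  p_death <- transition_probability(strategy$os_params, t_end, cycles$u_months)
  list(
    dfs_event = pmin(1, pmax(0, e_dfs * strategy$dfs_event_multiplier)),
    death = pmin(1, pmax(0, p_death * strategy$os_event_multiplier))
  )
}

#' Per-cycle transition matrix
#'
#' Rows and columns are ordered (DFS, PD, Death); Death is absorbing.
#' The death probability for both alive states is the conditional
#' probability from the overall-survival fit, so cohort survival tracks
#' the fitted OS curve exactly. The DFS-event probability (which includes
#' deaths) nets out death to give DFS to PD, floored at 0.
#'
#' @param strategy A [strategy_spec()].
#' @param cycle Cycle index, >= 1.
#' @param cycles A [cycle_spec()].
#' @return A 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(strategy, cycle, cycles = cycle_spec()) {
  stopifnot(inherits(strategy, "strategy_spec"), cycle >= 1)
  u <- cycles$u_months
  t_end <- cycle * u
  e <- min(1, max(0, transition_probability(strategy$dfs_params, t_end, u) *
                    strategy$dfs_event_multiplier))
  p_death <- min(1, max(0, transition_probability(strategy$os_params, t_end, u) *
                          strategy$os_event_multiplier))
  dfs_to_pd <- max(0, e - p_death)
  if (p_death + dfs_to_pd > 1)
    stop("combined transition probabilities exceed 1 at cycle ", cycle)
  m <- matrix(c(1 - p_death - dfs_to_pd, dfs_to_pd, p_death,
                0, 1 - p_death, p_death,
                0, 0, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("DFS", "PD", "Death"),
                              c("DFS", "PD", "Death")))
  m
}

#' Undiscounted cost accrued in one cycle
#'
#' `p_dfs * (followup + drug + I(on treatment) * ae_incidence * ae_cost)
#'  + new_pd * pd_entry_cost + p_pd * supportive_cost`, with occupancy
#' taken at the start of the cycle and `new_pd` the incident PD fraction.
#'
#' @param strategy A [strategy_spec()].
#' @param cycle Cycle index, >= 1.
#' @param p_dfs,p_pd Start-of-cycle state occupancy.
#' @param new_pd Fraction entering PD during the cycle.
#' @return Cost in USD.
#' @export
cycle_cost <- function(strategy, cycle, p_dfs, p_pd, new_pd = 0) {
  stopifnot(cycle >= 1)
  frac <- if (cycle <= length(strategy$treatment_fraction))
    strategy$treatment_fraction[cycle] else 0
  on_tx <- as.numeric(cycle <= strategy$treatment_cycles)
  p_dfs * (strategy$followup_cost +
             frac * strategy$drug_cost_per_full_cycle +
             on_tx * strategy$ae_incidence * strategy$ae_cost) +
    new_pd * strategy$pd_entry_cost +
    p_pd * strategy$supportive_cost
}

#' Undiscounted QALYs accrued in one cycle
#'
#' Utility weight `p_dfs * (dfs_utility - I(on treatment) * ae_incidence *
#' ae_disutility) + p_pd * pd_utility`, converted to QALYs by the cycle
#' length in years (21/365.25).
#'
#' @inheritParams cycle_cost
#' @param cycle_length_days Cycle length in days.
#' @return QALY increment for the cycle.
#' @export
cycle_utility <- function(strategy, cycle, p_dfs, p_pd,
                          cycle_length_days = 21) {
  stopifnot(cycle >= 1)
  on_tx <- as.numeric(cycle <= strategy$treatment_cycles)
  w <- p_dfs * (strategy$dfs_utility -
                  on_tx * strategy$ae_incidence * strategy$ae_disutility) +
    p_pd * strategy$pd_utility
  if (w < -1 || w > 1) stop("utility weight outside [-1, 1] at cycle ", cycle)
  w * cycle_length_days / DAYS_PER_YEAR
}

#' Run the Markov cohort simulation for one arm
#'
#' The whole cohort starts disease-free. Transitions are applied at cycle
#' end; costs and utilities accrue on start-of-cycle occupancy; discounting
#' uses start-of-cycle time. No half-cycle correction is applied.
#'
#' @param strategy A [strategy_spec()].
#' @param cycles A [cycle_spec()].
#' @param discount A [discount_spec()].
#' @param init Initial occupancy (DFS, PD, Death); defaults to (1, 0, 0).
#' @return A `markov_trace`: data.frame with one row per cycle time point
#'   (0..n_cycles) and columns `cycle`, `p_dfs`, `p_pd`, `p_death`,
#'   `new_pd`, `cost`, `qaly`, `disc_cost`, `disc_qaly`. Accrual columns
#'   on row k refer to cycle k (rows with cycle 0 accrue nothing).
#' @export
run_cohort <- function(strategy, cycles = cycle_spec(),
                       discount = discount_spec(), init = c(1, 0, 0)) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(cycles, "cycle_spec"),
            inherits(discount, "discount_spec"),
            length(init) == 3, abs(sum(init) - 1) < 1e-12, all(init >= 0))
  n <- cycles$n_cycles
  probs <- cycle_event_probs(strategy, cycles)
  e <- probs$dfs_event
  d <- probs$death
  # Both alive states share the OS death probability, so the alive
  # fraction and the DFS fraction are plain cumulative products.
  p_dfs <- init[1] * c(1, cumprod(1 - pmax(e, d)))
  p_alive <- (init[1] + init[2]) * c(1, cumprod(1 - d))
  p_pd <- pmax(0, p_alive - p_dfs)
  p_death <- 1 - p_alive
  new_pd <- c(0, p_dfs[seq_len(n)] * pmax(0, e - d))
  # accrual on start-of-cycle occupancy: row k + 1 describes cycle k
  k <- seq_len(n)
  frac <- strategy$treatment_fraction[k]
  frac[is.na(frac)] <- 0
  on_tx <- as.numeric(k <= strategy$treatment_cycles)
  cost <- c(0, p_dfs[k] * (strategy$followup_cost +
                             frac * strategy$drug_cost_per_full_cycle +
                             on_tx * strategy$ae_incidence * strategy$ae_cost) +
              new_pd[k + 1] * strategy$pd_entry_cost +
              p_pd[k] * strategy$supportive_cost)
  w <- p_dfs[k] * (strategy$dfs_utility -
                     on_tx * strategy$ae_incidence * strategy$ae_disutility) +
    p_pd[k] * strategy$pd_utility
  if (any(w < -1 | w > 1)) stop("utility weight outside [-1, 1]")
  qaly <- c(0, w * cycles$cycle_length_days / DAYS_PER_YEAR)
  # cycle k accrues at start-of-cycle time (k - 1) * u; row 1 accrues nothing
  disc <- c(1, discount_factor(0:(n - 1), discount, cycles$cycle_length_days))
  trace <- data.frame(cycle = 0:n, p_dfs = p_dfs, p_pd = p_pd,
                      p_death = p_death, new_pd = new_pd,
                      cost = cost, qaly = qaly,
                      disc_cost = cost * disc, disc_qaly = qaly * disc)
  attr(trace, "strategy_name") <- strategy$name
  class(trace) <- c("markov_trace", "data.frame")
  trace
}

#' Total discounted cost and QALYs of a trace
#'
#' @param trace A `markov_trace` from [run_cohort()].
#' @return An [arm_result()] with the summed discounted cost (USD) and
#'   QALYs.
#' @export
accumulate <- function(trace) {
  stopifnot(inherits(trace, "markov_trace"))
  arm_result(name = attr(trace, "strategy_name") %||% "arm",
             cost = sum(trace$disc_cost), qaly = sum(trace$disc_qaly))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Markov trace to CSV
#'
#' One row per cycle plus a totals row, columns
#' `cycle,p_dfs,p_pd,p_death,new_pd,disc_cost_usd,disc_qaly`.
#'
#' @param trace A `markov_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "markov_trace"))
  df <- data.frame(cycle = as.character(trace$cycle),
                   p_dfs = trace$p_dfs, p_pd = trace$p_pd,
                   p_death = trace$p_death, new_pd = trace$new_pd,
                   disc_cost_usd = round(trace$disc_cost, 2),
                   disc_qaly = trace$disc_qaly)
  totals <- data.frame(cycle = "total", p_dfs = NA, p_pd = NA, p_death = NA,
                       new_pd = sum(trace$new_pd),
                       disc_cost_usd = round(sum(trace$disc_cost), 2),
                       disc_qaly = sum(trace$disc_qaly))
  utils::write.csv(rbind(df, totals), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
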