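# Helper: a minimal strategy with controllable inputs.
toy_strategy <- function(dfs_median = 20, os_median = 60, name = "toy",
                         drug_cost = 0, treatment_cycles = 0,
                         followup = 0, supportive = 0, pd_entry = 0,
                         ae_cost = 0, ae_incidence = 0,
                         dfs_utility = 0.8, pd_utility = 0.7, ...) {
  n <- cycle_spec()$n_cycles
  frac <- c(rep(1, treatment_cycles), rep(0, n - treatment_cycles))
  strategy_spec(name = name,
                dfs_params = params_from_median(dfs_median),
                os_params = params_from_median(os_median),
                drug_cost_per_full_cycle = drug_cost,
                treatment_fraction = frac,
                followup_cost = followup, supportive_cost = supportive,
                pd_entry_cost = pd_entry, ae_cost = ae_cost,
                ae_incidence = ae_incidence, dfs_utility = dfs_utility,
                pd_utility = pd_utility, ...)
}

test_that("discount_factor matches its closed form", {
  d <- discount_spec(0.03)
  expect_equal(discount_factor(0, d), 1)
  expect_equal(discount_factor(0:50, discount_spec(0)), rep(1, 51))
  expect_equal(discount_factor(174, d), 1.03^(-174 * 21 / 365.25))
  expect_equal(discount_factor(174, d), 0.744, tolerance = 1e-3)
  expect_true(all(diff(discount_factor(0:174, d)) < 0))
  expect_error(discount_spec(-0.01), "nonnegative")
})

test_that("drug_schedule prices both arms from unit costs and BSA", {
  prof <- patient_profile()
  chemo <- drug_schedule(prof, "chemotherapy", 174)
  # vinorelbine 25 * 1.72 = 43 mg -> 5 x 10 mg vials, twice; cisplatin
  # 75 * 1.72 = 129 mg -> 5 x 30 mg vials
  expect_equal(chemo$cost_per_full_cycle, 5 * 8.16 * 2 + 5 * 2.80)
  expect_equal(chemo$cost_per_full_cycle, 95.60)
  expect_equal(chemo$fraction[1:4], rep(1, 4))
  expect_equal(chemo$fraction[5:174], rep(0, 170))
  expect_identical(chemo$treatment_cycles, 4L)

  gef <- drug_schedule(prof, "gefitinib", 174)
  expect_equal(gef$cost_per_full_cycle, 21 * 23.33)
  expect_equal(gef$fraction[1:34], rep(1, 34))
  # 24 months = 730.5 days = 34 full cycles + 0.786 of cycle 35
  expect_equal(gef$fraction[35], 24 * 365.25 / 12 / 21 - 34)
  expect_equal(gef$fraction[36:174], rep(0, 139))
  expect_identical(gef$treatment_cycles, 35L)
  # total course cost is independent of proration granularity
  expect_equal(sum(gef$fraction) * gef$cost_per_full_cycle,
               24 * 365.25 / 12 * 23.33)

  expect_error(drug_schedule(prof, "erlotinib"), "unknown arm")
  expect_error(patient_profile(bsa = -1), "positive")
})

test_that("cycle_cost implements the state-cost decomposition", {
  s <- toy_strategy(followup = 55.60, supportive = 337.50,
                    pd_entry = 1877.25)
  # disease-free beyond treatment: follow-up only
  expect_equal(cycle_cost(s, 10, p_dfs = 1, p_pd = 0), 55.60)
  # whole cohort progressed, no new entrants: supportive care only
  expect_equal(cycle_cost(s, 10, p_dfs = 0, p_pd = 1), 337.50)
  # incident progression pays the entry lump sum
  expect_equal(cycle_cost(s, 10, p_dfs = 0.5, p_pd = 0.3, new_pd = 0.1),
               0.5 * 55.60 + 0.1 * 1877.25 + 0.3 * 337.50)

  # gefitinib arm, first cycle, everyone disease-free:
  # follow-up + 21 daily tablets + expected AE management cost
  gef <- toy_strategy(drug_cost = 21 * 23.33, treatment_cycles = 35,
                      followup = 55.60, ae_cost = 507.40,
                      ae_incidence = 0.12)
  expect_equal(cycle_cost(gef, 1, p_dfs = 1, p_pd = 0),
               55.60 + 21 * 23.33 + 0.12 * 507.40)
  expect_equal(cycle_cost(gef, 1, p_dfs = 1, p_pd = 0), 606.418)
  # after treatment ends the drug and AE terms vanish
  expect_equal(cycle_cost(gef, 36, p_dfs = 1, p_pd = 0), 55.60)
})

test_that("cycle_utility weights occupancy by state utilities", {
  s <- toy_strategy(dfs_utility = 0.8, pd_utility = 0.7)
  yr <- 21 / 365.25
  expect_equal(cycle_utility(s, 5, p_dfs = 0, p_pd = 0), 0)  # all dead
  expect_equal(cycle_utility(s, 5, p_dfs = 0, p_pd = 1), 0.7 * yr)
  gef <- toy_strategy(dfs_utility = 0.8, ae_incidence = 0.12,
                      treatment_cycles = 35)
  expect_equal(cycle_utility(gef, 1, p_dfs = 1, p_pd = 0),
               (0.8 - 0.12 * 0.0731) * yr)
  # AE decrement only during treatment
  expect_equal(cycle_utility(gef, 36, p_dfs = 1, p_pd = 0), 0.8 * yr)
})

test_that("transition_matrix rows are stochastic and match the survival fits", {
  s <- toy_strategy()
  cs <- cycle_spec()
  for (k in c(1, 10, 100, 174)) {
    m <- transition_matrix(s, k, cs)
    expect_equal(rowSums(m), c(DFS = 1, PD = 1, Death = 1), tolerance = 1e-12)
    expect_equal(m["Death", ], c(DFS = 0, PD = 0, Death = 1))
    expect_true(all(m >= 0 & m <= 1))
  }
  # re-derive cycle 10 from the conditional-survival oracle
  m10 <- transition_matrix(s, 10, cs)
  u <- cs$u_months
  p_death <- 1 - weibull_survival(s$os_params, 10 * u) /
    weibull_survival(s$os_params, 9 * u)
  e <- 1 - weibull_survival(s$dfs_params, 10 * u) /
    weibull_survival(s$dfs_params, 9 * u)
  expect_equal(m10["DFS", "Death"], p_death, tolerance = 1e-12)
  expect_equal(m10["PD", "Death"], p_death, tolerance = 1e-12)
  expect_equal(m10["DFS", "PD"], e - p_death, tolerance = 1e-12)

  # zero event probabilities give the identity matrix
  null_s <- toy_strategy(dfs_median = 1e12, os_median = 1e12)
  expect_equal(transition_matrix(null_s, 50, cs), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the DFS row reproduces the stated decomposition arithmetic", {
  # event prob 0.10 with death prob 0.03 must split as (0.90, 0.07, 0.03);
  # calibrate exponential curves to those per-cycle probabilities
  cs <- cycle_spec()
  u <- cs$u_months
  s <- toy_strategy()
  s$dfs_params <- weibull_params(-log(1 - 0.10) / u, 1)
  s$os_params <- weibull_params(-log(1 - 0.03) / u, 1)
  m <- transition_matrix(s, 7, cs)
  expect_equal(unname(m["DFS", ]), c(0.90, 0.07, 0.03), tolerance = 1e-12)
})

test_that("run_cohort conserves occupancy and tracks the OS curve", {
  cfg <- fixture_config()
  cs <- cycle_spec()
  for (s in adjuvantCEA:::build_strategies(cfg)) {
    tr <- run_cohort(s, cs, discount_spec(0.03))
    expect_equal(tr$p_dfs + tr$p_pd + tr$p_death, rep(1, 175),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$p_death) >= 0))
    expect_true(all(tr$p_dfs >= 0 & tr$p_pd >= 0))
    # cohort survival equals the fitted OS curve at every cycle boundary
    os <- weibull_survival(s$os_params, tr$cycle * cs$u_months)
    expect_equal(1 - tr$p_death, os, tolerance = 1e-10)
  }
})

test_that("run_cohort matches closed forms in degenerate cases", {
  # stationary cohort: no transitions, utility 0.8, no discounting
  s <- toy_strategy(dfs_median = 1e15, os_median = 1e15, followup = 55.60)
  tr <- run_cohort(s, cycle_spec(), discount_spec(0))
  expect_equal(sum(tr$qaly), 174 * (21 / 365.25) * 0.8, tolerance = 1e-6)
  expect_equal(sum(tr$cost), 174 * 55.60, tolerance = 1e-6)
  res <- accumulate(tr)
  expect_equal(res$qaly, 174 * (21 / 365.25) * 0.8, tolerance = 1e-6)

  # cohort started dead accrues nothing
  dead <- run_cohort(toy_strategy(followup = 50), cycle_spec(),
                     discount_spec(0.03), init = c(0, 0, 1))
  expect_equal(sum(dead$disc_cost), 0)
  expect_equal(sum(dead$disc_qaly), 0)

  # discounting can only shrink totals
  s2 <- toy_strategy(followup = 55.6, supportive = 337.5)
  undisc <- run_cohort(s2, cycle_spec(), discount_spec(0))
  disc <- run_cohort(s2, cycle_spec(), discount_spec(0.03))
  expect_lt(sum(disc$disc_cost), sum(undisc$disc_cost))
  expect_lt(sum(disc$disc_qaly), sum(undisc$disc_qaly))
})

test_that("modeled median time to DFS event matches the input median", {
  cfg <- fixture_config()
  cs <- cycle_spec()
  strategies <- adjuvantCEA:::build_strategies(cfg)
  medians <- c(30.8, 19.8)
  for (i in 1:2) {
    tr <- run_cohort(strategies[[i]], cs, discount_spec(0))
    k_median <- min(which(tr$p_dfs <= 0.5)) - 1  # rows are cycle 0..n
    t_median <- k_median * cs$u_months
    expect_lt(abs(t_median - medians[i]), cs$u_months)
  }
})

test_that("raising utilities or costs weakly raises the respective total", {
  base <- toy_strategy(followup = 55.6, supportive = 337.5, pd_entry = 1877,
                       dfs_utility = 0.8, pd_utility = 0.7)
  cs <- cycle_spec(); d <- discount_spec(0.03)
  r0 <- accumulate(run_cohort(base, cs, d))
  up_u <- toy_strategy(followup = 55.6, supportive = 337.5, pd_entry = 1877,
                       dfs_utility = 0.9, pd_utility = 0.7)
  up_c <- toy_strategy(followup = 80, supportive = 337.5, pd_entry = 1877,
                       dfs_utility = 0.8, pd_utility = 0.7)
  expect_gt(accumulate(run_cohort(up_u, cs, d))$qaly, r0$qaly)
  expect_gt(accumulate(run_cohort(up_c, cs, d))$cost, r0$cost)
})

test_that("halving the cycle length changes total QALYs by less than 1%", {
  cfg <- fixture_config()
  for (s in adjuvantCEA:::build_strategies(cfg)) {
    q21 <- accumulate(run_cohort(s, cycle_spec(21, 10), discount_spec(0.03)))$qaly
    q10 <- accumulate(run_cohort(s, cycle_spec(10.5, 10), discount_spec(0.03)))$qaly
    expect_lt(abs(q21 - q10) / q21, 0.01)
  }
})

test_that("trace CSV has the documented layout with a totals row", {
  s <- toy_strategy(followup = 10)
  tr <- run_cohort(s, cycle_spec(), discount_spec(0.03))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  df <- utils::read.csv(path)
  expect_named(df, c("cycle", "p_dfs", "p_pd", "p_death", "new_pd",
                     "disc_cost_usd", "disc_qaly"))
  expect_equal(nrow(df), 176)  # cycles 0..174 plus totals
  expect_equal(df$cycle[176], "total")
  expect_equal(df$disc_cost_usd[176], round(sum(tr$disc_cost), 2))
})
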