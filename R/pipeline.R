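# Configuration validation, model construction and run orchestration.

config_defaults <- function() {
  list(schema_version = 1L,
       wtp = DEFAULT_WTP,
       cycles = list(cycle_length_days = 21, horizon_years = 10),
       discount = list(annual_rate = 0.03),
       patient = list(height = 1.64, weight = 65, bsa = 1.72),
       unit_costs = list(gefitinib_tablet = 23.33, vinorelbine_vial = 8.16,
                         cisplatin_vial = 2.80),
       psa = list(n = 1000L, seed = 42L, se_convention = "range/(2*1.96)"),
       metadata = list())
}

check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown configuration key(s) at ", path, ": ",
         paste(extra, collapse = ", "))
}

check_number <- function(x, path, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(path, " must be a single finite number")
  if (x < min || x > max)
    stop(path, " = ", x, " outside allowed range [", min, ", ", max, "]")
  x
}

#' Validate a model configuration
#'
#' Accepts a YAML/JSON file path or an already-parsed list; type- and
#' range-checks every field against the model schema, rejects unknown keys
#' with the offending path, and fills defaults only for the quantities the
#' base-case analysis fixes (WTP $30,828/QALY, 3% annual discounting,
#' 21-day cycles over 10 years, the reference patient and unit drug
#' prices).
#'
#' A strategy block needs `name`, `arm` (`"gefitinib"`, `"chemotherapy"`
#' or `"custom"` with an explicit `drug_cost_per_full_cycle` and
#' `treatment_cycles`), survival calibration (either `dfs_median` /
#' `os_median` with `shape`, or explicit `dfs_scale`/`dfs_shape` and
#' `os_scale`/`os_shape`), costs, utilities and the adverse-event burden.
#' Exactly two strategies are required; the first is the intervention.
#'
#' @param config Path to a YAML or JSON file, or a list.
#' @return A validated object of class `cea_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  check_keys(config, c("schema_version", "wtp", "cycles", "discount",
                       "patient", "strategies", "unit_costs", "psa",
                       "owsa", "metadata"), "<root>")
  defaults <- config_defaults()
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  for (key in names(defaults$psa))
    if (is.null(config$psa[[key]])) config$psa[[key]] <- defaults$psa[[key]]

  check_keys(config$cycles, c("cycle_length_days", "horizon_years"),
             "cycles")
  check_number(config$cycles$cycle_length_days, "cycles.cycle_length_days",
               min = 1)
  check_number(config$cycles$horizon_years, "cycles.horizon_years",
               min = 0.1)
  check_keys(config$discount, "annual_rate", "discount")
  check_number(config$discount$annual_rate, "discount.annual_rate", min = 0)
  check_number(config$wtp, "wtp", min = 0)
  check_keys(config$patient, c("height", "weight", "bsa"), "patient")
  check_number(config$patient$bsa, "patient.bsa", min = 0.1)
  check_keys(config$psa, c("n", "seed", "se_convention"), "psa")
  check_number(config$psa$n, "psa.n", min = 1)

  if (is.null(config$strategies) || length(config$strategies) != 2L)
    stop("strategies: exactly two strategy blocks are required ",
         "(two-arm model); got ", length(config$strategies))
  strategy_keys <- c("name", "arm", "dfs_median", "os_median", "shape",
                     "dfs_scale", "dfs_shape", "os_scale", "os_shape",
                     "dfs_km_csv", "os_km_csv",
                     "drug_cost_per_full_cycle", "treatment_cycles",
                     "followup_cost", "supportive_cost", "pd_entry_cost",
                     "ae_cost", "ae_incidence", "ae_disutility",
                     "dfs_utility", "pd_utility")
  for (i in 1:2) {
    s <- config$strategies[[i]]
    path <- paste0("strategies[", i, "]")
    check_keys(s, strategy_keys, path)
    if (is.null(s$name)) stop(path, ".name is required")
    for (f in c("followup_cost", "supportive_cost", "pd_entry_cost",
                "ae_cost"))
      check_number(s[[f]], paste0(path, ".", f), min = 0)
    for (f in c("dfs_utility", "pd_utility"))
      check_number(s[[f]], paste0(path, ".", f), min = 0, max = 1)
    check_number(s$ae_incidence, paste0(path, ".ae_incidence"),
                 min = 0, max = 1)
    check_number(s$ae_disutility, paste0(path, ".ae_disutility"),
                 min = 0, max = 1)
    has_median <- !is.null(s$dfs_median) && !is.null(s$os_median)
    has_scale <- !is.null(s$dfs_scale) && !is.null(s$os_scale)
    has_km <- !is.null(s$dfs_km_csv) && !is.null(s$os_km_csv)
    if (!has_median && !has_scale && !has_km)
      stop(path, ": survival calibration required (medians, explicit ",
           "scale/shape, or KM CSV paths)")
    if (is.null(s$arm)) stop(path, ".arm is required")
    if (!s$arm %in% c("gefitinib", "chemotherapy", "custom"))
      stop(path, ".arm must be gefitinib, chemotherapy or custom")
    if (s$arm == "custom" &&
        (is.null(s$drug_cost_per_full_cycle) || is.null(s$treatment_cycles)))
      stop(path, ": custom arm needs drug_cost_per_full_cycle and ",
           "treatment_cycles")
  }
  if (config$strategies[[1]]$name == config$strategies[[2]]$name)
    stop("strategies: the two arms must have distinct names")
  structure(config, class = c("cea_config", "list"))
}

# Survival parameters for one strategy block, fitting KM CSVs when given.
strategy_survival_params <- function(s) {
  get_params <- function(scale, shape, median, default_shape, km_path) {
    if (!is.null(km_path)) {
      fit <- fit_weibull_to_km(read_km_csv(km_path))
      return(list(params = fit$params, fit = fit))
    }
    if (!is.null(scale))
      return(list(params = weibull_params(scale, shape %||% 1), fit = NULL))
    list(params = params_from_median(median, default_shape %||% 1),
         fit = NULL)
  }
  list(dfs = get_params(s$dfs_scale, s$dfs_shape, s$dfs_median, s$shape,
                        s$dfs_km_csv),
       os = get_params(s$os_scale, s$os_shape, s$os_median, s$shape,
                       s$os_km_csv))
}

# Build the two strategy_spec objects from a validated config, applying
# named sensitivity overrides (see cea_model for the naming scheme).
build_strategies <- function(config, overrides = list()) {
  n_cycles <- cycle_spec(config$cycles$cycle_length_days,
                         config$cycles$horizon_years)$n_cycles
  profile <- patient_profile(config$patient$height, config$patient$weight,
                             config$patient$bsa)
  lapply(config$strategies, function(s) {
    surv <- strategy_survival_params(s)
    if (s$arm == "custom") {
      frac <- c(rep(1, s$treatment_cycles),
                rep(0, max(0, n_cycles - s$treatment_cycles)))
      sched <- list(cost_per_full_cycle = s$drug_cost_per_full_cycle,
                    fraction = frac)
    } else {
      sched <- drug_schedule(profile, s$arm, n_cycles, config$unit_costs)
    }
    ov <- function(field, value) {
      key_arm <- paste0(field, "_", s$name)
      if (!is.null(overrides[[key_arm]])) overrides[[key_arm]]
      else if (!is.null(overrides[[field]])) overrides[[field]]
      else value
    }
    clamp01 <- function(x, what) {
      if (x < 0 || x > 1) {
        warning(what, " override ", signif(x, 4), " clamped to [0, 1]")
        x <- min(1, max(0, x))
      }
      x
    }
    strategy_spec(
      name = s$name,
      dfs_params = surv$dfs$params, os_params = surv$os$params,
      drug_cost_per_full_cycle = ov("drug_cost", sched$cost_per_full_cycle),
      treatment_fraction = sched$fraction,
      followup_cost = ov("followup_cost", s$followup_cost),
      supportive_cost = ov("supportive_cost", s$supportive_cost),
      pd_entry_cost = ov("pd_entry_cost", s$pd_entry_cost),
      ae_cost = ov("ae_cost", s$ae_cost),
      ae_incidence = clamp01(ov("ae_incidence", s$ae_incidence),
                             "ae_incidence"),
      ae_disutility = clamp01(ov("ae_disutility", s$ae_disutility),
                              "ae_disutility"),
      dfs_utility = clamp01(ov("utility_dfs", s$dfs_utility), "utility_dfs"),
      pd_utility = clamp01(ov("utility_pd", s$pd_utility), "utility_pd"),
      dfs_event_multiplier = ov("surv_mult_dfs", 1),
      os_event_multiplier = ov("surv_mult_os", 1)
    )
  })
}

#' Build a re-runnable two-arm model closure
#'
#' Returns a function of a named override list that rebuilds both
#' strategies, runs the Markov cohort for each and returns
#' `list(intervention =, comparator =)` of [arm_result()]s. Override names
#' are either shared across arms (`followup_cost`, `supportive_cost`,
#' `pd_entry_cost`, `ae_cost`, `utility_pd`, `ae_disutility`) or
#' arm-specific with the strategy name suffixed
#' (`drug_cost_<arm>`, `utility_dfs_<arm>`, `ae_incidence_<arm>`,
#' `surv_mult_dfs_<arm>`, `surv_mult_os_<arm>`). Utility and probability
#' overrides outside [0, 1] are clamped with a warning.
#'
#' @param config A validated `cea_config` (see [validate_config()]).
#' @return A function `function(overrides = list())`.
#' @export
cea_model <- function(config) {
  config <- validate_config(config)
  cycles <- cycle_spec(config$cycles$cycle_length_days,
                       config$cycles$horizon_years)
  discount <- discount_spec(config$discount$annual_rate)
  function(overrides = list()) {
    strategies <- build_strategies(config, overrides)
    arms <- lapply(strategies, function(s)
      accumulate(run_cohort(s, cycles, discount)))
    list(intervention = arms[[1]], comparator = arms[[2]])
  }
}

#' Default sensitivity-analysis parameter set
#'
#' One [param_spec()] per model input varied in the published analysis:
#' per-arm drug cost, DFS utility, adverse-event incidence and survival
#' multipliers, plus the shared follow-up, supportive-care, PD-entry and
#' adverse-event costs, PD utility and adverse-event disutility. Ranges
#' are +/-30% for costs and +/-20% for utilities, probabilities and
#' survival multipliers.
#'
#' @param config A validated `cea_config`.
#' @return Named list of [param_spec()]s.
#' @export
default_param_specs <- function(config) {
  config <- validate_config(config)
  s1 <- config$strategies[[1]]; s2 <- config$strategies[[2]]
  profile <- patient_profile(config$patient$height, config$patient$weight,
                             config$patient$bsa)
  specs <- list()
  add <- function(name, role, base) {
    specs[[name]] <<- param_spec(name, role, base)
  }
  for (s in list(s1, s2)) {
    drug_cost <- if (s$arm == "custom") s$drug_cost_per_full_cycle
    else drug_schedule(profile, s$arm, 1, config$unit_costs)$cost_per_full_cycle
    add(paste0("drug_cost_", s$name), "cost", drug_cost)
    add(paste0("utility_dfs_", s$name), "utility", s$dfs_utility)
    add(paste0("ae_incidence_", s$name), "probability", s$ae_incidence)
    add(paste0("surv_mult_dfs_", s$name), "multiplier", 1)
    add(paste0("surv_mult_os_", s$name), "multiplier", 1)
  }
  shared <- function(field, name, role) {
    if (isTRUE(all.equal(s1[[field]], s2[[field]]))) {
      add(name, role, s1[[field]])
    } else {
      add(paste0(name, "_", s1$name), role, s1[[field]])
      add(paste0(name, "_", s2$name), role, s2[[field]])
    }
  }
  shared("followup_cost", "followup_cost", "cost")
  shared("supportive_cost", "supportive_cost", "cost")
  shared("pd_entry_cost", "pd_entry_cost", "cost")
  shared("ae_cost", "ae_cost", "cost")
  shared("pd_utility", "utility_pd", "utility")
  shared("ae_disutility", "ae_disutility", "utility")
  specs
}

config_hash <- function(config) {
  core <- unclass(config)
  core$metadata <- NULL
  json <- jsonlite::toJSON(core, auto_unbox = TRUE, digits = 15)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages against a validated configuration and
#' writes a deterministic file set to `out_dir`: a fitted-parameter report
#' (`fitted_params.csv`), per-arm Markov traces (`trace_<arm>.csv`), the
#' base-case results table (`results.csv`), the tornado table
#' (`tornado.csv`), probabilistic draws and acceptability curve
#' (`psa_draws.csv`, `ceac.csv`) and a run manifest (`manifest.json`) with
#' the seed, a configuration hash, package version and stage timings.
#' Identical configuration and seed reproduce all CSVs byte for byte.
#'
#' @param config A `cea_config`, or a path to a YAML/JSON config file.
#' @param stages Character subset of `c("fit", "base-case", "owsa",
#'   "psa")`; `"owsa"` and `"psa"` require `"base-case"`.
#' @param out_dir Output directory, created if needed.
#' @param psa_n,psa_seed Override the configuration's PSA iteration count
#'   and seed.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the computed objects (`fits`, `traces`,
#'   `result`, `tornado`, `psa`, `ceac_curve`) and `files` written.
#' @export
run_pipeline <- function(config, stages = c("fit", "base-case"),
                         out_dir = tempfile("cea_run_"),
                         psa_n = NULL, psa_seed = NULL, quiet = FALSE) {
  config <- validate_config(config)
  stages <- match.arg(stages, c("fit", "base-case", "owsa", "psa"),
                      several.ok = TRUE)
  needs_base <- intersect(stages, c("owsa", "psa"))
  if (length(needs_base) && !"base-case" %in% stages)
    stop("stage dependency unsatisfied: ",
         paste(needs_base, collapse = ", "),
         " require stages: base-case")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  cycles <- cycle_spec(config$cycles$cycle_length_days,
                       config$cycles$horizon_years)
  discount <- discount_spec(config$discount$annual_rate)
  out <- list(files = character())
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  if ("fit" %in% stages) {
    say("stage fit: survival parameters per curve")
    fits <- clock("fit", {
      rows <- lapply(config$strategies, function(s) {
        surv <- strategy_survival_params(s)
        do.call(rbind, lapply(c("dfs", "os"), function(curve) {
          p <- surv[[curve]]
          data.frame(curve_id = paste0(s$name, "_", curve),
                     scale = p$params$scale, shape = p$params$shape,
                     r_squared = if (is.null(p$fit)) NA_real_
                                 else p$fit$r_squared,
                     n_points = if (is.null(p$fit)) 0L else p$fit$n_points)
        }))
      })
      do.call(rbind, rows)
    })
    path <- file.path(out_dir, "fitted_params.csv")
    utils::write.csv(fits, path, row.names = FALSE, quote = FALSE, na = "")
    out$fits <- fits
    out$files <- c(out$files, path)
  }

  model <- cea_model(config)

  if ("base-case" %in% stages) {
    say("stage base-case: Markov cohort, ", cycles$n_cycles, " cycles")
    res <- clock("base-case", {
      strategies <- build_strategies(config)
      traces <- lapply(strategies, run_cohort, cycles = cycles,
                       discount = discount)
      arms <- lapply(traces, accumulate)
      list(traces = traces,
           result = compare_arms(arms[[1]], arms[[2]], config$wtp))
    })
    for (tr in res$traces) {
      path <- file.path(out_dir,
                        paste0("trace_", attr(tr, "strategy_name"), ".csv"))
      write_trace_csv(tr, path)
      out$files <- c(out$files, path)
    }
    path <- file.path(out_dir, "results.csv")
    write_results_csv(res$result, path)
    out$traces <- res$traces
    out$result <- res$result
    out$files <- c(out$files, path)
  }

  params <- if (any(c("owsa", "psa") %in% stages))
    default_param_specs(config) else NULL

  if ("owsa" %in% stages) {
    say("stage owsa: ", length(params), " parameters")
    tor <- clock("owsa", owsa(model, params, config$wtp))
    path <- file.path(out_dir, "tornado.csv")
    write_tornado_csv(tor, path)
    out$tornado <- tor
    out$files <- c(out$files, path)
  }

  if ("psa" %in% stages) {
    n <- psa_n %||% config$psa$n
    seed <- psa_seed %||% config$psa$seed
    say("stage psa: ", n, " iterations, seed ", seed)
    draws <- clock("psa", run_psa(model, params, n = n, seed = seed))
    curve <- ceac(draws, default_wtp_grid(config$wtp))
    p1 <- file.path(out_dir, "psa_draws.csv")
    p2 <- file.path(out_dir, "ceac.csv")
    write_psa_csv(draws, p1)
    write_ceac_csv(curve, p2)
    out$psa <- draws
    out$ceac_curve <- curve
    out$files <- c(out$files, p1, p2)
  }

  manifest <- list(
    package = "adjuvantCEA",
    version = as.character(utils::packageVersion("adjuvantCEA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    config_hash = config_hash(config),
    psa_seed = if ("psa" %in% stages) psa_seed %||% config$psa$seed else NULL,
    timings_s = timings
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  out$files <- c(out$files, mpath)
  out$manifest <- manifest
  invisible(out)
}
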