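# Shared fixtures: the paper-medians configuration and its base-case run,
# built once per test session.

fixture_config <- function() {
  if (is.null(.fixture_env$config))
    .fixture_env$config <- make_fixture("paper-medians")
  .fixture_env$config
}

fixture_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- cea_model(fixture_config())
  .fixture_env$model
}

fixture_base_case <- function() {
  if (is.null(.fixture_env$base)) {
    arms <- fixture_model()(list())
    .fixture_env$base <- compare_arms(arms$intervention, arms$comparator,
                                      fixture_config()$wtp)
  }
  .fixture_env$base
}

.fixture_env <- new.env(parent = emptyenv())

# A noise-free KM curve sampled exactly from a Weibull survival function.
exact_km_curve <- function(params, times) {
  km_curve(times, weibull_survival(params, times))
}
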