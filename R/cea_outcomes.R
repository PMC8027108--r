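# Cost-effectiveness arithmetic: ICER, ACER, net monetary benefit,
# dominance classification.

#' Default willingness-to-pay threshold (USD/QALY)
#'
#' Three times the per-capita gross domestic product of China at the time
#' of the analysis: $30,828 per QALY.
#' @export
DEFAULT_WTP <- 30828

#' Per-arm totals
#'
#' @param name Arm label.
#' @param cost Total discounted cost, USD, finite and nonnegative.
#' @param qaly Total discounted QALYs, finite and nonnegative.
#' @return An object of class `arm_result`.
#' @export
arm_result <- function(name, cost, qaly) {
  stopifnot(is.numeric(cost), is.numeric(qaly),
            length(cost) == 1L, length(qaly) == 1L)
  if (!is.finite(cost) || !is.finite(qaly) || cost < 0 || qaly < 0)
    stop("cost and qaly must be finite and nonnegative")
  structure(list(name = name, cost = cost, qaly = qaly),
            class = "arm_result")
}

#' Average cost-effectiveness ratio
#'
#' Cost per QALY within one arm: `cost / qaly`.
#'
#' @param arm An [arm_result()] with `qaly > 0`.
#' @return USD per QALY. `NA` with a warning when `qaly` is 0.
#' @export
acer <- function(arm) {
  stopifnot(inherits(arm, "arm_result"))
  if (arm$qaly == 0) {
    warning("ACER undefined: zero QALYs in arm ", arm$name)
    return(NA_real_)
  }
  arm$cost / arm$qaly
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; may be negative.
#'
#' @param arm An [arm_result()].
#' @param wtp Willingness-to-pay threshold, USD/QALY, nonnegative.
#' @return USD.
#' @export
net_benefit <- function(arm, wtp = DEFAULT_WTP) {
  stopifnot(inherits(arm, "arm_result"), is.numeric(wtp), length(wtp) == 1L)
  if (wtp < 0) stop("`wtp` must be nonnegative")
  wtp * arm$qaly - arm$cost
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost (IC) and effect (IE), the ICER when it is a
#' meaningful ratio, per-arm ACERs and net monetary benefits, and a
#' dominance classification. An intervention that is at least as cheap and
#' more effective is dominant (the ICER is not reported as a ratio); one
#' that is costlier and less effective is dominated. The cost-effectiveness
#' verdict at the given WTP equals the net-monetary-benefit ordering.
#'
#' @param intervention,comparator [arm_result()] objects.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return An object of class `cea_result`: list with `intervention`,
#'   `comparator`, `ic`, `ie`, `icer` (`NA` under dominance or IE = 0),
#'   `acer_intervention`, `acer_comparator`, `nmb_intervention`,
#'   `nmb_comparator`, `wtp`, `dominance` (one of `"none"`,
#'   `"intervention-dominant"`, `"intervention-dominated"`) and
#'   `cost_effective` (logical).
#' @export
#' @examples
#' gef <- arm_result("gefitinib", 12057.98, 12057.98 / 7802.30)
#' chemo <- arm_result("chemotherapy", 11883.73, 11883.73 / 8392.77)
#' compare_arms(gef, chemo)
compare_arms <- function(intervention, comparator, wtp = DEFAULT_WTP) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  ic <- intervention$cost - comparator$cost
  ie <- intervention$qaly - comparator$qaly
  nmb_i <- net_benefit(intervention, wtp)
  nmb_c <- net_benefit(comparator, wtp)
  dominance <- "none"
  icer <- NA_real_
  if (ie > 0 && ic <= 0) {
    dominance <- "intervention-dominant"
  } else if (ie < 0 && ic >= 0) {
    dominance <- "intervention-dominated"
  } else if (ie != 0) {
    icer <- ic / ie
  }
  # ie == 0, ic != 0: icer undefined; verdict decided by sign of -ic
  structure(list(
    intervention = intervention, comparator = comparator,
    ic = ic, ie = ie, icer = icer,
    acer_intervention = acer(intervention),
    acer_comparator = acer(comparator),
    nmb_intervention = nmb_i, nmb_comparator = nmb_c,
    wtp = wtp, dominance = dominance,
    cost_effective = nmb_i > nmb_c ||
      (nmb_i == nmb_c && dominance == "none" && ic <= 0)
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness comparison (WTP = $%s/QALY)\n",
              format(x$wtp, big.mark = ",")))
  df <- cea_result_table(x)
  print(format(df, digits = 6), row.names = FALSE)
  if (x$dominance != "none") {
    cat("Dominance:", x$dominance, "\n")
  } else if (!is.na(x$icer)) {
    cat(sprintf("ICER: $%.2f/QALY (%s at this WTP)\n", x$icer,
                if (x$cost_effective) "cost-effective" else
                  "not cost-effective"))
  }
  invisible(x)
}

#' Results table in standard column order
#'
#' `arm,qaly,ie,cost,ic,icer,acer,net_benefit`, intervention row first.
#'
#' @param result A `cea_result` from [compare_arms()].
#' @return A data.frame with two rows.
#' @export
cea_result_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  data.frame(
    arm = c(result$intervention$name, result$comparator$name),
    qaly = c(result$intervention$qaly, result$comparator$qaly),
    ie = c(result$ie, NA),
    cost = c(result$intervention$cost, result$comparator$cost),
    ic = c(result$ic, NA),
    icer = c(result$icer, NA),
    acer = c(result$acer_intervention, result$acer_comparator),
    net_benefit = c(result$nmb_intervention, result$nmb_comparator)
  )
}

#' Write the comparison table to CSV
#'
#' Monetary values are rounded to cents at serialization only.
#'
#' @param result A `cea_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result, path) {
  df <- cea_result_table(result)
  for (col in c("cost", "ic", "icer", "acer", "net_benefit"))
    df[[col]] <- round(df[[col]], 2)
  df$qaly <- round(df$qaly, 6)
  df$ie <- round(df$ie, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
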