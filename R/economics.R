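#' Incremental cost-effectiveness ratio between two strategy results
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`. When the QALY difference is below
#' `1e-12` in magnitude the ratio is undefined and `NA` is returned with the
#' deltas; that is a value, not an error.
#'
#' @param a,b results from [run_cohort()], or any lists with `expected_cost`
#'   and `expected_qaly`.
#' @return list with `delta_cost`, `delta_qaly`, `icer` (NA when undefined),
#'   `defined`.
#' @export
icer <- function(a, b) {
  dc <- a$expected_cost - b$expected_cost
  dq <- a$expected_qaly - b$expected_qaly
  defined <- abs(dq) >= 1e-12
  list(delta_cost = dc, delta_qaly = dq,
       icer = if (defined) dc / dq else NA_real_,
       defined = defined)
}

#' Net monetary benefit
#'
#' @param result a strategy result (or list with `expected_cost`,
#'   `expected_qaly`).
#' @param wtp willingness to pay, USD per QALY (nonnegative).
#' @return `wtp * qaly - cost`, USD.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$expected_qaly - result$expected_cost
}

#' Compare strategies against a comparator
#'
#' Labels each strategy against the comparator by cost-effectiveness-plane
#' quadrant: `dominant` (cheaper and more effective), `cost_effective`
#' (northeast quadrant with ICER below the willingness-to-pay, or southwest
#' quadrant with ICER — cost saved per QALY forgone — above it),
#' `not_optimal` otherwise, and `comparator` for the reference row. The
#' NMB-maximising strategy is flagged `optimal` (ties broken toward lower
#' cost).
#'
#' @param results data.frame from [run_strategies()], or a named list of
#'   [run_cohort()] results.
#' @param comparator strategy name used as reference.
#' @param wtp willingness to pay, USD per QALY.
#' @return data.frame of class `ich_comparison`: `strategy`, `cost`, `qaly`,
#'   `delta_cost`, `delta_qaly`, `icer`, `classification`, `nmb`, `optimal`.
#' @export
classify_strategies <- function(results, comparator = "DSA_STRATIFIED",
                                wtp = 100000) {
  results <- as_result_frame(results)
  if (!comparator %in% results$strategy)
    stop("comparator '", comparator, "' not among results", call. = FALSE)
  comp <- results[results$strategy == comparator, ]
  dc <- results$cost - comp$cost
  dq <- results$qaly - comp$qaly
  ic <- ifelse(abs(dq) >= 1e-12, dc / dq, NA_real_)
  cls <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    if (results$strategy[i] == comparator) {
      cls[i] <- "comparator"
    } else if (dc[i] < 0 && dq[i] > 0) {
      cls[i] <- "dominant"
    } else if (dq[i] > 0 && dc[i] >= 0 && !is.na(ic[i]) && ic[i] < wtp) {
      cls[i] <- "cost_effective"
    } else if (dq[i] < 0 && dc[i] < 0 && !is.na(ic[i]) && ic[i] > wtp) {
      # southwest: savings per QALY forgone exceed what we would pay for it
      cls[i] <- "cost_effective"
    } else {
      cls[i] <- "not_optimal"
    }
  }
  benefit <- wtp * results$qaly - results$cost
  # ties broken toward lower cost, then toward the comparator
  best <- order(-benefit, results$cost, results$strategy != comparator)[1]
  out <- data.frame(
    strategy = results$strategy, cost = results$cost, qaly = results$qaly,
    delta_cost = dc, delta_qaly = dq, icer = ic, classification = cls,
    nmb = benefit, optimal = seq_len(nrow(results)) == best,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ich_comparison", "data.frame")
  out
}

#' NMB-optimal strategy of a result set
#'
#' @inheritParams classify_strategies
#' @return the strategy name maximising net monetary benefit at `wtp`, ties
#'   broken toward lower cost.
#' @export
optimal_strategy <- function(results, wtp = 100000) {
  results <- as_result_frame(results)
  benefit <- wtp * results$qaly - results$cost
  results$strategy[order(-benefit, results$cost)[1]]
}

as_result_frame <- function(results) {
  if (is.data.frame(results)) return(results)
  data.frame(
    strategy = vapply(results, `[[`, character(1), "strategy"),
    cost = vapply(results, `[[`, numeric(1), "expected_cost"),
    qaly = vapply(results, `[[`, numeric(1), "expected_qaly"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ich_comparison <- function(x, ...) {
  y <- data.frame(
    strategy = x$strategy,
    cost = round(x$cost),
    qaly = round(x$qaly, 3),
    delta_cost = round(x$delta_cost),
    delta_qaly = round(x$delta_qaly, 4),
    icer = ifelse(is.na(x$icer), "--", format(round(x$icer), big.mark = ",")),
    classification = x$classification,
    optimal = ifelse(x$optimal, "*", "")
  )
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Efficiency frontier (secondary view)
#'
#' Sorts strategies by cost and removes strongly dominated entries (more
#' costly, no more effective) and extendedly dominated ones (higher
#' incremental ratio than the next step). The pairwise-vs-comparator framing
#' of [classify_strategies()] is the primary report; this frontier is
#' offered for completeness.
#'
#' @param results data.frame from [run_strategies()].
#' @return subset of `results` on the frontier, sorted by cost, with an
#'   `icer_step` column of frontier-step ICERs.
#' @export
efficiency_frontier <- function(results) {
  results <- as_result_frame(results)
  ord <- results[order(results$cost, -results$qaly), ]
  keep <- ord[1, , drop = FALSE]
  for (i in seq_len(nrow(ord))[-1]) {
    if (ord$qaly[i] > keep$qaly[nrow(keep)] + 1e-12)
      keep <- rbind(keep, ord[i, ])
  }
  # extended dominance: incremental ratios must increase along the frontier
  repeat {
    if (nrow(keep) < 3) break
    ic <- diff(keep$cost) / diff(keep$qaly)
    bad <- which(diff(ic) < 0)
    if (!length(bad)) break
    keep <- keep[-(bad[1] + 1), ]
  }
  keep$icer_step <- c(NA, diff(keep$cost) / diff(keep$qaly))
  rownames(keep) <- NULL
  keep
}
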