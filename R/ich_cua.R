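#' Cost-utility analysis of the four ICH imaging strategies
#'
#' The main entry point: runs the lifetime Markov cohort model for all four
#' imaging strategies on one parameter deck and compares them against the
#' comparator (stratified DSA by default) at the deck's willingness to pay.
#'
#' @param deck an `ich_deck`; [default_deck()] reproduces the base case
#'   (40-year-old cohort, 45% lesion prevalence).
#' @param comparator reference strategy for incremental comparisons.
#' @param wtp willingness to pay, USD/QALY; defaults to the deck setting.
#' @return object of class `ich_cua` with components `results` (per-strategy
#'   cost and QALYs), `comparison` (the [classify_strategies()] table),
#'   `frontier`, `deck`, `comparator`, `wtp`.
#' @examples
#' fit <- ich_cua(default_deck())
#' fit
#' summary(fit)
#' @export
ich_cua <- function(deck = default_deck(), comparator = "DSA_STRATIFIED",
                    wtp = deck$settings$wtp) {
  validate_deck(deck)
  comparator <- match.arg(comparator, strategies())
  results <- run_strategies(deck)
  comparison <- classify_strategies(results, comparator, wtp)
  out <- list(results = results, comparison = comparison,
              frontier = efficiency_frontier(results),
              deck = deck, comparator = comparator, wtp = wtp)
  class(out) <- "ich_cua"
  out
}

#' @export
print.ich_cua <- function(x, ...) {
  s <- x$deck$settings
  cat(sprintf(
    "ICH imaging cost-utility analysis (age %s, lesion prevalence %.0f%%, WTP $%s/QALY)\n",
    format(s$initial_age), 100 * x$deck$epi$lesion_prevalence,
    format(x$wtp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("Comparator: %s\n\n", x$comparator))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.ich_cua <- function(object, ...) {
  cmp <- object$comparison
  opt <- cmp$strategy[cmp$optimal]
  dom <- cmp$strategy[cmp$classification == "dominant"]
  structure(
    list(comparison = cmp, optimal = opt, dominant = dom,
         frontier = object$frontier, wtp = object$wtp,
         comparator = object$comparator),
    class = "summary.ich_cua")
}

#' @export
print.summary.ich_cua <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("\nNMB-optimal strategy at $%s/QALY: %s\n",
              format(x$wtp, big.mark = ",", scientific = FALSE), x$optimal))
  if (length(x$dominant))
    cat("Dominant vs comparator:", paste(x$dominant, collapse = ", "), "\n")
  cat("\nEfficiency frontier (secondary view):\n")
  print.data.frame(x$frontier, row.names = FALSE)
  invisible(x)
}

#' Extract per-strategy costs and QALYs
#'
#' @param object an `ich_cua`.
#' @param ... unused.
#' @return named vector interleaving each strategy's cost and QALYs.
#' @export
coef.ich_cua <- function(object, ...) {
  r <- object$results
  stats::setNames(
    as.vector(rbind(r$cost, r$qaly)),
    as.vector(rbind(paste0("cost_", r$strategy), paste0("qaly_", r$strategy))))
}

#' Cost-effectiveness plane of a fitted analysis
#'
#' Incremental costs and QALYs of every strategy relative to the comparator,
#' with the willingness-to-pay line.
#'
#' @param x an `ich_cua`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ich_cua <- function(x, ...) {
  cmp <- x$comparison
  dq <- cmp$delta_qaly
  dc <- cmp$delta_cost
  lim_q <- range(c(dq, 0)) * 1.3 + c(-1e-3, 1e-3)
  lim_c <- range(c(dc, 0)) * 1.3 + c(-1, 1)
  graphics::plot(dq, dc, pch = 19, col = "#4477AA", xlim = lim_q,
                 ylim = lim_c, xlab = "Incremental QALYs vs comparator",
                 ylab = "Incremental cost (USD) vs comparator", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = x$wtp, lty = 2, col = "grey40")
  graphics::text(dq, dc, cmp$strategy, pos = 3, cex = 0.75)
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted analysis
#'
#' `simulate` on an `ich_cua` runs the PSA of [run_psa()] on the fitted
#' deck.
#'
#' @param object an `ich_cua`.
#' @param nsim number of joint parameter draws.
#' @param seed integer seed.
#' @param ... passed to [run_psa()].
#' @return an `ich_psa`.
#' @export
simulate.ich_cua <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$deck, n = nsim, seed = seed, ...)
}
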