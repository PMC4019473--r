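#' One-way deterministic sensitivity analysis
#'
#' Sweeps one scalar model input over its plausible range (all other inputs
#' at base case), rerunning the full four-strategy model and the comparator
#' classification at every grid point. The base-case value is always
#' included in the grid.
#'
#' @param deck an `ich_deck`.
#' @param parameter a name from [deck_table()], e.g. `"lesion_prevalence"`.
#' @param n number of grid points (ignored when `values` given).
#' @param values optional explicit grid, each within the parameter's range.
#' @param wtp willingness to pay for classification and NMB.
#' @param comparator reference strategy.
#' @return data.frame of class `ich_oneway`: one row per grid value per
#'   strategy with costs, QALYs, deltas, ICER, classification, NMB and the
#'   optimal flag.
#' @export
one_way <- function(deck, parameter, n = 11, values = NULL,
                    wtp = deck$settings$wtp, comparator = "DSA_STRATIFIED") {
  validate_deck(deck)
  reg <- param_registry()
  if (!parameter %in% reg$name)
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  lo <- reg$low[reg$name == parameter]
  hi <- reg$high[reg$name == parameter]
  base <- get_param(deck, parameter)
  if (is.null(values)) {
    values <- if (n == 1) base else seq(lo, hi, length.out = n)
    if (!any(abs(values - base) < 1e-12)) values <- sort(c(values, base))
  }
  if (any(values < lo - 1e-9 | values > hi + 1e-9))
    stop("grid values outside the range [", lo, ", ", hi, "] of '",
         parameter, "'", call. = FALSE)
  rows <- lapply(values, function(v) {
    d <- set_param(deck, parameter, v)
    cmp <- classify_strategies(run_strategies(d), comparator, wtp)
    cbind(parameter = parameter, value = v, as.data.frame(cmp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ich_oneway", "data.frame")
  out
}

#' Prevalence sweep with all-strategy dominance flags
#'
#' The classification table of [one_way()] over lesion prevalence, augmented
#' per grid point with whether CTA-for-everyone or stratified CTA is
#' simultaneously cheapest and most effective of all four strategies
#' ("dominant vs all"), and which strategy is NMB-optimal.
#'
#' @param deck an `ich_deck`.
#' @param prevalences grid of lesion prevalences.
#' @param wtp willingness to pay.
#' @return data.frame: one row per prevalence with `optimal`,
#'   `cta_all_dominant_all`, `cta_strat_dominant_all`, and per-strategy
#'   classifications vs the stratified-DSA comparator.
#' @export
prevalence_sweep <- function(deck, prevalences = seq(0.01, 0.60, by = 0.01),
                             wtp = deck$settings$wtp) {
  validate_deck(deck)
  values <- compute_values(deck)  # state values do not depend on prevalence
  rows <- lapply(prevalences, function(p) {
    d <- set_param(deck, "lesion_prevalence", p)
    res <- lapply(strategies(), run_cohort, deck = d, values = values)
    rf <- as_result_frame(res)
    cmp <- classify_strategies(rf, "DSA_STRATIFIED", wtp)
    dom_all <- function(s) {
      i <- rf$strategy == s
      all(rf$cost[i] <= rf$cost[!i] + 1e-9) &&
        all(rf$qaly[i] >= rf$qaly[!i] - 1e-12) &&
        any(rf$cost[i] < rf$cost[!i] - 1e-9)
    }
    data.frame(
      prevalence = p,
      optimal = optimal_strategy(rf, wtp),
      cta_all_dominant_all = dom_all("CTA_ALL"),
      cta_strat_dominant_all = dom_all("CTA_STRATIFIED"),
      cls_cta_all = cmp$classification[cmp$strategy == "CTA_ALL"],
      cls_cta_strat = cmp$classification[cmp$strategy == "CTA_STRATIFIED"],
      cls_dsa_all = cmp$classification[cmp$strategy == "DSA_ALL"],
      icer_cta_all = cmp$icer[cmp$strategy == "CTA_ALL"],
      icer_dsa_all = cmp$icer[cmp$strategy == "DSA_ALL"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity analysis over cohort age and lesion prevalence
#'
#' Evaluates the NMB-optimal strategy on an age-by-prevalence grid at a
#' stated willingness to pay, the map underlying strategy choice by patient
#' profile.
#'
#' @param deck an `ich_deck`.
#' @param ages grid of initial ages (years).
#' @param prevalences grid of lesion prevalences.
#' @param wtp willingness to pay, USD/QALY.
#' @return matrix of class `ich_twoway` (rows = prevalences, columns = ages)
#'   of optimal-strategy labels, with the grids as dimnames.
#' @export
two_way_age_prevalence <- function(deck, ages = seq(10, 80, by = 5),
                                   prevalences = seq(0.01, 0.60, by = 0.02),
                                   wtp = deck$settings$wtp) {
  validate_deck(deck)
  if (!length(ages) || !length(prevalences))
    stop("age and prevalence grids must be nonempty", call. = FALSE)
  out <- matrix(NA_character_, nrow = length(prevalences),
                ncol = length(ages),
                dimnames = list(prevalence = format(prevalences),
                                age = format(ages)))
  for (j in seq_along(ages)) {
    d_age <- deck
    d_age$settings$initial_age <- ages[j]
    values <- compute_values(d_age)
    for (i in seq_along(prevalences)) {
      d <- set_param(d_age, "lesion_prevalence", prevalences[i])
      res <- lapply(strategies(), run_cohort, deck = d, values = values)
      out[i, j] <- optimal_strategy(as_result_frame(res), wtp)
    }
  }
  class(out) <- c("ich_twoway", class(out))
  attr(out, "wtp") <- wtp
  out
}

#' @export
plot.ich_twoway <- function(x, ...) {
  labs <- strategies()
  z <- matrix(match(unclass(x), labs), nrow(x), ncol(x))
  ages <- as.numeric(colnames(x))
  prevs <- as.numeric(rownames(x))
  cols <- c("#4477AA", "#EE7733", "#AA3377", "#228833")
  graphics::image(ages, prevs, t(z), col = cols[sort(unique(as.vector(z)))],
                  xlab = "Cohort age (years)", ylab = "Lesion prevalence",
                  main = sprintf("Optimal strategy at $%s/QALY",
                                 format(attr(x, "wtp"), big.mark = ",")), ...)
  graphics::legend("topright", legend = labs[sort(unique(as.vector(z)))],
                   fill = cols[sort(unique(as.vector(z)))], bg = "white",
                   cex = 0.8)
  invisible(x)
}

#' Threshold search on a model input
#'
#' Bisects a scalar input over (a subset of) its range for the value at
#' which a model predicate flips, e.g. "the ICER of DSA-for-everyone crosses
#' the willingness-to-pay". If the predicate does not change value across
#' the range a no-threshold result is returned, not an error.
#'
#' @param deck an `ich_deck`.
#' @param parameter a name from [deck_table()].
#' @param predicate function of a deck returning a single logical; see
#'   [icer_exceeds()].
#' @param lo,hi search interval; defaults to the parameter's range.
#' @param tol absolute tolerance as a fraction of the interval width.
#' @return list with `threshold` (NA when the predicate is constant),
#'   `lower`, `upper` (final bracket), `predicate_low`, `predicate_high`.
#' @export
threshold_search <- function(deck, parameter, predicate, lo = NULL, hi = NULL,
                             tol = 1e-4) {
  validate_deck(deck)
  reg <- param_registry()
  if (!parameter %in% reg$name)
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  if (is.null(lo)) lo <- reg$low[reg$name == parameter]
  if (is.null(hi)) hi <- reg$high[reg$name == parameter]
  f <- function(v) isTRUE(predicate(set_param(deck, parameter, v)))
  p_lo <- f(lo)
  p_hi <- f(hi)
  if (p_lo == p_hi)
    return(list(threshold = NA_real_, lower = lo, upper = hi,
                predicate_low = p_lo, predicate_high = p_hi))
  width <- hi - lo
  a <- lo; b <- hi
  while (b - a > tol * width) {
    m <- (a + b) / 2
    if (f(m) == p_lo) a <- m else b <- m
  }
  list(threshold = (a + b) / 2, lower = a, upper = b,
       predicate_low = p_lo, predicate_high = p_hi)
}

#' Predicate: a strategy's ICER against the comparator exceeds a threshold
#'
#' Returns a function of a deck, suitable for [threshold_search()]. A
#' strategy that is dominated (no QALY gain at extra cost) counts as
#' exceeding any threshold; a dominant strategy exceeds none.
#'
#' @param strategy strategy whose ICER is tested.
#' @param threshold USD/QALY threshold (typically the willingness to pay).
#' @param comparator reference strategy.
#' @return function: deck -> logical.
#' @export
icer_exceeds <- function(strategy, threshold, comparator = "DSA_STRATIFIED") {
  force(strategy); force(threshold); force(comparator)
  function(deck) {
    res <- run_strategies(deck)
    a <- list(expected_cost = res$cost[res$strategy == strategy],
              expected_qaly = res$qaly[res$strategy == strategy])
    b <- list(expected_cost = res$cost[res$strategy == comparator],
              expected_qaly = res$qaly[res$strategy == comparator])
    v <- icer(a, b)
    if (v$delta_qaly > 1e-12) v$icer > threshold
    else v$delta_cost > 0  # no QALY gain: cost-ineffective iff it costs more
  }
}

## ---- probabilistic sensitivity analysis ------------------------------------

#' Probabilistic sensitivity analysis with acceptability curve
#'
#' Draws every uncertain input jointly and independently from its fitted
#' distribution ([fit_distribution()]; families and ranges from
#' `deck$psa`), evaluates all four strategies per draw, and tallies how
#' often each strategy maximises net monetary benefit over a grid of
#' willingness-to-pay values — the cost-effectiveness acceptability curve
#' (CEAC). The lesion prevalence and the discount rate carry no PSA
#' distribution and are held at their deck values; the sampled initial age
#' re-indexes the background mortality curve (and is truncated to the
#' supported 10-80 range). Normal cost draws are truncated at zero;
#' relative-risk draws are redrawn in the (vanishingly rare) case that the
#' implied treated re-bleed rate would exceed one.
#'
#' @param deck an `ich_deck`.
#' @param n number of joint draws.
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @param wtp_grid willingness-to-pay grid for the CEAC, USD/QALY.
#' @param couple_prevalence_to_age if TRUE the sampled age also sets the
#'   lesion prevalence through the deck's look-up table; off by default so
#'   parameter uncertainty is isolated.
#' @return list of class `ich_psa`: `samples` (one row per draw: sampled
#'   values, per-strategy cost and QALY, optimal strategy at the deck WTP),
#'   `ceac` (long data.frame: wtp, strategy, probability optimal), `n`,
#'   `seed`, `wtp_grid`.
#' @export
run_psa <- function(deck, n = 1000, seed = 1,
                    wtp_grid = seq(0, 200000, by = 10000),
                    couple_prevalence_to_age = FALSE) {
  validate_deck(deck)
  stopifnot(n >= 1)
  set.seed(seed)
  specs <- deck$psa
  draws <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    trunc <- NULL
    if (sp$family == "normal")
      trunc <- if (nm == "initial_age") c(sp$low, sp$high) else c(0, Inf)
    draws[[nm]] <- fit_distribution(sp, truncate = trunc)$sample(n)
  }
  if (!is.null(draws$initial_age))
    draws$initial_age <- round(draws$initial_age)
  # keep treated re-bleed probability a probability
  if (!is.null(draws$rr_after_repair)) {
    rb <- if (is.null(draws$rebleed_secondary_untreated))
      rep(deck$epi$rebleed_secondary_untreated, n)
    else draws$rebleed_secondary_untreated
    d <- fit_distribution(specs$rr_after_repair)
    bad <- which(draws$rr_after_repair * rb > 1)
    while (length(bad)) {
      draws$rr_after_repair[bad] <- d$sample(length(bad))
      bad <- bad[draws$rr_after_repair[bad] * rb[bad] > 1]
    }
  }

  scalar_names <- intersect(names(specs), param_registry()$name)
  strat <- strategies()
  cost_m <- qaly_m <- matrix(NA_real_, n, length(strat),
                             dimnames = list(NULL, strat))
  for (i in seq_len(n)) {
    d <- deck
    for (nm in scalar_names)
      d <- set_param(d, nm, draws[[nm]][i])
    for (m in c("primary", "secondary")) {
      key <- paste0("mrs_", m)
      if (!is.null(draws[[key]])) {
        v <- draws[[key]][i, ]
        names(v) <- c("mrs01", "mrs23", "mrs45", "mrs6")
        d$mrs[[m]] <- v
      }
    }
    if (couple_prevalence_to_age)
      d$epi$lesion_prevalence <-
        prevalence_at_age(d$prevalence_lookup, d$settings$initial_age)
    values <- compute_values(d)
    for (s in strat) {
      r <- run_cohort(s, d, values = values)
      cost_m[i, s] <- r$expected_cost
      qaly_m[i, s] <- r$expected_qaly
    }
  }

  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    ben <- w * qaly_m - cost_m
    win <- strat[max.col(ben, ties.method = "first")]
    data.frame(wtp = w, strategy = strat,
               probability = as.numeric(table(factor(win, levels = strat))) / n,
               stringsAsFactors = FALSE)
  }))
  ben0 <- deck$settings$wtp * qaly_m - cost_m
  samples <- data.frame(draw = seq_len(n))
  for (nm in scalar_names) samples[[nm]] <- draws[[nm]]
  for (s in strat) {
    samples[[paste0("cost_", s)]] <- cost_m[, s]
    samples[[paste0("qaly_", s)]] <- qaly_m[, s]
  }
  samples$optimal <- strat[max.col(ben0, ties.method = "first")]
  out <- list(samples = samples, ceac = ceac, n = n, seed = seed,
              wtp_grid = wtp_grid)
  class(out) <- "ich_psa"
  out
}

#' Probability a strategy is optimal across a willingness-to-pay band
#'
#' @param psa an `ich_psa` from [run_psa()].
#' @param strategy strategy name.
#' @param wtp_range length-2 numeric; CEAC rows with `wtp` inside the range
#'   (inclusive) are used.
#' @return named list: `mean`, `min`, `max` of the per-wtp probabilities.
#' @export
ceac_band <- function(psa, strategy = "CTA_STRATIFIED",
                      wtp_range = c(50000, 150000)) {
  cc <- psa$ceac
  sel <- cc$strategy == strategy &
    cc$wtp >= wtp_range[1] & cc$wtp <= wtp_range[2]
  p <- cc$probability[sel]
  list(mean = mean(p), min = min(p), max = max(p))
}

#' @export
print.ich_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %s)\n",
              x$n, format(x$seed)))
  b <- ceac_band(x)
  cat(sprintf("  CTA_STRATIFIED optimal in %.1f%% of draws (mean over $50k-$150k/QALY)\n",
              100 * b$mean))
  invisible(x)
}

#' @export
plot.ich_psa <- function(x, ...) {
  strat <- strategies()
  cols <- c("#4477AA", "#EE7733", "#AA3377", "#228833")
  graphics::plot(NULL, xlim = range(x$wtp_grid), ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "Probability strategy is optimal",
                 main = "Cost-effectiveness acceptability curves", ...)
  for (i in seq_along(strat)) {
    cc <- x$ceac[x$ceac$strategy == strat[i], ]
    graphics::lines(cc$wtp, cc$probability, col = cols[i], lwd = 2)
  }
  graphics::legend("right", legend = strat, col = cols, lwd = 2, cex = 0.8)
  invisible(x)
}
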