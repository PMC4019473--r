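## Markov cohort engine.
##
## State space: living states are (mRS band in {0-1, 2-3, 4-5}) x (lesion
## status in {none, untreated, treated}) x (years-since-last-bleed tunnel in
## {0, 1, 2+}), plus one absorbing dead state: 28 states. The tunnel exists
## because mRS 4-5 long-term care costs more in the year of a bleed than in
## later years.
##
## Cycle order (1-year cycles): background death by current age, then
## re-bleed events, then cost/utility accrual by end-of-cycle occupancy.
## A re-bleed sends the subject to DSA (cost) plus a hospitalization
## (secondary if a lesion is present - which is then treated - primary
## otherwise), redraws the mRS band from the etiology-appropriate
## distribution under a worse-of rule, and resets the tunnel. Re-bleeding
## subjects accrue no long-term-care cost or utility in the event cycle;
## non-re-bleed survivors accrue both. Cycle-k accruals are discounted by
## (1+r)^-k; time-0 imaging and index hospitalization costs are undiscounted.

N_BAND <- 3L
N_LESION <- 3L
N_TUNNEL <- 3L
N_STATE <- N_BAND * N_LESION * N_TUNNEL + 1L  # 28
DEAD <- N_STATE

# state index; band 1..3, lesion 1..3 (none, untreated, treated), tunnel 0..2
sidx <- function(band, lesion, tunnel) {
  ((band - 1L) * N_LESION + (lesion - 1L)) * N_TUNNEL + tunnel + 1L
}

#' Living-state index table
#'
#' @return data.frame mapping each state index to its mRS band, lesion
#'   status and tunnel year; the final index is the absorbing dead state.
#' @keywords internal
state_table <- function() {
  g <- expand.grid(tunnel = 0:2,
                   lesion = c("none", "untreated", "treated"),
                   band = c("mrs01", "mrs23", "mrs45"),
                   stringsAsFactors = FALSE)[, 3:1]
  g <- g[order(match(g$band, c("mrs01", "mrs23", "mrs45")),
               match(g$lesion, c("none", "untreated", "treated")),
               g$tunnel), ]
  rbind(data.frame(band = g$band, lesion = g$lesion, tunnel = g$tunnel),
        data.frame(band = "dead", lesion = "none", tunnel = 0))
}

#' Per-cycle re-bleed probability of a health state
#'
#' Primary etiology (no lesion) re-bleeds at the primary rate; an untreated
#' lesion at the secondary rate; a treated lesion at the secondary rate times
#' the relative risk after repair.
#'
#' @param lesion_status `"none"`, `"untreated"` or `"treated"` (or `"dead"`,
#'   which errors).
#' @param deck an `ich_deck`.
#' @return per-cycle probability.
#' @examples
#' rebleed_probability("treated", default_deck())
#' @export
rebleed_probability <- function(lesion_status, deck) {
  switch(lesion_status,
    none = deck$epi$rebleed_primary,
    untreated = deck$epi$rebleed_secondary_untreated,
    treated = deck$epi$rebleed_secondary_untreated * deck$epi$rr_after_repair,
    stop("re-bleed probability is undefined for state '", lesion_status, "'",
         call. = FALSE)
  )
}

# Age-independent cycle kernel: re-bleed/tunnel transition matrix M over the
# 28 states plus expected event+care cost and utility accrued per cycle from
# each starting state (before background mortality and discounting).
build_kernel <- function(deck) {
  M <- matrix(0, N_STATE, N_STATE)
  cost0 <- numeric(N_STATE)
  util0 <- numeric(N_STATE)
  cs <- deck$costs
  u <- c(deck$utilities[["mrs01"]], deck$utilities[["mrs23"]],
         deck$utilities[["mrs45"]])
  lesions <- c("none", "untreated", "treated")
  for (b in 1:N_BAND) for (li in 1:N_LESION) for (tn in 0:2) {
    i <- sidx(b, li, tn)
    p_rb <- rebleed_probability(lesions[li], deck)
    # no re-bleed: band and lesion unchanged, tunnel advances (capped)
    j <- sidx(b, li, min(tn + 1L, 2L))
    M[i, j] <- M[i, j] + (1 - p_rb)
    # re-bleed: etiology decides hospitalization and mRS redraw; any lesion
    # present is found on DSA and treated
    if (li == 1L) {
      draw <- deck$mrs$primary; hosp <- cs$hosp_primary; li2 <- 1L
    } else {
      draw <- deck$mrs$secondary; hosp <- cs$hosp_secondary; li2 <- 3L
    }
    # with "state" accrual the event cycle itself is lived at tunnel 0, so
    # survivors enter the next cycle one tunnel year on; with "none" the
    # first post-bleed care year is the next cycle
    tn2 <- if (identical(deck$settings$event_cycle_accrual, "state")) 1L else 0L
    for (d in 1:N_BAND) {
      nb <- max(b, d)  # worse-of: disability does not vanish
      j2 <- sidx(nb, li2, tn2)
      M[i, j2] <- M[i, j2] + p_rb * draw[[d]]
    }
    M[i, DEAD] <- M[i, DEAD] + p_rb * draw[["mrs6"]]
    ltc_of <- function(band, tunnel) {
      if (band == 1L) 0
      else if (band == 2L) cs$ltc_mrs23
      else if (tunnel == 0L) cs$ltc_mrs45_year1
      else cs$ltc_mrs45_later
    }
    cost0[i] <- p_rb * (cs$dsa + hosp) + (1 - p_rb) * ltc_of(b, tn)
    util0[i] <- (1 - p_rb) * u[b]
    if (identical(deck$settings$event_cycle_accrual, "state")) {
      # re-bleed survivors accrue the event cycle by their post-event state
      # (tunnel 0, worse-of band) - mirrors how model entry is accrued
      for (d in 1:N_BAND) {
        nb <- max(b, d)
        cost0[i] <- cost0[i] + p_rb * draw[[d]] * ltc_of(nb, 0L)
        util0[i] <- util0[i] + p_rb * draw[[d]] * u[nb]
      }
    }
  }
  M[DEAD, DEAD] <- 1
  list(M = M, cost0 = cost0, util0 = util0)
}

# Expected discounted lifetime cost and QALY from each state at cycle 0,
# by backward induction over K = max_age - initial_age cycles.
compute_values <- function(deck, kernel = build_kernel(deck)) {
  s <- deck$settings
  K <- as.integer(ceiling(s$max_age - s$initial_age))
  r <- s$discount_rate
  q <- if (isTRUE(s$background_mortality))
    mortality_at_age(deck$life_table, s$initial_age + 0:(K - 1))
  else
    rep(0, K)
  w <- rep(1, K)
  if (isTRUE(s$half_cycle_correction)) {
    w[1] <- 0.5
    w[K] <- 0.5
  }
  Vc <- Vq <- numeric(N_STATE)
  for (k in (K - 1):0) {
    disc <- (1 + r)^(-k)
    surv <- 1 - q[k + 1]
    Vc <- surv * (w[k + 1] * disc * kernel$cost0 + as.vector(kernel$M %*% Vc))
    Vq <- surv * (w[k + 1] * disc * kernel$util0 + as.vector(kernel$M %*% Vq))
  }
  list(Vc = Vc, Vq = Vq, K = K, q = q, kernel = kernel)
}

#' Initial state distribution of a diagnostic pathway
#'
#' Distributes the pathway's survivors over the three living mRS bands per
#' its outcome source, with the mRS 6 mass entering the dead state; lesion
#' status is set by the pathway and the tunnel counter starts at zero.
#'
#' @param pathway one row of [enumerate_pathways()].
#' @param deck an `ich_deck`.
#' @return occupancy vector over the 28 health states, summing to 1.
#' @export
initial_state_distribution <- function(pathway, deck) {
  d0 <- deck$mrs[[pathway$mrs_source]]
  li <- match(pathway$lesion_after, c("none", "untreated", "treated"))
  init <- numeric(N_STATE)
  for (b in 1:N_BAND)
    init[sidx(b, li, 0L)] <- d0[[b]]
  init[DEAD] <- d0[["mrs6"]]
  init
}

#' Lifetime discounted cost and QALYs of one imaging strategy
#'
#' Sums the pathway-weighted upfront imaging and index hospitalization costs
#' with the expected discounted lifetime costs and QALYs of the Markov cohort
#' started from each pathway's initial state. Deterministic for a fixed deck.
#'
#' @param strategy one of [strategies()].
#' @param deck an `ich_deck`.
#' @param values optional precomputed state values (internal reuse).
#' @return list of class `ich_strategy_result` with `strategy`,
#'   `expected_cost` (USD), `expected_qaly`, `upfront_cost`.
#' @examples
#' run_cohort("CTA_STRATIFIED", default_deck())
#' @export
run_cohort <- function(strategy, deck, values = NULL) {
  strategy <- match.arg(strategy, strategies())
  validate_deck(deck)
  if (is.null(values)) values <- compute_values(deck)
  pw <- enumerate_pathways(strategy, deck)
  upfront <- sum(pw$probability * (pw$imaging_cost + pw$hosp_cost))
  cost <- upfront
  qaly <- 0
  for (i in seq_len(nrow(pw))) {
    init <- initial_state_distribution(pw[i, ], deck)
    cost <- cost + pw$probability[i] * sum(init * values$Vc)
    qaly <- qaly + pw$probability[i] * sum(init * values$Vq)
  }
  out <- list(strategy = strategy, expected_cost = cost,
              expected_qaly = qaly, upfront_cost = upfront)
  class(out) <- "ich_strategy_result"
  out
}

#' @export
print.ich_strategy_result <- function(x, ...) {
  cat(sprintf("%s: expected cost $%s, expected QALYs %.3f (discounted)\n",
              x$strategy, format(round(x$expected_cost), big.mark = ","),
              x$expected_qaly))
  invisible(x)
}

#' Run all four strategies on one deck
#'
#' @param deck an `ich_deck`.
#' @return data.frame with one row per strategy: `strategy`, `cost`, `qaly`.
#' @export
run_strategies <- function(deck) {
  validate_deck(deck)
  values <- compute_values(deck)
  res <- lapply(strategies(), run_cohort, deck = deck, values = values)
  data.frame(
    strategy = vapply(res, `[[`, character(1), "strategy"),
    cost = vapply(res, `[[`, numeric(1), "expected_cost"),
    qaly = vapply(res, `[[`, numeric(1), "expected_qaly"),
    stringsAsFactors = FALSE
  )
}

#' Forward cohort trace of one strategy
#'
#' Simulates the cohort forward cycle by cycle, recording state occupancy and
#' per-cycle (discounted and undiscounted) cost and QALY accrual. The
#' cumulative discounted totals equal [run_cohort()]'s expectations up to the
#' upfront costs, which are booked at cycle 0 in the `upfront_cost` column.
#'
#' @inheritParams run_cohort
#' @return data.frame of class `ich_trace`: one row per cycle with `cycle`,
#'   `age`, occupancy of each state (`occ_*` columns, summing to 1), cycle
#'   and cumulative cost/QALY columns.
#' @export
cohort_trace <- function(strategy, deck) {
  strategy <- match.arg(strategy, strategies())
  validate_deck(deck)
  s <- deck$settings
  kern <- build_kernel(deck)
  K <- as.integer(ceiling(s$max_age - s$initial_age))
  q <- if (isTRUE(s$background_mortality))
    mortality_at_age(deck$life_table, s$initial_age + 0:(K - 1))
  else rep(0, K)
  w <- rep(1, K)
  if (isTRUE(s$half_cycle_correction)) { w[1] <- 0.5; w[K] <- 0.5 }
  r <- s$discount_rate

  pw <- enumerate_pathways(strategy, deck)
  occ <- numeric(N_STATE)
  for (i in seq_len(nrow(pw)))
    occ <- occ + pw$probability[i] * initial_state_distribution(pw[i, ], deck)
  upfront <- sum(pw$probability * (pw$imaging_cost + pw$hosp_cost))

  st <- state_table()
  occ_names <- paste0("occ_", st$band, "_", st$lesion, "_t", st$tunnel)
  occ_names[DEAD] <- "occ_dead"
  rows <- vector("list", K)
  cum_c <- cum_cd <- cum_q <- cum_qd <- 0
  for (k in 0:(K - 1)) {
    surv <- 1 - q[k + 1]
    # death, then re-bleed/accrual among survivors
    occ_alive <- occ
    occ_alive[DEAD] <- 0
    dead_mass <- occ[DEAD] + sum(occ_alive) * q[k + 1]
    occ_s <- surv * occ_alive
    cyc_c <- w[k + 1] * sum(occ_s * kern$cost0)
    cyc_q <- w[k + 1] * sum(occ_s * kern$util0)
    disc <- (1 + r)^(-k)
    cum_c <- cum_c + cyc_c;        cum_q <- cum_q + cyc_q
    cum_cd <- cum_cd + disc * cyc_c; cum_qd <- cum_qd + disc * cyc_q
    occ <- as.vector(t(kern$M) %*% occ_s)
    occ[DEAD] <- occ[DEAD] + dead_mass
    row <- c(cycle = k, age = s$initial_age + k,
             upfront_cost = if (k == 0) upfront else 0,
             stats::setNames(occ, occ_names),
             cycle_cost = cyc_c, cycle_qaly = cyc_q,
             cycle_cost_disc = disc * cyc_c, cycle_qaly_disc = disc * cyc_q,
             cum_cost = cum_c, cum_qaly = cum_q,
             cum_cost_disc = cum_cd, cum_qaly_disc = cum_qd)
    rows[[k + 1]] <- row
  }
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("ich_trace", "data.frame")
  out
}

#' Write a cohort trace to CSV
#'
#' @param trace an `ich_trace` from [cohort_trace()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
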