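# Independent individual-level microsimulation oracle.
#
# Implements the model *rules* directly — per-person annual simulation with
# explicit draws — sharing no kernel code with the cohort engine, so that
# agreement between the two is a real cross-check. Returns per-person
# discounted lifetime cost and QALYs.
microsim_strategy <- function(strategy, deck, n = 5000, seed = 1) {
  set.seed(seed)
  pw <- enumerate_pathways(strategy, deck)
  s <- deck$settings
  cs <- deck$costs
  u <- c(deck$utilities[["mrs01"]], deck$utilities[["mrs23"]],
         deck$utilities[["mrs45"]])
  state_acc <- identical(s$event_cycle_accrual, "state")

  path_i <- sample.int(nrow(pw), n, replace = TRUE, prob = pw$probability)
  cost <- pw$imaging_cost[path_i] + pw$hosp_cost[path_i]
  qaly <- numeric(n)
  band <- integer(n)
  for (i in seq_len(nrow(pw))) {
    sel <- which(path_i == i)
    if (length(sel))
      band[sel] <- sample.int(4, length(sel), replace = TRUE,
                              prob = deck$mrs[[pw$mrs_source[i]]])
  }
  lesion <- pw$lesion_after[path_i]
  alive <- band < 4L
  tunnel <- integer(n)

  K <- as.integer(ceiling(s$max_age - s$initial_age))
  for (k in 0:(K - 1)) {
    if (!any(alive)) break
    disc <- (1 + s$discount_rate)^(-k)
    q <- if (isTRUE(s$background_mortality))
      mortality_at_age(deck$life_table, s$initial_age + k) else 0
    idx <- which(alive)
    die <- idx[stats::runif(length(idx)) < q]
    alive[die] <- FALSE
    idx <- which(alive)
    if (!length(idx)) break
    prb <- vapply(lesion[idx], rebleed_probability, numeric(1), deck = deck)
    is_rb <- stats::runif(length(idx)) < prb
    rb <- idx[is_rb]
    norb <- idx[!is_rb]
    if (length(rb)) {
      haslesion <- lesion[rb] != "none"
      hosp <- ifelse(haslesion, cs$hosp_secondary, cs$hosp_primary)
      cost[rb] <- cost[rb] + disc * (cs$dsa + hosp)
      newb <- integer(length(rb))
      for (m in c("primary", "secondary")) {
        sel <- which(ifelse(haslesion, "secondary", "primary") == m)
        if (length(sel))
          newb[sel] <- sample.int(4, length(sel), replace = TRUE,
                                  prob = deck$mrs[[m]])
      }
      dead_now <- newb == 4L
      band[rb] <- pmax(band[rb], pmin(newb, 3L))
      alive[rb[dead_now]] <- FALSE
      lesion[rb[haslesion]] <- "treated"
      surv <- rb[!dead_now]
      if (length(surv)) {
        if (state_acc) {
          bb <- band[surv]
          ltc <- ifelse(bb == 2L, cs$ltc_mrs23,
                        ifelse(bb == 3L, cs$ltc_mrs45_year1, 0))
          cost[surv] <- cost[surv] + disc * ltc
          qaly[surv] <- qaly[surv] + disc * u[bb]
          tunnel[surv] <- 1L
        } else {
          tunnel[surv] <- 0L
        }
      }
    }
    if (length(norb)) {
      bb <- band[norb]
      ltc <- ifelse(bb == 2L, cs$ltc_mrs23,
                    ifelse(bb == 3L,
                           ifelse(tunnel[norb] == 0L, cs$ltc_mrs45_year1,
                                  cs$ltc_mrs45_later), 0))
      cost[norb] <- cost[norb] + disc * ltc
      qaly[norb] <- qaly[norb] + disc * u[bb]
      tunnel[norb] <- pmin(tunnel[norb] + 1L, 2L)
    }
  }
  list(cost = cost, qaly = qaly)
}

expect_microsim_agrees <- function(strategy, deck, n = 6000, seed = 1) {
  ms <- microsim_strategy(strategy, deck, n = n, seed = seed)
  ref <- run_cohort(strategy, deck)
  se_c <- stats::sd(ms$cost) / sqrt(n)
  se_q <- stats::sd(ms$qaly) / sqrt(n)
  expect_lt(abs(mean(ms$cost) - ref$expected_cost), 3 * se_c)
  expect_lt(abs(mean(ms$qaly) - ref$expected_qaly), 3 * se_q)
}
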