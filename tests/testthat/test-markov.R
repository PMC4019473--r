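# deck with all chance of dying or re-bleeding switched off
immortal_deck <- function() {
  deck <- default_deck()
  deck$settings$background_mortality <- FALSE
  deck$epi$rebleed_primary <- 0
  deck$epi$rebleed_secondary_untreated <- 0
  deck
}

test_that("re-bleed probability follows lesion status and the repair RR", {
  deck <- default_deck()
  expect_equal(rebleed_probability("none", deck), 0.0208)
  expect_equal(rebleed_probability("untreated", deck), 0.0392)
  expect_equal(rebleed_probability("treated", deck), 0.0392 * 0.35)
  d1 <- set_param(deck, "rr_after_repair", 1)
  expect_equal(rebleed_probability("treated", d1),
               rebleed_probability("untreated", d1))
  expect_error(rebleed_probability("dead", deck), "undefined")
})

test_that("initial state distributions place survivors and deaths correctly", {
  deck <- default_deck()
  pw <- enumerate_pathways("DSA_ALL", deck)
  tp <- initial_state_distribution(pw[pw$label == "TP", ], deck)
  expect_equal(sum(tp), 1)
  expect_equal(tp[length(tp)], 0.047)  # mRS 6 mass enters dead
  tn <- initial_state_distribution(pw[pw$label == "TN", ], deck)
  st <- state_table <- ichscreen:::state_table()
  expect_equal(sum(tn[st$band == "mrs01"]), 0.08)
  expect_equal(unique(st$tunnel[which(tn > 0 & st$band != "dead")]), 0)
  degen <- deck
  degen$mrs$primary <- c(mrs01 = 1, mrs23 = 0, mrs45 = 0, mrs6 = 0)
  d0 <- initial_state_distribution(
    enumerate_pathways("CTA_ALL", degen)[3, ], degen)  # TN row, primary mRS
  expect_equal(sum(d0[st$band == "mrs01"]), 1)
})

test_that("occupancy is conserved every cycle and dead is absorbing", {
  deck <- default_deck()
  for (s in strategies()) {
    tr <- cohort_trace(s, deck)
    occ <- as.matrix(tr[, grep("^occ_", names(tr))])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr$occ_dead) >= -1e-12))
  }
  # an all-dead cohort accrues nothing
  dead <- deck
  dead$mrs$primary <- dead$mrs$secondary <- c(mrs01 = 0, mrs23 = 0,
                                              mrs45 = 0, mrs6 = 1)
  tr <- cohort_trace("CTA_ALL", dead)
  expect_equal(max(abs(tr$cycle_cost)), 0)
  expect_equal(max(abs(tr$cycle_qaly)), 0)
  expect_equal(run_cohort("CTA_ALL", dead)$expected_qaly, 0)
})

test_that("a disability-band year accrues its care cost and utility", {
  deck <- default_deck(lesion_prevalence = 0)
  deck$tests$cta$spec <- 1           # whole cohort is a primary-ICH TN
  deck$settings$background_mortality <- FALSE
  deck$epi$rebleed_primary <- 0
  deck$mrs$primary <- c(mrs01 = 0, mrs23 = 1, mrs45 = 0, mrs6 = 0)
  tr <- cohort_trace("CTA_ALL", deck)
  expect_equal(tr$cycle_cost[1], 8438)
  expect_equal(tr$cycle_qaly[1], 0.75)
  # mRS 4-5 long-term care: first post-bleed year dearer than later years
  deck$mrs$primary <- c(mrs01 = 0, mrs23 = 0, mrs45 = 1, mrs6 = 0)
  tr <- cohort_trace("CTA_ALL", deck)
  expect_equal(tr$cycle_cost[1:3], c(71428, 37140, 37140))
})

test_that("discounting identities hold", {
  deck <- default_deck(discount_rate = 0)
  tr <- cohort_trace("CTA_STRATIFIED", deck)
  expect_equal(tr$cum_cost_disc, tr$cum_cost)
  expect_equal(tr$cum_qaly_disc, tr$cum_qaly)
  # positive discounting can only shrink cumulative totals
  tr3 <- cohort_trace("CTA_STRATIFIED", default_deck())
  expect_true(all(tr3$cum_cost_disc <= tr3$cum_cost + 1e-9))
})

test_that("backward-induction totals equal the forward trace", {
  for (deck in list(default_deck(), random_deck(7))) {
    for (s in c("CTA_ALL", "DSA_STRATIFIED")) {
      r <- run_cohort(s, deck)
      tr <- cohort_trace(s, deck)
      n <- nrow(tr)
      expect_equal(r$expected_cost, tr$upfront_cost[1] + tr$cum_cost_disc[n],
                   tolerance = 1e-9)
      expect_equal(r$expected_qaly, tr$cum_qaly_disc[n], tolerance = 1e-9)
    }
  }
})

test_that("structural bounds on cost and QALYs hold for random decks", {
  for (seed in c(2, 13, 77)) {
    deck <- random_deck(seed)
    horizon <- deck$settings$max_age - deck$settings$initial_age
    for (s in strategies()) {
      r <- run_cohort(s, deck)
      expect_lte(r$expected_qaly, horizon)
      expect_gte(r$expected_cost, expected_upfront_cost(s, deck))
    }
  }
})

test_that("an immortal undiscounted cohort accrues exactly horizon x mean utility", {
  deck <- immortal_deck()
  deck$settings$discount_rate <- 0
  K <- deck$settings$max_age - deck$settings$initial_age
  u <- deck$utilities
  for (s in c("CTA_ALL", "DSA_STRATIFIED")) {
    pw <- enumerate_pathways(s, deck)
    u0 <- sum(vapply(seq_len(nrow(pw)), function(i) {
      m <- deck$mrs[[pw$mrs_source[i]]]
      pw$probability[i] * (m[["mrs01"]] * u[["mrs01"]] +
        m[["mrs23"]] * u[["mrs23"]] + m[["mrs45"]] * u[["mrs45"]])
    }, numeric(1)))
    expect_equal(run_cohort(s, deck)$expected_qaly, K * u0, tolerance = 1e-9)
  }
})

test_that("with no lesions and a perfect CTA the strategies differ only in imaging cost", {
  deck <- default_deck(lesion_prevalence = 0)
  deck$tests$cta$spec <- 1
  ra <- run_cohort("CTA_ALL", deck)
  rs <- run_cohort("CTA_STRATIFIED", deck)
  imaged_frac <- 1 - deck$tests$ncct$spec
  expect_equal(ra$expected_cost - rs$expected_cost,
               deck$costs$cta * (1 - imaged_frac), tolerance = 1e-9)
  expect_equal(ra$expected_qaly, rs$expected_qaly, tolerance = 1e-12)
})

test_that("costs, utilities and the repair RR move results monotonically", {
  deck <- default_deck()
  base <- run_strategies(deck)
  up_u <- run_strategies(set_param(deck, "u_mrs45", 0.6))
  expect_true(all(up_u$qaly >= base$qaly - 1e-12))
  up_c <- run_strategies(set_param(deck, "hosp_secondary", 120000))
  expect_true(all(up_c$cost >= base$cost - 1e-9))
  worse_rr <- run_strategies(set_param(deck, "rr_after_repair", 0.9))
  for (s in c("CTA_ALL", "CTA_STRATIFIED", "DSA_ALL", "DSA_STRATIFIED"))
    expect_lte(worse_rr$qaly[worse_rr$strategy == s],
               base$qaly[base$strategy == s] + 1e-12)
})

test_that("the cohort engine agrees with an independent microsimulation", {
  picks <- c("CTA_ALL", "CTA_STRATIFIED", "DSA_ALL", "DSA_STRATIFIED",
             "CTA_STRATIFIED")
  for (i in 1:5) {
    deck <- random_deck(100 + i)
    expect_microsim_agrees(picks[i], deck, n = 6000, seed = 500 + i)
  }
})

test_that("half-cycle correction halves the first and last cycle weights", {
  deck <- immortal_deck()
  deck$settings$discount_rate <- 0
  half <- deck
  half$settings$half_cycle_correction <- TRUE
  r_full <- run_cohort("DSA_ALL", deck)
  r_half <- run_cohort("DSA_ALL", half)
  # one full cycle of utility is removed (half at entry, half at horizon)
  K <- deck$settings$max_age - deck$settings$initial_age
  expect_equal(r_half$expected_qaly / r_full$expected_qaly, (K - 1) / K,
               tolerance = 1e-9)
})
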