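res <- function(cost, qaly) list(expected_cost = cost, expected_qaly = qaly)

test_that("ICER arithmetic and the undefined case", {
  v <- icer(res(1000, 0.01), res(0, 0))
  expect_equal(v$icer, 100000)
  expect_true(v$defined)
  same <- icer(res(5, 1), res(5, 1))
  expect_false(same$defined)
  expect_true(is.na(same$icer))
})

test_that("net monetary benefit identities", {
  expect_equal(nmb(res(0, 1), 100000), 100000)
  expect_equal(nmb(res(50000, 0.5), 100000), 0)
  expect_equal(nmb(res(1234, 0.7), 0), -1234)
  expect_error(nmb(res(0, 1), -1))
})

test_that("classification implements the quadrant rules", {
  results <- data.frame(
    strategy = strategies(),
    cost = c(900, 1100, 2000, 1000),
    qaly = c(10.5, 10.4, 10.6, 10.0))
  cmp <- classify_strategies(results, "DSA_STRATIFIED", wtp = 100000)
  expect_equal(cmp$classification[cmp$strategy == "CTA_ALL"], "dominant")
  expect_equal(cmp$classification[cmp$strategy == "DSA_STRATIFIED"], "comparator")
  expect_equal(cmp$delta_cost[cmp$strategy == "DSA_STRATIFIED"], 0)
  expect_equal(cmp$delta_qaly[cmp$strategy == "DSA_STRATIFIED"], 0)
  # NE quadrant below the line
  expect_equal(cmp$classification[cmp$strategy == "DSA_ALL"], "cost_effective")
  expect_error(classify_strategies(results, "NOT_A_STRATEGY"), "comparator")
})

test_that("identical results elect the comparator by tie-break", {
  results <- data.frame(strategy = strategies(), cost = 100, qaly = 1)
  cmp <- classify_strategies(results, "DSA_STRATIFIED", 100000)
  expect_equal(cmp$strategy[cmp$optimal], "DSA_STRATIFIED")
})

test_that("dominance labels agree with a brute-force quadrant check (property)", {
  set.seed(11)
  for (rep in 1:1000) {
    results <- data.frame(
      strategy = strategies(),
      cost = stats::runif(4, 0, 2e5),
      qaly = stats::runif(4, 0, 20))
    cmp <- classify_strategies(results, "DSA_STRATIFIED", 100000)
    comp <- results[results$strategy == "DSA_STRATIFIED", ]
    brute <- with(results, cost < comp$cost & qaly > comp$qaly &
                    strategy != "DSA_STRATIFIED")
    expect_identical(cmp$classification == "dominant", brute)
  }
})

test_that("NMB ordering matches the ICER-threshold rule when defined", {
  set.seed(21)
  for (rep in 1:200) {
    a <- res(stats::runif(1, 0, 2e5), stats::runif(1, 0, 20))
    b <- res(stats::runif(1, 0, 2e5), stats::runif(1, 0, 20))
    wtp <- stats::runif(1, 1e4, 2e5)
    v <- icer(a, b)
    if (!v$defined) next
    nmb_pref_a <- nmb(a, wtp) > nmb(b, wtp)
    icer_pref_a <- if (v$delta_qaly > 0) v$icer < wtp else v$icer > wtp
    expect_identical(nmb_pref_a, icer_pref_a)
  }
})

test_that("the optimal strategy is invariant to consistent cost/wtp scaling", {
  set.seed(31)
  for (rep in 1:100) {
    results <- data.frame(
      strategy = strategies(),
      cost = stats::runif(4, 0, 2e5),
      qaly = stats::runif(4, 0, 20))
    wtp <- stats::runif(1, 1e4, 2e5)
    lambda <- stats::runif(1, 0.1, 10)
    scaled <- results
    scaled$cost <- scaled$cost * lambda
    expect_equal(optimal_strategy(results, wtp),
                 optimal_strategy(scaled, wtp * lambda))
  }
})

test_that("the efficiency frontier has increasing step ICERs", {
  deck <- default_deck()
  fr <- efficiency_frontier(run_strategies(deck))
  expect_true(all(diff(fr$cost) > 0))
  expect_true(all(diff(fr$qaly) > 0))
  steps <- fr$icer_step[-1]
  if (length(steps) > 1) expect_true(all(diff(steps) >= 0))
})
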