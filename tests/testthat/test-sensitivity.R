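test_that("a one-point one-way sweep reproduces the base case", {
  deck <- default_deck()
  ow <- one_way(deck, "lesion_prevalence", n = 1)
  base <- classify_strategies(run_strategies(deck))
  expect_equal(ow$cost, base$cost)
  expect_equal(ow$classification, base$classification)
  expect_error(one_way(deck, "bogus"), "valid names")
  expect_error(one_way(deck, "lesion_prevalence", values = c(0.9)),
               "outside the range")
})

test_that("sweeping a fixed value gives constant results", {
  deck <- default_deck()
  ow <- one_way(deck, "cost_cta", values = c(425, 425, 425))
  expect_equal(length(unique(round(ow$cost[ow$strategy == "DSA_ALL"], 6))), 1)
})

test_that("threshold searches agree with a dense grid scan", {
  deck <- default_deck()
  pred <- icer_exceeds("DSA_ALL", 100000)

  scan_crossing <- function(parameter, npts) {
    reg <- ichscreen:::param_registry()
    lo <- reg$low[reg$name == parameter]
    hi <- reg$high[reg$name == parameter]
    grid <- seq(lo, hi, length.out = npts)
    vals <- vapply(grid, function(v) pred(set_param(deck, parameter, v)),
                   logical(1))
    flip <- which(diff(vals) != 0)
    list(at = (grid[flip] + grid[flip + 1]) / 2, step = grid[2] - grid[1])
  }

  for (parameter in c("rebleed_secondary_untreated", "rr_after_repair")) {
    ts <- threshold_search(deck, parameter, pred, tol = 1e-4)
    sc <- scan_crossing(parameter, 500)
    expect_length(sc$at, 1)  # a single crossing over the range
    expect_lt(abs(ts$threshold - sc$at), 2 * sc$step)
  }
})

test_that("a constant predicate yields a no-threshold result", {
  deck <- default_deck()
  ts <- threshold_search(deck, "cost_cta", function(d) FALSE)
  expect_true(is.na(ts$threshold))
  expect_false(ts$predicate_low)
  expect_false(ts$predicate_high)
})

test_that("PSA draws are reproducible and CEAC fractions are coherent", {
  deck <- default_deck()
  p1 <- run_psa(deck, n = 25, seed = 123, wtp_grid = seq(0, 2e5, 5e4))
  p2 <- run_psa(deck, n = 25, seed = 123, wtp_grid = seq(0, 2e5, 5e4))
  expect_equal(p1$samples, p2$samples)
  expect_equal(p1$ceac, p2$ceac)
  p3 <- run_psa(deck, n = 25, seed = 124, wtp_grid = seq(0, 2e5, 5e4))
  expect_false(isTRUE(all.equal(p1$samples, p3$samples)))

  sums <- as.vector(tapply(p1$ceac$probability, p1$ceac$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)

  single <- run_psa(deck, n = 1, seed = 5, wtp_grid = c(5e4, 1e5))
  expect_true(all(single$ceac$probability %in% c(0, 1)))
})

test_that("a zero-width PSA reproduces the deterministic base case", {
  deck <- default_deck()
  for (nm in names(deck$psa))
    deck$psa[[nm]]$low <- deck$psa[[nm]]$high <- deck$psa[[nm]]$base
  psa <- run_psa(deck, n = 4, seed = 9)
  base <- run_strategies(deck)
  for (s in strategies()) {
    expect_equal(psa$samples[[paste0("cost_", s)]],
                 rep(base$cost[base$strategy == s], 4), tolerance = 1e-9)
    expect_equal(psa$samples[[paste0("qaly_", s)]],
                 rep(base$qaly[base$strategy == s], 4), tolerance = 1e-9)
  }
})

test_that("sampled parameters respect their supports", {
  deck <- default_deck()
  psa <- run_psa(deck, n = 60, seed = 31)
  s <- psa$samples
  expect_true(all(s$initial_age >= 10 & s$initial_age <= 80))
  expect_true(all(s$cost_cta >= 0 & s$cost_dsa >= 0))
  expect_true(all(s$cta_sens > 0 & s$cta_sens < 1))
  expect_true(all(s$rr_after_repair * s$rebleed_secondary_untreated <= 1))
})

test_that("the two-way age x prevalence map is consistent and regime-like", {
  deck <- default_deck()
  one <- two_way_age_prevalence(deck, ages = 40, prevalences = 0.45,
                                wtp = 1e5)
  base <- classify_strategies(run_strategies(deck), wtp = 1e5)
  expect_equal(as.vector(unclass(one)), base$strategy[base$optimal])
  expect_error(two_way_age_prevalence(deck, ages = numeric(0)), "nonempty")

  prevs <- seq(0.02, 0.60, by = 0.04)
  m <- two_way_age_prevalence(deck, ages = c(40, 60), prevalences = prevs,
                              wtp = 1e5)
  expect_true(all(unclass(m) %in% strategies()))
  # piecewise-constant in prevalence: few regime changes per age column
  for (j in 1:2)
    expect_lte(length(rle(m[, j])$values), 4)
})
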