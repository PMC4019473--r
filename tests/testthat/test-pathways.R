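test_that("Bayes revision matches hand arithmetic and limiting cases", {
  ncct <- list(sens = 0.95, spec = 0.35)
  expect_equal(bayes_posttest(0.45, ncct, "positive"),
               0.45 * 0.95 / (0.45 * 0.95 + 0.55 * 0.65))
  expect_equal(round(bayes_posttest(0.45, ncct, "positive"), 4), 0.5446)
  perfect <- list(sens = 1, spec = 1)
  expect_equal(bayes_posttest(0.3, perfect, "positive"), 1)
  expect_equal(bayes_posttest(0.3, perfect, "negative"), 0)
  expect_equal(bayes_posttest(0, ncct, "positive"), 0)
  expect_error(bayes_posttest(0, list(sens = 1, spec = 1), "positive"),
               "impossible")
})

test_that("Bayes post-test probability is monotone in prevalence and sensitivity", {
  ncct <- list(sens = 0.95, spec = 0.35)
  post <- vapply(seq(0, 1, 0.05), bayes_posttest, numeric(1),
                 perf = ncct, result = "positive")
  expect_true(all(diff(post) >= -1e-12))
  post_se <- vapply(seq(0.5, 1, 0.05), function(se)
    bayes_posttest(0.45, list(sens = se, spec = 0.35), "positive"), numeric(1))
  expect_true(all(diff(post_se) >= -1e-12))
})

test_that("pathway probabilities follow the test cascade", {
  deck <- default_deck()
  pa <- enumerate_pathways("CTA_ALL", deck)
  expect_equal(pa$probability[pa$label == "TP"], 0.45 * 0.96)
  pd <- enumerate_pathways("DSA_ALL", deck)
  expect_setequal(pd$label, c("TP", "TN"))
  expect_equal(pd$probability[pd$label == "TP"], 0.45)
  ps <- enumerate_pathways("CTA_STRATIFIED", deck)
  expect_equal(ps$probability[ps$label == "TP"], 0.45 * 0.95 * 0.96)
  expect_equal(ps$probability[ps$label == "UNIMAGED_LESION"], 0.45 * 0.05)
  # cost/outcome assignments
  expect_equal(ps$hosp_cost[ps$label == "TP"], 85400)
  expect_equal(ps$hosp_cost[ps$label == "FN"], 25300)
  expect_equal(ps$lesion_after[ps$label == "TP"], "treated")
  expect_equal(ps$lesion_after[ps$label == "UNIMAGED_LESION"], "untreated")
  expect_equal(ps$mrs_source[ps$label == "TN"], "primary")
})

test_that("expected upfront imaging cost weights the imaged fraction", {
  deck <- default_deck()
  expect_equal(expected_upfront_cost("CTA_ALL", deck), 425)
  expect_equal(expected_upfront_cost("DSA_STRATIFIED", deck),
               1100 * (0.45 * 0.95 + 0.55 * 0.65))
  free <- deck
  free$costs$cta <- free$costs$dsa <- 0
  for (s in strategies())
    expect_equal(expected_upfront_cost(s, free), 0)
})

test_that("pathway probabilities sum to one for random decks (property)", {
  for (seed in 1:20) {
    d <- random_deck(seed)
    for (s in strategies()) {
      pw <- enumerate_pathways(s, d)
      expect_equal(sum(pw$probability), 1, tolerance = 1e-9)
      expect_true(all(pw$lesion_after[pw$label == "TP"] == "treated"))
    }
  }
})

test_that("P(TP) is nondecreasing in prevalence and cascade sensitivities", {
  deck <- default_deck()
  tp <- function(d, s) {
    pw <- enumerate_pathways(s, d)
    pw$probability[pw$label == "TP"]
  }
  for (s in c("CTA_ALL", "CTA_STRATIFIED")) {
    tps <- vapply(seq(0, 0.7, 0.05), function(p)
      tp(set_param(deck, "lesion_prevalence", p), s), numeric(1))
    expect_true(all(diff(tps) >= -1e-12))
    tps <- vapply(seq(0.8, 1, 0.02), function(se)
      tp(set_param(deck, "cta_sens", se), s), numeric(1))
    expect_true(all(diff(tps) >= -1e-12))
  }
  tps <- vapply(seq(0.7, 1, 0.05), function(se)
    tp(set_param(deck, "ncct_sens", se), "CTA_STRATIFIED"), numeric(1))
  expect_true(all(diff(tps) >= -1e-12))
})

test_that("an all-flagging NCCT makes stratified arms equal their screen-all twins", {
  deck <- default_deck()
  deck$tests$ncct <- list(sens = 1, spec = 0)  # everyone high/indeterminate
  for (pair in list(c("CTA_ALL", "CTA_STRATIFIED"),
                    c("DSA_ALL", "DSA_STRATIFIED"))) {
    a <- enumerate_pathways(pair[1], deck)
    b <- enumerate_pathways(pair[2], deck)
    b <- b[b$probability > 0, ]
    merged <- merge(a, b, by = "label")
    expect_equal(merged$probability.x, merged$probability.y, tolerance = 1e-12)
    ra <- run_cohort(pair[1], deck)
    rb <- run_cohort(pair[2], deck)
    expect_equal(ra$expected_cost, rb$expected_cost, tolerance = 1e-9)
    expect_equal(ra$expected_qaly, rb$expected_qaly, tolerance = 1e-9)
  }
})
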