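---
title: "A Markov cohort model of vascular imaging strategies in intracerebral hemorrhage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of vascular imaging strategies in intracerebral hemorrhage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichscreen)
```

## The decision problem

After intracerebral hemorrhage (ICH) is diagnosed on non-contrast head CT
(NCCT), some patients harbor an underlying vascular anomaly — an aneurysm or
arteriovenous malformation — whose repair sharply reduces the risk of
re-bleeding. Finding it requires vascular imaging: CT angiography (CTA, a
cheap non-invasive test with imperfect sensitivity and specificity) or
digital subtraction angiography (DSA, the invasive reference standard).
NCCT appearance itself can stratify patients into low versus
high/indeterminate suspicion. That yields four strategies at the decision
node:

* **CTA_ALL** — CTA for the whole cohort;
* **CTA_STRATIFIED** — CTA only after a high/indeterminate NCCT;
* **DSA_ALL** — DSA for the whole cohort;
* **DSA_STRATIFIED** — DSA only after a high/indeterminate NCCT (the
  comparator).

`ichscreen` evaluates the lifetime discounted cost (2011 USD, payer
perspective) and quality-adjusted life years (QALYs) of each strategy with
a yearly-cycle Markov cohort model, then compares them by incremental
cost-effectiveness ratio (ICER), dominance classification and net monetary
benefit (NMB).

```{r basecase}
fit <- ich_cua(default_deck())
fit
```

## Model structure

**Diagnostic phase (time 0).** The cohort splits into joint-probability
pathways by the test cascade: under stratified strategies NCCT
(sensitivity 0.95, specificity 0.35 for high/indeterminate appearance)
gates who is imaged, then CTA (0.96/0.99) or DSA (assumed a perfect
reference test) applies to the imaged subset. Each pathway carries an
imaging cost (CTA \$425, DSA \$1,100; NCCT is common to all branches and
carries no differential cost), a hospitalization cost (secondary-ICH
admission \$85,400 when a lesion is identified and repaired, including
false positives, who undergo an unnecessary intervention; primary-ICH /
missed-lesion admission \$25,300 otherwise) and a downstream lesion status:
`treated` for true positives, `untreated` for missed lesions, `none`
otherwise. Post-test lesion probabilities follow Bayes revision
(`bayes_posttest()`).

**Index outcome.** Survivorship and disability after the presenting bleed
follow a modified Rankin Scale (mRS) distribution banded 0–1 / 2–3 / 4–5 /
6 (dead): 8/23/40/29% after primary ICH, 69.4/22.4/3.5/4.7% after
secondary ICH.

**Markov phase.** Living states are mRS band × lesion status × a
years-since-bleed tunnel (0, 1, 2+) that prices the first post-bleed year
of mRS 4–5 care (\$71,428) above later years (\$37,140; extended to all
subsequent years); mRS 2–3 care costs \$8,438 every year, mRS 0–1 nothing.
Each one-year cycle applies, in order: background all-cause mortality by
current age; re-bleed events (primary etiology 2.08%/cycle, untreated
lesion 3.92%, treated lesion 3.92% × RR 0.35); then cost and utility
accrual (utilities 0.90 / 0.75 / 0.25 / 0). A re-bleed sends the subject
to DSA plus the etiology-appropriate hospitalization, any lesion present is
then repaired, and the mRS band is redrawn from the etiology-appropriate
distribution under a worse-of rule — prior disability does not vanish.
Costs and QALYs accrue to the horizon (age 100 by default) discounted at
3%/year with end-of-cycle factors $(1+r)^{-k}$, the time-0 imaging and
admission costs undiscounted.

The engine computes expected values by backward induction over the 28
states, which makes prevalence sweeps cheap (state values are independent
of prevalence); `cohort_trace()` exposes the equivalent forward trace and
the test suite checks the two agree to 1e-9.

## Two conventions the evidence base does not settle

Two structural choices materially affect the comparison and are explicit
deck settings rather than silent assumptions.

**Outcome of a missed lesion (`missed_lesion_mrs`).** When a lesion goes
undetected (false-negative CTA, or an unimaged low-suspicion NCCT), which
index-bleed outcome distribution applies? The default, `"secondary"`,
assigns the outcome of the hemorrhage the patient actually had — a
secondary ICH — so detection changes treatment, costs and re-bleed risk but
not the severity of the index bleed. This is the internally consistent
reading: the model's own re-bleed rule redraws outcomes by etiology, and
the health states are organized around primary versus secondary
presentation. The alternative `"primary"` ties outcome to the mistaken
working diagnosis; it makes a missed lesion catastrophic (29% dead versus
4.7%), and under it the stratified-CTA arm — which misses 4% of what
stratified DSA confirms — can never be both cheaper and more effective
than its DSA counterpart, for any parameter values.

**Accrual in a re-bleed year (`event_cycle_accrual`).** The default,
`"state"`, accrues the event year's care cost and utility by the
post-event state occupancy (tunnel year 0, worse-of band), exactly as the
model-entry year is accrued; survivors then enter the next cycle at tunnel
year 1. The alternative `"none"` books only the event costs and treats the
bleed year as lost to hospitalization, which prices each re-bleed at
roughly a full utility-year on top of its clinical consequences.

```{r conventions}
strict <- default_deck()
strict$settings$missed_lesion_mrs <- "primary"
strict$settings$event_cycle_accrual <- "none"
rbind(default = run_strategies(default_deck())$qaly,
      strict = run_strategies(strict)$qaly)
```

## Synthetic inputs

Two inputs the model needs are not part of the published evidence base and
are generated as clearly labelled synthetic stand-ins:

* **Background life table** (`make_life_table()`): a Gompertz–Makeham
  curve $q(a) = \min(1, A + B\,c^a)$ with defaults $A = 5\times10^{-4}$,
  $B = 3\times10^{-5}$, $c = 1.09$, approximating a 2010-era US all-cause
  schedule; $q(110)$ is forced to 1. A lifetime horizon starting at age 40
  is meaningless without background mortality; it can be switched off
  (`settings$background_mortality = FALSE`) for structural checks.
* **Age-to-prevalence look-up** (`make_prevalence_lookup()`):
  piecewise-constant by decade, anchored at 45% for the base-case
  40-year-old, with a marked dip (8%) in the 41–50 decade — the feature
  that makes imaging everyone with CTA attractive in exactly that band.
  The anchors are explicit arguments and should be replaced when real
  look-up data are available.

`random_deck(seed)` draws every input uniformly from its one-way range
(outcome distributions renormalised), producing valid decks for
property-style testing.

What these stand-ins cannot do: reproduce the absolute dollar and QALY
levels of the original analysis, which used an unpublished life table and
look-up. Comparisons *between* strategies are far less sensitive to both,
because all four arms share the same mortality and, at a fixed prevalence,
the same case mix; the test suite therefore checks orderings, regime
structure and toleranced magnitudes rather than absolute levels.

## Sensitivity machinery

* `one_way()` sweeps any scalar input over its plausible range;
  `prevalence_sweep()` adds all-strategy dominance flags per grid point.
* `two_way_age_prevalence()` maps the NMB-optimal strategy over an age ×
  prevalence grid at a stated willingness to pay.
* `threshold_search()` bisects an input for the point where a predicate
  (e.g. `icer_exceeds("DSA_ALL", 1e5)`) flips, to 1e-4 of the range; a
  predicate constant over the range returns a no-threshold result.
* `run_psa()` draws all uncertain inputs jointly and independently from
  the distributions declared in the deck (`beta`, `dirichlet`, `normal`,
  `lognormal`) and builds the cost-effectiveness acceptability curve. The
  lesion prevalence and the discount rate carry no distribution and stay
  fixed; sampled age re-indexes the mortality curve and is truncated to
  10–80; normal cost draws are truncated at zero.

Distribution fitting (`fit_distribution()`) treats a (low, high) range as
an approximate central 95% interval when no SD is stated, and
parameterises every family so the distribution **mean** equals the
base-case value — including lognormals, whose log-mean is shifted by
$-\sigma^2/2$; with a zero lower range endpoint, $\sigma$ comes from the
upper half-interval. The Dirichlet concentration defaults to
$\alpha_0 = 100$ (marginal SDs of a few percentage points, roughly
matching the per-band ranges); it is a spec field (`alpha0`), not a fit.

```{r psa, eval = FALSE}
psa <- simulate(fit, nsim = 1000, seed = 1)
plot(psa)                      # acceptability curves
ceac_band(psa, "CTA_STRATIFIED", c(5e4, 1.5e5))
```

## Numerical choices

* Cycle length fixed at one year; horizon `max_age` 100.
* No half-cycle correction by default (flag available; it removes half of
  the first and last cycle's accrual).
* Occupancy conservation is asserted at 1e-9; ICERs are flagged undefined
  below a QALY difference of 1e-12 rather than returning ±Inf.
* NMB ties break toward lower cost, then toward the comparator.
* Bisection tolerance 1e-4 of the range; the suite cross-checks both
  published threshold searches against a 500-point grid scan.
* PSA relative-risk draws are redrawn in the rare case the implied treated
  re-bleed probability would exceed one.

## Validation strategy and problem sizes

The cohort engine is validated against an independent individual-level
microsimulation (per-person annual draws, no shared code) on five random
decks at 6,000 simulees each, within three Monte-Carlo standard errors of
both cost and QALYs. Deck invariants are property-tested over 1,000
random seeds, pathway algebra over 20, and the full pipeline end-to-end
with a 50-draw PSA; the in-suite reproduction checks run the published
PSA size (n = 1,000). These sizes are the package's own choices,
balancing statistical resolution against a suite that runs in well under
a minute for the deterministic parts.

## Known limitations

* Hemorrhage from tumor, DSA procedural complications as a separate event,
  contrast nephropathy, time-varying re-bleed rates and covariates
  (hypertension, anticoagulation) are all out of scope, matching the
  source analysis's own simplifications.
* PSA draws are independent — no correlation structure is imposed.
* The pairwise-vs-comparator classification mirrors the source framing;
  `efficiency_frontier()` offers the league-table view as a secondary
  report only.
* The false-positive CTA pathway (secondary-ICH admission cost,
  primary-ICH outcomes, no lesion) is an assumption: the source describes
  the true-positive and false-negative cost structures in prose but not
  the false-positive one.
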