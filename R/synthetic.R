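#' Synthetic background life table
#'
#' The lifetime-horizon model needs an all-cause annual mortality schedule,
#' which the published inputs do not include. This constructor supplies a
#' synthetic stand-in: a Gompertz-Makeham curve `q(age) = min(1, a + b *
#' c^age)` with defaults chosen to approximate a 2010-era United States
#' all-cause curve (life expectancy at age 40 of roughly four decades).
#' `q(110)` is forced to 1 so the cohort is extinct by the end of the table.
#'
#' @param a Makeham age-independent floor (annual probability).
#' @param b Gompertz level parameter.
#' @param c Gompertz rate of aging (per year).
#' @return a data.frame of class `ich_life_table` with columns `age` (0..110)
#'   and `qx` (annual death probability).
#' @examples
#' lt <- make_life_table()
#' lt$qx[lt$age == 40]
#' @export
make_life_table <- function(a = 5e-4, b = 3e-5, c = 1.09) {
  if (a < 0 || b < 0 || c <= 0)
    stop("life table parameters must be positive", call. = FALSE)
  age <- 0:110
  qx <- pmin(1, a + b * c^age)
  qx[length(qx)] <- 1
  if (qx[age == 40] > 0.05)
    warning("q(40) > 5% is implausible for an all-cause background curve")
  out <- data.frame(age = age, qx = qx)
  class(out) <- c("ich_life_table", "data.frame")
  out
}

#' Annual death probability at an age
#'
#' @param life_table a life table from [make_life_table()].
#' @param age age in years (vectorised); ages beyond the table use `qx = 1`.
#' @return annual death probabilities.
#' @export
mortality_at_age <- function(life_table, age) {
  idx <- pmin(floor(age), max(life_table$age)) + 1
  life_table$qx[idx]
}

#' Synthetic age-to-lesion-prevalence look-up
#'
#' The probability that an ICH harbors an underlying vascular anomaly varies
#' with age, but the per-decade values used in the source analyses are not
#' published. This builds a piecewise-constant (by decade) stand-in anchored
#' at 45% for a 40-year-old — the base case — and with a marked dip in the
#' 41-50 decade, the feature that makes screening everyone with CTA
#' attractive in exactly that age band. All anchors are explicit arguments;
#' the defaults are synthetic and should be replaced when real look-up data
#' are available.
#'
#' @param anchors named numeric vector: names are decade lower bounds
#'   (`"0"`, `"11"`, `"21"`, ...), values are lesion prevalences for the
#'   decade starting there.
#' @return a data.frame of class `ich_prevalence_lookup` with columns
#'   `age_lo`, `age_hi`, `prevalence`.
#' @examples
#' pl <- make_prevalence_lookup()
#' prevalence_at_age(pl, 40)
#' @export
make_prevalence_lookup <- function(anchors = c(`0` = 0.60, `11` = 0.60,
                                               `21` = 0.55, `31` = 0.45,
                                               `41` = 0.08, `51` = 0.30,
                                               `61` = 0.25, `71` = 0.20,
                                               `81` = 0.20)) {
  if (any(anchors < 0 | anchors > 1))
    stop("prevalence anchors must be probabilities", call. = FALSE)
  lo <- as.integer(names(anchors))
  ord <- order(lo)
  lo <- lo[ord]
  prev <- as.numeric(anchors)[ord]
  hi <- c(lo[-1] - 1, 110L)
  out <- data.frame(age_lo = lo, age_hi = hi, prevalence = prev)
  class(out) <- c("ich_prevalence_lookup", "data.frame")
  out
}

#' @rdname make_prevalence_lookup
#' @param lookup a prevalence look-up table.
#' @param age age in years (vectorised).
#' @export
prevalence_at_age <- function(lookup, age) {
  vapply(age, function(a) {
    row <- which(lookup$age_lo <= a & a <= lookup$age_hi)
    if (!length(row)) row <- nrow(lookup)
    lookup$prevalence[row[1]]
  }, numeric(1))
}

#' Random valid parameter deck
#'
#' Draws every scalar model input uniformly from its one-way range and both
#' mRS distributions from renormalised uniform band draws, producing a deck
#' that passes all invariants. Deterministic per seed. Used for
#' property-style testing of the pipeline.
#'
#' @param seed integer seed.
#' @return a validated `ich_deck`.
#' @export
random_deck <- function(seed) {
  r <- runif_lcg(seed)
  deck <- unclass(default_deck())
  reg <- param_registry()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    v <- reg$low[i] + r() * (reg$high[i] - reg$low[i])
    if (nm == "initial_age") v <- floor(v)
    # keep sens/spec and rates away from degenerate endpoints
    deck <- set_param_raw(deck, nm, v)
  }
  # guarantee treated re-bleed probability stays a probability
  rrmax <- 1 / max(deck$epi$rebleed_secondary_untreated, 1e-6)
  deck$epi$rr_after_repair <- min(deck$epi$rr_after_repair, min(rrmax, 2))
  for (m in c("primary", "secondary")) {
    x <- vapply(1:4, function(i) r(), numeric(1))
    x <- x / sum(x)
    names(x) <- c("mrs01", "mrs23", "mrs45", "mrs6")
    deck$mrs[[m]] <- x
  }
  class(deck) <- "ich_deck"
  validate_deck(deck)
  deck
}

# set_param without the class round-trip
set_param_raw <- function(deck, name, value) {
  cls <- class(deck)
  class(deck) <- "ich_deck"
  deck <- set_param(deck, name, value)
  class(deck) <- cls
  deck
}

# small deterministic uniform generator so random_deck does not disturb the
# caller's .Random.seed
runif_lcg <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
}
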