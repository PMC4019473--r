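#' Default parameter deck
#'
#' Builds the complete set of model inputs for the base-case analysis: a
#' 40-year-old cohort presenting with intracerebral hemorrhage (ICH) and a 45%
#' probability of an underlying vascular anomaly. Diagnostic test performance,
#' modified Rankin Scale (mRS) outcome distributions by hemorrhage etiology,
#' per-cycle re-bleed probabilities, costs (2011 USD, payer perspective),
#' utility weights and run settings are all explicit fields and can be edited
#' before running the model. Probabilistic sensitivity analysis (PSA)
#' distribution specifications (family, base value, plausible range) ride
#' along in `$psa`.
#'
#' Two inputs the published evidence base does not supply — an all-cause
#' background life table and an age-to-lesion-prevalence look-up — default to
#' synthetic stand-ins from [make_life_table()] and
#' [make_prevalence_lookup()].
#'
#' @param initial_age cohort age in years at presentation.
#' @param lesion_prevalence pre-test probability of an underlying vascular
#'   anomaly (aneurysm, arteriovenous malformation) at presentation.
#' @param discount_rate annual discount rate applied to future costs and
#'   QALYs.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @param max_age horizon cap in years; the cohort is followed until this age
#'   or extinction.
#' @param missed_lesion_mrs which mRS outcome distribution governs patients
#'   whose vascular lesion goes undetected at presentation (false negatives
#'   and unimaged low-risk patients): `"secondary"` (default) assigns the
#'   outcome of the hemorrhage they actually had — a secondary ICH — so that
#'   detection changes treatment and costs but not the severity of the index
#'   bleed; `"primary"` assigns the primary-ICH distribution, tying outcome to
#'   the (mistaken) working diagnosis. See the package vignette for why the
#'   etiology-based default is the internally consistent reading.
#'
#' A related convention, `settings$event_cycle_accrual`, controls the cycle
#' in which a re-bleed occurs: `"state"` (default) accrues that year's
#' long-term-care cost and utility by the post-event state occupancy, the
#' same way the model-entry year is accrued; `"none"` books only the event
#' costs, treating the event year as lost to hospitalization.
#'
#' @return A list of class `ich_deck` with components `tests`, `mrs`, `epi`,
#'   `costs`, `utilities`, `settings`, `life_table`, `prevalence_lookup`,
#'   `psa`.
#' @examples
#' deck <- default_deck()
#' deck$tests$cta$sens
#' @export
default_deck <- function(initial_age = 40,
                         lesion_prevalence = 0.45,
                         discount_rate = 0.03,
                         wtp = 100000,
                         max_age = 100,
                         missed_lesion_mrs = c("secondary", "primary")) {
  missed_lesion_mrs <- match.arg(missed_lesion_mrs)
  deck <- list(
    tests = list(
      cta  = list(sens = 0.96, spec = 0.99),
      ncct = list(sens = 0.95, spec = 0.35),
      # catheter angiography treated as the reference standard
      dsa  = list(sens = 1.00, spec = 1.00)
    ),
    mrs = list(
      primary   = c(mrs01 = 0.08,  mrs23 = 0.23,  mrs45 = 0.40,  mrs6 = 0.29),
      secondary = c(mrs01 = 0.694, mrs23 = 0.224, mrs45 = 0.035, mrs6 = 0.047)
    ),
    epi = list(
      lesion_prevalence = lesion_prevalence,
      rebleed_primary = 0.0208,
      rebleed_secondary_untreated = 0.0392,
      rr_after_repair = 0.35
    ),
    costs = list(
      cta = 425, dsa = 1100,
      hosp_secondary = 85400, hosp_primary = 25300,
      ltc_mrs23 = 8438, ltc_mrs45_year1 = 71428, ltc_mrs45_later = 37140
    ),
    utilities = c(mrs01 = 0.90, mrs23 = 0.75, mrs45 = 0.25, dead = 0),
    settings = list(
      initial_age = initial_age,
      max_age = max_age,
      discount_rate = discount_rate,
      wtp = wtp,
      cycle_length = 1,
      half_cycle_correction = FALSE,
      background_mortality = TRUE,
      missed_lesion_mrs = missed_lesion_mrs,
      event_cycle_accrual = "state"
    ),
    life_table = make_life_table(),
    prevalence_lookup = make_prevalence_lookup(),
    psa = default_psa_specs()
  )
  class(deck) <- "ich_deck"
  validate_deck(deck)
}

#' PSA distribution specifications for every uncertain input
#'
#' One `DistributionSpec` per sampled parameter: family (`beta`, `dirichlet`,
#' `normal`, `lognormal`), base-case value, and the low/high range treated as
#' an approximate central 95% interval when no SD is stated. The lesion
#' prevalence and the discount rate carry no distribution and are held fixed
#' in the PSA.
#'
#' @return named list of specs, each a list with fields `family`, `base`,
#'   `low`, `high` and optionally `sd` (normal) or `alpha0` (dirichlet).
#' @export
default_psa_specs <- function() {
  spec <- function(family, base, low, high, ...)
    c(list(family = family, base = base, low = low, high = high), list(...))
  list(
    cta_sens  = spec("beta", 0.96, 0.8, 1.0),
    cta_spec  = spec("beta", 0.99, 0.8, 1.0),
    ncct_sens = spec("beta", 0.95, 0.7, 1.0),
    ncct_spec = spec("beta", 0.35, 0.0, 0.6),
    mrs_primary = spec("dirichlet",
                       c(mrs01 = 0.08, mrs23 = 0.23, mrs45 = 0.40, mrs6 = 0.29),
                       c(0, 0, 0.30, 0.15), c(0.18, 0.50, 0.50, 0.45),
                       alpha0 = 100),
    mrs_secondary = spec("dirichlet",
                         c(mrs01 = 0.694, mrs23 = 0.224, mrs45 = 0.035, mrs6 = 0.047),
                         c(0.30, 0, 0, 0), c(1, 0.50, 0.20, 0.20),
                         alpha0 = 100),
    rebleed_primary = spec("beta", 0.0208, 0, 0.06),
    rebleed_secondary_untreated = spec("beta", 0.0392, 0, 0.10),
    rr_after_repair = spec("lognormal", 0.35, 0, 2),
    cost_cta = spec("normal", 425, 100, 1500),
    cost_dsa = spec("normal", 1100, 450, 2000),
    hosp_secondary = spec("lognormal", 85400, 10000, 300000),
    hosp_primary = spec("lognormal", 25300, 3000, 120000),
    ltc_mrs23 = spec("lognormal", 8438, 0, 20000),
    ltc_mrs45_year1 = spec("lognormal", 71428, 30000, 150000),
    ltc_mrs45_later = spec("lognormal", 37140, 10000, 90000),
    u_mrs01 = spec("beta", 0.90, 0.2, 1.0),
    u_mrs23 = spec("beta", 0.75, 0.0, 1.0),
    u_mrs45 = spec("beta", 0.25, -0.1, 1.0),
    initial_age = spec("normal", 40, 10, 80, sd = 12.5)
  )
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter deck: field '%s' %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop_field(field, "must be a nonnegative number")
  invisible(x)
}

#' Validate a parameter deck
#'
#' Checks every invariant: probabilities in \[0,1\], mRS distributions summing
#' to one (tolerance 1e-9), nonnegative costs and relative risk, utilities no
#' greater than one (negative values, states worse than death, are allowed),
#' `initial_age < max_age`, a well-formed life table and prevalence look-up,
#' and PSA specs with `low <= base <= high`. Missing required fields are
#' reported by name.
#'
#' @param deck an `ich_deck`.
#' @return the deck, invisibly, if valid; otherwise an error describing the
#'   offending field.
#' @export
validate_deck <- function(deck) {
  required <- c("tests", "mrs", "epi", "costs", "utilities", "settings",
                "life_table", "prevalence_lookup", "psa")
  missing <- setdiff(required, names(deck))
  if (length(missing))
    stop_field(missing[1], "is missing")

  for (tname in c("cta", "ncct", "dsa")) {
    t <- deck$tests[[tname]]
    if (is.null(t) || is.null(t$sens) || is.null(t$spec))
      stop_field(paste0("tests$", tname), "must supply sens and spec")
    check_prob(t$sens, paste0("tests$", tname, "$sens"))
    check_prob(t$spec, paste0("tests$", tname, "$spec"))
  }
  for (mname in c("primary", "secondary")) {
    m <- deck$mrs[[mname]]
    if (is.null(m) || length(m) != 4)
      stop_field(paste0("mrs$", mname), "must have four mRS bands")
    for (i in seq_along(m)) check_prob(m[[i]], paste0("mrs$", mname))
    if (abs(sum(m) - 1) > 1e-9)
      stop_field(paste0("mrs$", mname), "must sum to 1 (tolerance 1e-9)")
  }
  check_prob(deck$epi$lesion_prevalence, "epi$lesion_prevalence")
  check_prob(deck$epi$rebleed_primary, "epi$rebleed_primary")
  check_prob(deck$epi$rebleed_secondary_untreated,
             "epi$rebleed_secondary_untreated")
  check_nonneg(deck$epi$rr_after_repair, "epi$rr_after_repair")
  if (deck$epi$rebleed_secondary_untreated * deck$epi$rr_after_repair > 1)
    stop_field("epi$rr_after_repair",
               "times the untreated re-bleed rate must not exceed 1")
  for (cname in names(deck$costs))
    check_nonneg(deck$costs[[cname]], paste0("costs$", cname))
  u <- deck$utilities
  if (length(u) != 4 || any(is.na(u)) || any(u > 1))
    stop_field("utilities", "must be four values, each <= 1")
  if (u[["dead"]] != 0)
    stop_field("utilities$dead", "must be 0")
  s <- deck$settings
  if (!is.numeric(s$initial_age) || s$initial_age < 0 ||
      s$initial_age >= s$max_age)
    stop_field("settings$initial_age", "must satisfy 0 <= initial_age < max_age")
  check_nonneg(s$discount_rate, "settings$discount_rate")
  check_nonneg(s$wtp, "settings$wtp")
  if (!identical(s$cycle_length, 1) && !identical(s$cycle_length, 1L))
    stop_field("settings$cycle_length", "is fixed at 1 year")
  if (!s$missed_lesion_mrs %in% c("primary", "secondary"))
    stop_field("settings$missed_lesion_mrs",
               "must be 'primary' or 'secondary'")
  if (!s$event_cycle_accrual %in% c("state", "none"))
    stop_field("settings$event_cycle_accrual",
               "must be 'state' or 'none'")
  lt <- deck$life_table
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt)) ||
      nrow(lt) != 111)
    stop_field("life_table", "must be a data.frame with ages 0..110 and qx")
  if (any(lt$qx < 0 | lt$qx > 1) || lt$qx[nrow(lt)] != 1)
    stop_field("life_table$qx", "must lie in [0,1] with qx(110) = 1")
  if (any(diff(lt$qx[lt$age >= 30]) < -1e-12))
    stop_field("life_table$qx", "must be nondecreasing above age 30")
  pl <- deck$prevalence_lookup
  if (!is.data.frame(pl) || !all(c("age_lo", "age_hi", "prevalence") %in% names(pl)))
    stop_field("prevalence_lookup", "must have age_lo, age_hi, prevalence")
  if (any(pl$prevalence < 0 | pl$prevalence > 1))
    stop_field("prevalence_lookup$prevalence", "must lie in [0,1]")
  for (pn in names(deck$psa)) {
    sp <- deck$psa[[pn]]
    if (!sp$family %in% c("beta", "dirichlet", "normal", "lognormal"))
      stop_field(paste0("psa$", pn, "$family"), "has unknown family")
    if (any(sp$base < sp$low - 1e-12) || any(sp$base > sp$high + 1e-12))
      stop_field(paste0("psa$", pn), "must satisfy low <= base <= high")
    if (sp$family == "beta" &&
        (any(sp$base <= 0) || any(sp$base >= 1)))
      stop_field(paste0("psa$", pn), "beta base must lie in (0, 1)")
  }
  invisible(deck)
}

#' @export
print.ich_deck <- function(x, ...) {
  s <- x$settings
  cat("ICH imaging cost-utility parameter deck\n")
  cat(sprintf("  cohort: age %s, lesion prevalence %.1f%%\n",
              format(s$initial_age), 100 * x$epi$lesion_prevalence))
  cat(sprintf("  horizon to age %d, discount %.1f%%/yr, WTP $%s/QALY\n",
              s$max_age, 100 * s$discount_rate,
              format(s$wtp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  CTA sens/spec %.2f/%.2f; NCCT high-or-indeterminate %.2f/%.2f\n",
              x$tests$cta$sens, x$tests$cta$spec,
              x$tests$ncct$sens, x$tests$ncct$spec))
  cat(sprintf("  re-bleed per cycle: primary %.2f%%, secondary untreated %.2f%%, RR after repair %.2f\n",
              100 * x$epi$rebleed_primary,
              100 * x$epi$rebleed_secondary_untreated,
              x$epi$rr_after_repair))
  invisible(x)
}

## ---- deck file i/o (YAML) --------------------------------------------------

#' Read a parameter deck from a YAML file
#'
#' The file holds one YAML document mirroring the structure of
#' [default_deck()]. Any field omitted from the file keeps its base-case
#' default; the assembled deck is validated before being returned.
#'
#' @param path file path.
#' @return a validated `ich_deck`.
#' @seealso [write_deck()]
#' @export
read_deck <- function(path) {
  if (!file.exists(path))
    stop("deck file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  deck <- unclass(default_deck())
  deck <- modify_deck(deck, raw)
  # YAML stores the tables as per-column lists
  if (!is.null(raw$life_table))
    deck$life_table <- as.data.frame(raw$life_table)
  if (!is.null(raw$prevalence_lookup))
    deck$prevalence_lookup <- as.data.frame(raw$prevalence_lookup)
  class(deck$life_table) <- c("ich_life_table", "data.frame")
  class(deck$prevalence_lookup) <- c("ich_prevalence_lookup", "data.frame")
  for (m in c("primary", "secondary"))
    deck$mrs[[m]] <- unlist(deck$mrs[[m]])
  deck$utilities <- unlist(deck$utilities)
  for (pn in names(deck$psa)) {
    deck$psa[[pn]]$base <- unlist(deck$psa[[pn]]$base)
    deck$psa[[pn]]$low <- unlist(deck$psa[[pn]]$low)
    deck$psa[[pn]]$high <- unlist(deck$psa[[pn]]$high)
  }
  class(deck) <- "ich_deck"
  validate_deck(deck)
  deck
}

# recursive overlay of user values onto defaults
modify_deck <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !is.data.frame(base[[nm]]))
      base[[nm]] <- modify_deck(base[[nm]], new[[nm]])
    else
      base[[nm]] <- new[[nm]]
  }
  base
}

#' Write a parameter deck to a YAML file
#'
#' Round-trip lossless with [read_deck()] at 15 significant digits.
#'
#' @param deck a validated `ich_deck`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_deck <- function(deck, path) {
  validate_deck(deck)
  x <- unclass(deck)
  x$mrs <- lapply(x$mrs, as.list)
  x$utilities <- as.list(x$utilities)
  x$life_table <- as.list(x$life_table)
  x$prevalence_lookup <- as.list(x$prevalence_lookup)
  for (pn in names(x$psa)) {
    for (f in c("base", "low", "high")) {
      v <- x$psa[[pn]][[f]]
      if (length(v) > 1) x$psa[[pn]][[f]] <- as.list(v)
    }
  }
  txt <- yaml::as.yaml(x, precision = 15)
  ok <- tryCatch(suppressWarnings({
    writeLines(txt, path)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop("cannot write deck to ", path, call. = FALSE)
  invisible(path)
}

#' Export the deck as a flat input table
#'
#' One row per model input with its base-case value, one-way range and PSA
#' distribution family — a machine-readable replica of the model-input table.
#' All monetary values are 2011 USD.
#'
#' @param deck an `ich_deck`.
#' @return a data.frame with columns `parameter`, `base`, `low`, `high`,
#'   `distribution`.
#' @export
deck_table <- function(deck) {
  validate_deck(deck)
  reg <- param_registry(deck)
  psa_family <- function(nm) {
    sp <- deck$psa[[nm]]
    if (is.null(sp)) "not included" else sp$family
  }
  out <- data.frame(
    parameter = reg$name,
    base = vapply(reg$name, function(nm) get_param(deck, nm), numeric(1)),
    low = reg$low,
    high = reg$high,
    distribution = vapply(reg$name, psa_family, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

## ---- scalar parameter registry --------------------------------------------

# Scalar inputs addressable by name in one-way sweeps, threshold searches and
# the PSA. Ranges follow the one-way sensitivity ranges of the input table.
param_registry <- function(deck = NULL) {
  ranges <- list(
    cta_sens  = c(0.8, 1.0), cta_spec = c(0.8, 1.0),
    ncct_sens = c(0.7, 1.0), ncct_spec = c(0.0, 0.6),
    lesion_prevalence = c(0.0, 0.7),
    rebleed_primary = c(0.0, 0.06),
    rebleed_secondary_untreated = c(0.0, 0.10),
    rr_after_repair = c(0.0, 2.0),
    cost_cta = c(100, 1500), cost_dsa = c(450, 2000),
    hosp_secondary = c(10000, 300000), hosp_primary = c(3000, 120000),
    ltc_mrs23 = c(0, 20000), ltc_mrs45_year1 = c(30000, 150000),
    ltc_mrs45_later = c(10000, 90000),
    u_mrs01 = c(0.2, 1.0), u_mrs23 = c(0.0, 1.0), u_mrs45 = c(-0.1, 1.0),
    initial_age = c(10, 80),
    discount_rate = c(0.0, 0.08)
  )
  data.frame(
    name = names(ranges),
    low = vapply(ranges, `[`, numeric(1), 1),
    high = vapply(ranges, `[`, numeric(1), 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

param_path <- function(name) {
  switch(name,
    cta_sens = c("tests", "cta", "sens"),
    cta_spec = c("tests", "cta", "spec"),
    ncct_sens = c("tests", "ncct", "sens"),
    ncct_spec = c("tests", "ncct", "spec"),
    lesion_prevalence = c("epi", "lesion_prevalence"),
    rebleed_primary = c("epi", "rebleed_primary"),
    rebleed_secondary_untreated = c("epi", "rebleed_secondary_untreated"),
    rr_after_repair = c("epi", "rr_after_repair"),
    cost_cta = c("costs", "cta"),
    cost_dsa = c("costs", "dsa"),
    hosp_secondary = c("costs", "hosp_secondary"),
    hosp_primary = c("costs", "hosp_primary"),
    ltc_mrs23 = c("costs", "ltc_mrs23"),
    ltc_mrs45_year1 = c("costs", "ltc_mrs45_year1"),
    ltc_mrs45_later = c("costs", "ltc_mrs45_later"),
    u_mrs01 = c("utilities", "mrs01"),
    u_mrs23 = c("utilities", "mrs23"),
    u_mrs45 = c("utilities", "mrs45"),
    initial_age = c("settings", "initial_age"),
    discount_rate = c("settings", "discount_rate"),
    stop("unknown parameter '", name, "'; valid names: ",
         paste(param_registry()$name, collapse = ", "), call. = FALSE)
  )
}

#' Get or set a scalar model input by name
#'
#' Addressable names are those of [deck_table()], e.g. `"lesion_prevalence"`,
#' `"rr_after_repair"`, `"u_mrs45"`.
#'
#' @param deck an `ich_deck`.
#' @param name parameter name.
#' @param value replacement value (`set_param`).
#' @return `get_param`: the scalar value. `set_param`: the modified deck
#'   (not revalidated, so sweeps may probe the full one-way range).
#' @export
get_param <- function(deck, name) {
  p <- param_path(name)
  v <- deck
  for (k in p) v <- v[[k]]
  as.numeric(v)
}

#' @rdname get_param
#' @export
set_param <- function(deck, name, value) {
  p <- param_path(name)
  expr <- Reduce(function(acc, k) call("[[", acc, k), p, quote(deck))
  eval(call("<-", expr, value))
  deck
}
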