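## File-based reports: each writes diff-able CSVs plus a run manifest so a
## result directory is self-describing and reproducible.

write_manifest <- function(out_dir, subcommand, deck_path = NA, seed = NA) {
  manifest <- list(
    subcommand = subcommand,
    deck = if (is.na(deck_path)) "builtin default" else deck_path,
    seed = seed,
    out_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("ichscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write the base-case report
#'
#' Runs [ich_cua()] and writes `strategy_results.csv` (per-strategy lifetime
#' discounted cost and QALYs), `comparison.csv` (incremental table vs the
#' comparator), `frontier.csv` and a run manifest to `out_dir`.
#'
#' @param deck an `ich_deck` or a path to a deck YAML file.
#' @param out_dir output directory, created if needed.
#' @param wtp willingness to pay.
#' @return the `ich_cua` fit, invisibly.
#' @export
report_basecase <- function(deck = default_deck(), out_dir, wtp = NULL) {
  deck_path <- NA
  if (is.character(deck)) {
    deck_path <- deck
    deck <- read_deck(deck)
  }
  if (is.null(wtp)) wtp <- deck$settings$wtp
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- ich_cua(deck, wtp = wtp)
  utils::write.csv(fit$results, file.path(out_dir, "strategy_results.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  utils::write.csv(fit$frontier, file.path(out_dir, "frontier.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "basecase", deck_path)
  invisible(fit)
}

#' Write the prevalence-regime report
#'
#' Sweeps lesion prevalence (1-60% by default) at the deck's cohort age and
#' writes the per-prevalence classification of every strategy against the
#' stratified-DSA comparator (`prevalence_sweep.csv`) plus a compressed
#' regime table (`regimes.csv`) in which contiguous prevalences sharing a
#' classification pattern collapse to one row.
#'
#' @param deck an `ich_deck` or a path to a deck YAML file.
#' @param out_dir output directory, created if needed.
#' @param prevalences sweep grid (nonempty, each in \[0,1\]).
#' @param wtp willingness to pay.
#' @return the sweep data.frame, invisibly.
#' @export
report_table2 <- function(deck = default_deck(), out_dir,
                          prevalences = seq(0.01, 0.60, by = 0.01),
                          wtp = NULL) {
  deck_path <- NA
  if (is.character(deck)) {
    deck_path <- deck
    deck <- read_deck(deck)
  }
  if (!length(prevalences) || any(prevalences < 0 | prevalences > 1))
    stop("prevalences must be a nonempty grid of probabilities", call. = FALSE)
  if (is.null(wtp)) wtp <- deck$settings$wtp
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sweep <- prevalence_sweep(deck, prevalences, wtp)
  utils::write.csv(sweep, file.path(out_dir, "prevalence_sweep.csv"),
                   row.names = FALSE)
  pattern <- paste(sweep$cls_cta_all, sweep$cls_cta_strat, sweep$cls_dsa_all,
                   sweep$optimal, sep = "|")
  run_id <- cumsum(c(TRUE, pattern[-1] != pattern[-length(pattern)]))
  regimes <- do.call(rbind, lapply(split(sweep, run_id), function(g) {
    data.frame(prevalence_lo = min(g$prevalence),
               prevalence_hi = max(g$prevalence),
               cls_cta_all = g$cls_cta_all[1],
               cls_cta_strat = g$cls_cta_strat[1],
               cls_dsa_all = g$cls_dsa_all[1],
               optimal = g$optimal[1],
               stringsAsFactors = FALSE)
  }))
  rownames(regimes) <- NULL
  utils::write.csv(regimes, file.path(out_dir, "regimes.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "table2", deck_path)
  invisible(sweep)
}

#' Write the PSA report
#'
#' Runs [run_psa()] and writes the per-draw sample table and the CEAC to
#' CSV, plus a run manifest.
#'
#' @param deck an `ich_deck` or a path to a deck YAML file.
#' @param out_dir output directory, created if needed.
#' @param n number of draws.
#' @param seed integer seed.
#' @return the `ich_psa`, invisibly.
#' @export
report_psa <- function(deck = default_deck(), out_dir, n = 1000, seed = 1) {
  deck_path <- NA
  if (is.character(deck)) {
    deck_path <- deck
    deck <- read_deck(deck)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(deck, n = n, seed = seed)
  utils::write.csv(psa$samples, file.path(out_dir, "psa_samples.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "psa", deck_path, seed)
  invisible(psa)
}
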