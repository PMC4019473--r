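#' Strategy labels
#'
#' The four imaging strategies at the decision node: CTA for the whole
#' cohort, CTA restricted to high/indeterminate NCCT, DSA for the whole
#' cohort, DSA restricted to high/indeterminate NCCT. The stratified-DSA arm
#' is the comparator throughout.
#'
#' @return character vector of the four strategy names.
#' @export
strategies <- function() {
  c("CTA_ALL", "CTA_STRATIFIED", "DSA_ALL", "DSA_STRATIFIED")
}

#' Post-test probability of a vascular lesion (Bayes revision)
#'
#' Revises the pre-test lesion probability with the sensitivity and
#' specificity of an imaging test.
#'
#' @param prevalence pre-test probability of a lesion.
#' @param perf list with `sens` and `spec`.
#' @param result `"positive"` or `"negative"`.
#' @return the post-test probability `P(lesion | result)`.
#' @examples
#' bayes_posttest(0.45, list(sens = 0.95, spec = 0.35), "positive")
#' @export
bayes_posttest <- function(prevalence, perf, result = c("positive", "negative")) {
  result <- match.arg(result)
  check_prob(prevalence, "prevalence")
  se <- perf$sens
  sp <- perf$spec
  num <- if (result == "positive") prevalence * se else prevalence * (1 - se)
  den <- if (result == "positive")
    prevalence * se + (1 - prevalence) * (1 - sp)
  else
    prevalence * (1 - se) + (1 - prevalence) * sp
  if (den == 0)
    stop("impossible observation: P(", result, " result) = 0", call. = FALSE)
  num / den
}

#' Enumerate the diagnostic pathways of a strategy
#'
#' Splits the cohort into joint-probability pathways — true/false positives
#' and negatives of the confirmatory test, plus the unimaged low-risk NCCT
#' groups under stratified strategies — and assigns each its upfront imaging
#' cost, hospitalization cost, index-bleed mRS outcome source and downstream
#' lesion status.
#'
#' Cost and outcome assignments:
#' * true positive: secondary-ICH hospitalization; lesion treated;
#'   secondary-ICH mRS.
#' * false negative / unimaged lesion: primary-ICH ("missed lesion")
#'   hospitalization; lesion untreated; mRS source set by
#'   `settings$missed_lesion_mrs` (etiology-based secondary by default).
#' * false positive: secondary-ICH hospitalization (an unnecessary
#'   intervention occurs) but primary-ICH outcomes and no lesion — an
#'   assumption, since the source does not spell this pathway out.
#' * true negative / unimaged no-lesion: primary-ICH hospitalization,
#'   primary-ICH mRS, no lesion.
#'
#' DSA is modelled as a perfect reference test by default
#' (`deck$tests$dsa`), so DSA arms have no false results. NCCT itself
#' carries no cost (it is common to every branch).
#'
#' @param strategy one of [strategies()].
#' @param deck an `ich_deck`.
#' @return a data.frame with columns `label`, `probability`, `imaging_cost`,
#'   `hosp_cost`, `mrs_source`, `lesion_after`; probabilities sum to 1.
#' @examples
#' enumerate_pathways("CTA_STRATIFIED", default_deck())
#' @export
enumerate_pathways <- function(strategy, deck) {
  strategy <- match.arg(strategy, strategies())
  p <- deck$epi$lesion_prevalence
  conf <- if (startsWith(strategy, "CTA")) deck$tests$cta else deck$tests$dsa
  conf_cost <- if (startsWith(strategy, "CTA")) deck$costs$cta else deck$costs$dsa
  stratified <- endsWith(strategy, "STRATIFIED")
  ncct <- deck$tests$ncct
  missed_mrs <- deck$settings$missed_lesion_mrs

  # mass reaching the confirmatory test, by lesion status
  if (stratified) {
    m_lesion <- p * ncct$sens
    m_nolesion <- (1 - p) * (1 - ncct$spec)
    unimaged_lesion <- p * (1 - ncct$sens)
    unimaged_nolesion <- (1 - p) * ncct$spec
  } else {
    m_lesion <- p
    m_nolesion <- 1 - p
    unimaged_lesion <- unimaged_nolesion <- 0
  }

  row <- function(label, prob, imaging, hosp, mrs, lesion)
    data.frame(label = label, probability = prob, imaging_cost = imaging,
               hosp_cost = hosp, mrs_source = mrs, lesion_after = lesion,
               stringsAsFactors = FALSE)
  cs <- deck$costs
  out <- rbind(
    row("TP", m_lesion * conf$sens, conf_cost, cs$hosp_secondary,
        "secondary", "treated"),
    row("FN", m_lesion * (1 - conf$sens), conf_cost, cs$hosp_primary,
        missed_mrs, "untreated"),
    row("TN", m_nolesion * conf$spec, conf_cost, cs$hosp_primary,
        "primary", "none"),
    row("FP", m_nolesion * (1 - conf$spec), conf_cost, cs$hosp_secondary,
        "primary", "none"),
    row("UNIMAGED_LESION", unimaged_lesion, 0, cs$hosp_primary,
        missed_mrs, "untreated"),
    row("UNIMAGED_NO_LESION", unimaged_nolesion, 0, cs$hosp_primary,
        "primary", "none")
  )
  out <- out[out$probability > 0 | out$label %in% c("TP", "TN"), ]
  stopifnot(abs(sum(out$probability) - 1) < 1e-9)
  rownames(out) <- NULL
  out
}

#' Expected upfront imaging cost of a strategy
#'
#' Probability-weighted cost of the angiographic test; under stratified
#' strategies only the NCCT high/indeterminate fraction is imaged.
#'
#' @inheritParams enumerate_pathways
#' @return expected imaging cost per cohort member, USD.
#' @export
expected_upfront_cost <- function(strategy, deck) {
  pw <- enumerate_pathways(strategy, deck)
  sum(pw$probability * pw$imaging_cost)
}

#' Write the pathway table of every strategy to CSV
#'
#' @param deck an `ich_deck`.
#' @param path destination CSV file.
#' @return the combined pathway table, invisibly.
#' @export
write_pathway_table <- function(deck, path) {
  tabs <- lapply(strategies(), function(s) {
    cbind(strategy = s, enumerate_pathways(s, deck))
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
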