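#' Estimate antigen-specific T-cell frequencies for one sample
#'
#' Apportions the sample's multimer-positive percentage of CD8+ T cells
#' among its enriched barcodes, proportionally to their clonally reduced
#' read counts: `est_freq_pct(b) = multimer_pct * count(b) / sum(counts over
#' enriched barcodes)`. The estimated frequencies of the enriched barcodes
#' therefore sum exactly to the sample's multimer-positive percentage. When
#' the sample has no exported flow data (`multimer_pct` is `NA`) frequencies
#' are `NA` and the sample is marked frequency-incomplete; detection-level
#' summaries are still computable.
#'
#' @param records Per-barcode records for one sample with columns
#'   `enriched` and `read_fraction_pct` (or raw `count`).
#' @param multimer_pct Percent of CD8+ cells that are multimer-positive
#'   (0-100) or `NA`.
#' @return `records` with `est_freq_pct` added (NA for non-enriched
#'   barcodes) and attribute `frequency_incomplete`.
#' @export
estimate_frequencies <- function(records, multimer_pct) {
  stopifnot(is.na(multimer_pct) ||
              (multimer_pct >= 0 && multimer_pct <= 100))
  share_col <- if ("count" %in% names(records)) {
    records$count
  } else {
    records$read_fraction_pct
  }
  est <- rep(NA_real_, nrow(records))
  enr <- which(records$enriched)
  if (length(enr) > 0 && !is.na(multimer_pct)) {
    tot <- sum(share_col[enr])
    est[enr] <- if (tot > 0) {
      multimer_pct * share_col[enr] / tot
    } else 0
  }
  records$est_freq_pct <- est
  attr(records, "frequency_incomplete") <- is.na(multimer_pct)
  records
}

#' Call biologically relevant antigen-specific T-cell populations
#'
#' Converts enriched, frequency-annotated barcodes into NART / virus-specific
#' T-cell calls, applying the two relevance filters: an estimated frequency
#' of at least `min_freq_pct` percent of CD8+ T cells (inclusive), and
#' absence of the specificity from partially HLA-matching healthy-donor
#' screens. Calls with an indeterminate frequency (missing flow data) pass
#' the frequency filter and are flagged `freq_indeterminate`; they count
#' toward diversity but not toward summed frequency.
#'
#' @param records Output of [estimate_frequencies()] annotated with
#'   `peptide`, `hla`, `category`, `mutation_id` (e.g. merged from the
#'   panel).
#' @param donor_blacklist Data frame of specificities seen in healthy donors
#'   (`peptide`, `hla`) or character vector of `peptide|hla` keys.
#' @param min_freq_pct Minimum estimated frequency in percent (default
#'   0.01, inclusive).
#' @return Data frame of calls (enriched barcodes only) with
#'   `passed_frequency_filter`, `passed_donor_filter`, `freq_indeterminate`
#'   and `passes` (both filters).
#' @export
call_narts <- function(records, donor_blacklist = NULL,
                       min_freq_pct = 0.01) {
  calls <- records[which(records$enriched), , drop = FALSE]
  if (nrow(calls) == 0) {
    calls$passed_frequency_filter <- logical(0)
    calls$passed_donor_filter <- logical(0)
    calls$freq_indeterminate <- logical(0)
    calls$passes <- logical(0)
    return(calls)
  }
  calls$freq_indeterminate <- is.na(calls$est_freq_pct)
  calls$passed_frequency_filter <- calls$freq_indeterminate |
    calls$est_freq_pct >= min_freq_pct
  black <- blacklist_keys(donor_blacklist)
  calls$passed_donor_filter <- !(spec_key(calls) %in% black)
  calls$passes <- calls$passed_frequency_filter & calls$passed_donor_filter
  rownames(calls) <- NULL
  calls
}

spec_key <- function(records) paste(records$peptide, records$hla, sep = "|")

blacklist_keys <- function(donor_blacklist) {
  if (is.null(donor_blacklist)) return(character(0))
  if (is.character(donor_blacklist)) return(donor_blacklist)
  paste(donor_blacklist$peptide, donor_blacklist$hla, sep = "|")
}

#' Normalize a per-patient value to the cohort's mean HLA coverage
#'
#' Panels cover different numbers of HLA alleles (producibility varies), so
#' NART diversity and summed frequency are rescaled by
#' `cohort_mean_coverage / patient_coverage` before cohort comparisons. The
#' rescaling is linear and applied identically to counts and to summed
#' frequencies.
#'
#' @param value Numeric value(s) to normalize.
#' @param patient_coverage Number of HLA alleles covered by this panel
#'   (>= 1).
#' @param cohort_mean_coverage Mean coverage across all panels (> 0).
#' @return Normalized value(s).
#' @export
hla_normalize <- function(value, patient_coverage, cohort_mean_coverage) {
  if (any(patient_coverage < 1)) stop("patient HLA coverage must be >= 1")
  stopifnot(cohort_mean_coverage > 0)
  value * cohort_mean_coverage / patient_coverage
}

#' Summarize NART calls for one sample
#'
#' Diversity counts neo-category calls passing both relevance filters;
#' summed frequency pools their estimated frequencies (calls with
#' indeterminate frequency contribute to diversity only). Virus-specific
#' calls are tallied separately and never enter NART summaries or HLA
#' normalization.
#'
#' @param calls Calls for one sample from [call_narts()].
#' @param hla_coverage The patient panel's HLA coverage.
#' @param cohort_mean_coverage Cohort mean coverage (default 4.4).
#' @return One-row data frame: `diversity_raw`, `sum_freq_raw`,
#'   `diversity_norm`, `sum_freq_norm`, `diversity_virus`, `hla_coverage`.
#' @export
sample_summary <- function(calls, hla_coverage, cohort_mean_coverage = 4.4) {
  neo <- calls[calls$category == "neo" & calls$passes, , drop = FALSE]
  virus <- calls[calls$category == "virus" & calls$passes, , drop = FALSE]
  diversity <- nrow(neo)
  sum_freq <- sum(neo$est_freq_pct, na.rm = TRUE)
  data.frame(
    diversity_raw = diversity,
    sum_freq_raw = sum_freq,
    diversity_norm = hla_normalize(diversity, hla_coverage,
                                   cohort_mean_coverage),
    sum_freq_norm = hla_normalize(sum_freq, hla_coverage,
                                  cohort_mean_coverage),
    diversity_virus = nrow(virus),
    hla_coverage = hla_coverage
  )
}
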