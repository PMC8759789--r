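#' Canonical longitudinal time points
#'
#' The ordered sampling time points around adoptive cell therapy: PBMCs
#' taken shortly before infusion (`preACT`), the infusion product itself
#' (`TIL`), and PBMC bins up to <1, <4, <12, <24 and <48 months after
#' infusion.
#'
#' @return Character vector of time point labels in temporal order.
#' @export
timepoint_levels <- function() {
  c("preACT", "TIL", "post1", "post4", "post12", "post24", "post48")
}

post_timepoints <- function() setdiff(timepoint_levels(),
                                      c("preACT", "TIL"))

#' Build detection timelines from per-sample calls
#'
#' For each patient x specificity, records at every time point whether a
#' sample was available and whether the population was detected there
#' (detection = a call passing both relevance filters in that sample), plus
#' the estimated frequency. A time point with no sample is unknown, never
#' absent.
#'
#' @param calls Stacked call tables from [call_narts()] across samples, with
#'   `sample_id` columns.
#' @param manifest Sample manifest with `sample_id`, `patient_id`,
#'   `timepoint`.
#' @return Data frame with one row per patient x specificity x available
#'   time point: `patient_id`, `peptide`, `hla`, `category`, `mutation_id`,
#'   `timepoint`, `available`, `detected`, `est_freq_pct`.
#' @export
build_timelines <- function(calls, manifest) {
  tp <- timepoint_levels()
  manifest <- manifest[!is.na(manifest$timepoint), , drop = FALSE]
  stopifnot(all(manifest$timepoint %in% tp))
  calls <- calls[, setdiff(names(calls), c("patient_id", "timepoint")),
                 drop = FALSE]
  calls <- merge(calls, manifest[, c("sample_id", "patient_id", "timepoint")],
                 by = "sample_id", sort = FALSE)
  detected <- calls[calls$passes, , drop = FALSE]

  specs <- unique(detected[, c("patient_id", "peptide", "hla", "category",
                               "mutation_id")])
  if (nrow(specs) == 0) {
    return(data.frame(patient_id = character(), peptide = character(),
                      hla = character(), category = character(),
                      mutation_id = character(), timepoint = character(),
                      available = logical(), detected = logical(),
                      est_freq_pct = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    avail_tp <- manifest$timepoint[manifest$patient_id == s$patient_id]
    rows <- data.frame(s, timepoint = tp, available = tp %in% avail_tp,
                       row.names = NULL, stringsAsFactors = FALSE)
    hit <- detected[detected$patient_id == s$patient_id &
                      spec_key(detected) == spec_key(s), , drop = FALSE]
    m <- match(rows$timepoint, hit$timepoint)
    rows$detected <- rows$available & !is.na(m)
    rows$est_freq_pct <- ifelse(rows$detected, hit$est_freq_pct[m], NA_real_)
    rows
  }))
  out$timepoint <- factor(out$timepoint, levels = tp, ordered = TRUE)
  rownames(out) <- NULL
  out
}

#' Classify a population's origin by its first appearance
#'
#' Categories, determined solely by where the population is first (and, for
#' the pre-ACT cases, subsequently) detected:
#' * `pre_TIL` - detected both in pre-ACT PBMCs and in the infusion product;
#' * `preACT_only` - detected in pre-ACT PBMCs but never in the infusion
#'   product;
#' * `TIL` - first detected in the infusion product;
#' * `novel_<tp>` - first detected at post-infusion time point `<tp>`.
#'
#' @param detected Named logical vector over [timepoint_levels()] (missing
#'   names treated as not detected).
#' @return The category string, or `NA` if nothing was detected.
#' @export
annotate_origin <- function(detected) {
  d <- detection_vector(detected)
  if (!any(d)) return(NA_character_)
  if (d[["preACT"]]) {
    if (d[["TIL"]]) return("pre_TIL")
    return("preACT_only")
  }
  if (d[["TIL"]]) return("TIL")
  first <- names(d)[which(d)[1]]
  paste0("novel_", first)
}

detection_vector <- function(detected) {
  tp <- timepoint_levels()
  d <- stats::setNames(rep(FALSE, length(tp)), tp)
  if (is.null(names(detected))) {
    stopifnot(length(detected) == length(tp))
    names(detected) <- tp
  }
  d[names(detected)] <- as.logical(detected)
  d
}

#' Engraftment and persistence flags
#'
#' A population is engrafted when it is detected both in the infusion
#' product and in at least one post-infusion PBMC sample; it is persisting
#' when it is detected in at least two post-infusion PBMC samples (not
#' necessarily consecutive). Undetected time points without a sample carry
#' no evidence either way; only observed detections count.
#'
#' @param detected Named logical vector over [timepoint_levels()].
#' @return Logical vector `c(engrafted, persisting)`, named.
#' @export
engraftment_flags <- function(detected) {
  d <- detection_vector(detected)
  n_post <- sum(d[post_timepoints()])
  c(engrafted = unname(d[["TIL"]] && n_post >= 1),
    persisting = unname(n_post >= 2))
}

#' Annotate all timelines with origin/engraftment/persistence
#'
#' @param timelines Output of [build_timelines()].
#' @return One row per patient x specificity: identifiers plus `category_origin`,
#'   `engrafted`, `persisting`, `n_post_detections`, `max_freq_pct`.
#' @export
annotate_timelines <- function(timelines) {
  key <- paste(timelines$patient_id, spec_key(timelines), sep = "@")
  out <- do.call(rbind, lapply(split(timelines, key), function(tl) {
    det <- stats::setNames(tl$detected, as.character(tl$timepoint))
    flags <- engraftment_flags(det)
    data.frame(tl[1, c("patient_id", "peptide", "hla", "category",
                       "mutation_id")],
               category_origin = annotate_origin(det),
               engrafted = flags[["engrafted"]],
               persisting = flags[["persisting"]],
               n_post_detections = sum(tl$detected[
                 as.character(tl$timepoint) %in% post_timepoints()]),
               max_freq_pct = if (all(is.na(tl$est_freq_pct))) NA_real_
                              else max(tl$est_freq_pct, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Collapse epitope-level calls to mutation level
#'
#' Overlapping peptides from the same somatic mutation can be recognized by
#' cross-reactive T cells; to avoid counting them as independent responses,
#' calls are collapsed to one record per `mutation_id`, using the most
#' frequent epitope as the representative (proxy) for recognition of that
#' mutation. When all of a mutation's epitopes lack frequencies the
#' representative is chosen by detection only and keeps an `NA` frequency.
#'
#' @param calls Call table for one sample (rows with `mutation_id` and
#'   `est_freq_pct`).
#' @return One row per distinct mutation, representative frequency in
#'   `est_freq_pct`.
#' @export
collapse_mutations <- function(calls) {
  stopifnot("mutation_id" %in% names(calls))
  out <- do.call(rbind, lapply(split(calls, calls$mutation_id), function(g) {
    i <- if (all(is.na(g$est_freq_pct))) 1L else which.max(g$est_freq_pct)
    g[i, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Per-time-point diversity and summed frequency for one patient
#'
#' Tallies, at each time point with an available sample, the number of
#' detected neo-specific populations and their summed estimated frequency,
#' HLA-normalized. Time points without a sample yield `NA` (absent), not
#' zero.
#'
#' @param timelines Timelines for one patient ([build_timelines()] rows).
#' @param hla_coverage Patient panel coverage.
#' @param cohort_mean_coverage Cohort mean coverage (default 4.4).
#' @return Data frame with one row per time point: `timepoint`, `available`,
#'   `diversity`, `sum_freq`, `diversity_norm`, `sum_freq_norm`.
#' @export
timecourse_summary <- function(timelines, hla_coverage,
                               cohort_mean_coverage = 4.4) {
  stopifnot(length(unique(timelines$patient_id)) <= 1)
  tp <- timepoint_levels()
  out <- do.call(rbind, lapply(tp, function(t) {
    tl <- timelines[as.character(timelines$timepoint) == t &
                      timelines$category == "neo", , drop = FALSE]
    avail <- any(tl$available)
    if (!avail) {
      return(data.frame(timepoint = t, available = FALSE,
                        diversity = NA_real_, sum_freq = NA_real_))
    }
    data.frame(timepoint = t, available = TRUE,
               diversity = sum(tl$detected),
               sum_freq = sum(tl$est_freq_pct[tl$detected], na.rm = TRUE))
  }))
  out$diversity_norm <- hla_normalize(out$diversity, hla_coverage,
                                      cohort_mean_coverage)
  out$sum_freq_norm <- hla_normalize(out$sum_freq, hla_coverage,
                                     cohort_mean_coverage)
  out$timepoint <- factor(out$timepoint, levels = tp, ordered = TRUE)
  rownames(out) <- NULL
  out
}
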