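#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors for a set of samples in
#' one comparison (a sorted sample plus its baseline triplicate, or any
#' count-matrix subset). For each sample the factor is the weighted trimmed
#' mean of per-barcode log2 ratios (M values) against a reference sample,
#' trimming the most extreme 30% of M values on each side and the most
#' extreme 5% of average log intensities (A values) on each side, with
#' inverse asymptotic (binomial) variance weights. Barcodes with zero count
#' in either sample are excluded. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean upper-quartile
#' fraction. Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Non-negative count matrix, barcodes x samples (>= 2
#'   columns, each with a positive total).
#' @param logratio_trim,abundance_trim Two-sided trim fractions for M and A
#'   values (defaults 0.3 and 0.05).
#' @return Numeric vector of per-sample factors (product 1), named by
#'   column.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive total count")

  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75) )/ lib
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    tmm_pair_factor(counts[, i], counts[, ref], lib[i], lib[ref],
                    logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One-sample-vs-reference weighted trimmed mean of M values (log2 scale).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) {
    warning("sample shares no positive barcode with the reference; factor 1")
    return(1)
  }
  o <- obs[pos]; r <- ref[pos]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Estimate a common negative-binomial dispersion from baseline replicates
#'
#' Method-of-moments estimate pooled over barcodes: counts are put on a
#' common effective library size, per-barcode replicate means and variances
#' are computed, and the common dispersion is the pooled ratio
#' `sum(variance - mean) / sum(mean^2)` over barcodes with positive mean,
#' floored at zero (Poisson limit).
#'
#' @param baseline Count matrix of baseline replicates (>= 2 columns).
#' @param factors TMM factors for these columns (default all 1).
#' @return A single non-negative dispersion value.
#' @export
estimate_dispersion <- function(baseline, factors = NULL) {
  baseline <- as.matrix(baseline)
  stopifnot(ncol(baseline) >= 2)
  if (is.null(factors)) factors <- rep(1, ncol(baseline))
  eff <- colSums(baseline) * factors
  common <- exp(mean(log(eff)))
  z <- sweep(baseline, 2, common / eff, "*")
  m <- rowMeans(z)
  v <- apply(z, 1, stats::var)
  pos <- m > 0
  if (!any(pos)) return(0)
  max(0, sum(v[pos] - m[pos]) / sum(m[pos]^2))
}

#' Per-barcode enrichment test of a sorted sample against baselines
#'
#' Tests each barcode for enrichment in one sorted sample relative to the
#' mean of the baseline replicates, using a negative-binomial exact test on
#' counts equalized to a common effective library size, with a common
#' dispersion estimated from the baseline replicate variability (see
#' [estimate_dispersion()]). Fold changes are moderated with a prior count
#' of 0.5 added to the equalized sample count and to the normalized mean
#' baseline. One-sided enrichment p-values are doubled and capped at 1.
#'
#' The exact test conditions on the equalized sample + pooled-baseline total
#' per barcode; the conditional distribution of the sample share is
#' beta-negative-binomial with size parameters `1/dispersion` and
#' `n_replicates/dispersion`, reducing to a binomial split in the Poisson
#' (zero-dispersion) limit. Barcodes at zero across all columns get
#' `log2fc = 0`, `pvalue = 1`.
#'
#' @param sample_counts Integer vector of the sorted sample's counts.
#' @param baseline Count matrix of baseline replicates (same barcodes,
#'   >= 2 columns).
#' @param factors Optional TMM factors for `cbind(sample, baseline)`;
#'   computed with [tmm_factors()] when `NULL`.
#' @param dispersion Common NB dispersion; estimated from the baselines
#'   when `NULL`.
#' @param prior_count Fold-change prior (default 0.5).
#' @param effective_size Common effective library size the counts are
#'   equalized to; default the geometric mean of the effective sizes.
#'   Supplying a fixed value makes the test invariant to a global rescaling
#'   of all columns.
#' @return Data frame: `barcode_id`, `log2fc`, `pvalue`,
#'   `read_fraction_pct` (share of the sample's total clonally reduced
#'   counts, in percent).
#' @export
enrichment_test <- function(sample_counts, baseline, factors = NULL,
                            dispersion = NULL, prior_count = 0.5,
                            effective_size = NULL) {
  baseline <- as.matrix(baseline)
  stopifnot(ncol(baseline) >= 2,
            length(sample_counts) == nrow(baseline))
  counts <- cbind(sample = sample_counts, baseline)
  if (is.null(factors)) factors <- tmm_factors(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(baseline, factors[-1])
  }
  n_rep <- ncol(baseline)
  eff <- colSums(counts) * factors
  if (is.null(effective_size)) effective_size <- exp(mean(log(eff)))

  pseudo <- sweep(counts, 2, effective_size / eff, "*")
  y1 <- round(pseudo[, 1])
  y2 <- round(rowSums(pseudo[, -1, drop = FALSE]))

  base_mean <- rowMeans(pseudo[, -1, drop = FALSE])
  log2fc <- log2((pseudo[, 1] + prior_count) / (base_mean + prior_count))

  pvalue <- vapply(seq_along(y1), function(i) {
    exact_split_pvalue(y1[i], y2[i], n_rep, dispersion)
  }, numeric(1))

  zero <- rowSums(counts) == 0
  log2fc[zero] <- 0
  pvalue[zero] <- 1

  total <- sum(sample_counts)
  frac <- if (total > 0) 100 * sample_counts / total else rep(0, length(y1))
  data.frame(barcode_id = rownames(counts) %||% as.character(seq_along(y1)),
             log2fc = log2fc, pvalue = pvalue, read_fraction_pct = frac,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Doubled upper-tail p for observing y1 of t = y1 + y2 in the sample slot,
# when sample ~ NB(size r1) and pooled baseline ~ NB(size n_rep * r1) at
# equal per-replicate effective size. dispersion == 0 is the Poisson limit
# (binomial split with probability 1 / (1 + n_rep)).
exact_split_pvalue <- function(y1, y2, n_rep, dispersion) {
  t <- y1 + y2
  if (t == 0) return(1)
  k <- seq.int(y1, t)
  if (dispersion <= 1e-12) {
    p_up <- sum(stats::dbinom(k, t, 1 / (1 + n_rep)))
  } else {
    r1 <- 1 / dispersion
    r2 <- n_rep / dispersion
    logf <- lgamma(k + r1) - lgamma(r1) - lgamma(k + 1) +
      lgamma(t - k + r2) - lgamma(r2) - lgamma(t - k + 1)
    all_k <- seq.int(0, t)
    logall <- lgamma(all_k + r1) - lgamma(r1) - lgamma(all_k + 1) +
      lgamma(t - all_k + r2) - lgamma(r2) - lgamma(t - all_k + 1)
    mx <- max(logall)
    p_up <- sum(exp(logf - mx)) / sum(exp(logall - mx))
  }
  min(1, 2 * p_up)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wrapper over
#' [stats::p.adjust()]); monotone in the sorted order and capped at 1.
#'
#' @param pvalues Numeric vector in \[0, 1\]; an empty vector returns an
#'   empty vector.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  if (length(pvalues) == 0) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Flag significantly enriched barcodes
#'
#' A barcode is enriched when its BH-adjusted p-value is strictly below
#' `alpha_adj`, its share of the sample's clonally reduced reads is at least
#' `min_read_fraction_pct` percent (signals below this arise from
#' insufficient read depth), and its fold change is positive.
#'
#' @param records Data frame from [enrichment_test()], with `p_adj` added
#'   here if absent.
#' @param alpha_adj Adjusted-p threshold, strict (default 0.001).
#' @param min_read_fraction_pct Minimum percent read fraction, inclusive
#'   (default 0.1).
#' @return `records` with columns `p_adj` and logical `enriched`.
#' @export
call_enriched <- function(records, alpha_adj = 0.001,
                          min_read_fraction_pct = 0.1) {
  if (!"p_adj" %in% names(records)) {
    records$p_adj <- bh_adjust(records$pvalue)
  }
  records$enriched <- records$p_adj < alpha_adj &
    records$read_fraction_pct >= min_read_fraction_pct &
    records$log2fc > 0
  records
}

#' Run the enrichment analysis for every sorted sample in a count matrix
#'
#' For each non-baseline sample, normalizes the sample together with its
#' baseline replicate group (manifest column `baseline_group`, matched
#' against baseline samples' `sample_id` group membership), runs the exact
#' test, adjusts p-values per sample, and flags enriched barcodes.
#'
#' @param counts Count matrix from [build_count_table()] (manifest attached)
#'   or a plain matrix plus an explicit `manifest`.
#' @param manifest Optional manifest overriding the attached one.
#' @param ... Passed to [call_enriched()].
#' @return Data frame of per-barcode records across all sorted samples, with
#'   a `sample_id` column.
#' @export
screen_enrichment <- function(counts, manifest = NULL, ...) {
  manifest <- manifest %||% attr(counts, "manifest")
  if (is.null(manifest)) stop("a sample manifest is required")
  is_base <- manifest$sample_type == "baseline"
  if (!"baseline_group" %in% names(manifest)) {
    manifest$baseline_group <- manifest$patient_id %||%
      rep("all", nrow(manifest))
  }
  out <- lapply(which(!is_base), function(i) {
    grp <- manifest$baseline_group[i]
    base_ids <- manifest$sample_id[is_base & manifest$baseline_group == grp]
    if (length(base_ids) < 2) {
      stop("sample ", manifest$sample_id[i],
           " has fewer than 2 baseline replicates")
    }
    res <- enrichment_test(counts[, manifest$sample_id[i]],
                           counts[, base_ids, drop = FALSE])
    res$p_adj <- bh_adjust(res$pvalue)
    res <- call_enriched(res, ...)
    res$sample_id <- manifest$sample_id[i]
    res
  })
  do.call(rbind, out)
}
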