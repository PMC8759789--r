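#' Configuration for the synthetic screen generator
#'
#' Bundles every tunable of the synthetic cohort. Parameter distributions
#' mirror the assay being emulated: patient panels of 151-585 neopeptides
#' over 2-6 HLA alleles, a small immunogenic fraction with true T-cell
#' frequencies log-uniform between 0.01% and 40% of CD8+ cells, triplicate
#' baseline samples of the multimer reagent pool, 25-mer AxBy barcodes with
#' a 6-nt UMI, PCR duplication and substitution sequencing errors, a
#' geometric per-time-point frequency decay after infusion, and an
#' exponential survival model whose hazard differs between NART-high and
#' NART-low patients.
#'
#' @param seed Integer seed; the same seed reproduces every output byte.
#' @param n_patients Number of patients (>= 1).
#' @param library_size_range Range the per-patient neopeptide library size
#'   is drawn from (default 151-585).
#' @param hla_range Range of covered HLA alleles per panel (default 2-6).
#' @param frac_immunogenic Fraction of library peptides with a true
#'   T-cell response (default 0.02).
#' @param freq_range_pct Log-uniform range of true frequencies, percent of
#'   CD8+ cells (default 0.01-40).
#' @param read_depth Sequenced reads per sample before clonal reduction is
#'   applied to molecules; molecules per sample = depth / umi_dup_rate.
#' @param umi_dup_rate Mean PCR duplicates per molecule (default 3).
#' @param error_rate Per-base substitution error probability (default 1e-3).
#' @param baseline_dispersion Negative-binomial dispersion of baseline
#'   replicate counts (default 0.05).
#' @param baseline_lognormal_sd Log-normal sd of per-barcode reagent-pool
#'   abundances (default 0.5).
#' @param decay Geometric per-time-point frequency multiplier after
#'   infusion (default 0.5) with per-clone jitter.
#' @param detect_floor_pct Frequencies decaying below this are absent from
#'   later samples (default 0.005).
#' @param background_pct Multimer-positive background (nonspecific binding)
#'   in percent; also the floor of the reported multimer percentage
#'   (default 0.2).
#' @param gating_noise_pct Gaussian sd of the reported multimer percentage
#'   (default 0.05).
#' @param n_virus Virus-control epitopes per panel (default 10).
#' @param virus_detect_prob Probability a virus control has a responding
#'   population (default 0.4).
#' @param preact_detect_prob Probability an immunogenic clone is already
#'   circulating before infusion (default 0.4).
#' @param preact_scale Frequency multiplier for pre-infusion detections
#'   (default 0.1).
#' @param novel_mean Mean number of novel post-infusion populations per
#'   patient (Poisson, default 1.5).
#' @param novel_freq_range_pct Log-uniform frequency range of novel
#'   populations (default 0.02-0.5).
#' @param post_availability Probability each PBMC time point has a sample
#'   (default 0.85; the infusion product is always available).
#' @param timepoints Time points simulated (subset of
#'   [timepoint_levels()]).
#' @param donor_detect_frac Fraction of specificities also detectable in
#'   partially HLA-matching healthy donors (default 0.05).
#' @param true_hr Hazard ratio of NART-low vs NART-high patients
#'   (default 2.5).
#' @param base_rate Exponential event rate of the NART-high group per month
#'   (default log(2)/6).
#' @param censor_rate Exponential censoring rate per month (default 0.04).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_patients = 6L,
                       library_size_range = c(151L, 585L),
                       hla_range = c(2L, 6L),
                       frac_immunogenic = 0.02,
                       freq_range_pct = c(0.01, 40),
                       read_depth = 30000L,
                       umi_dup_rate = 3,
                       error_rate = 0.001,
                       baseline_dispersion = 0.05,
                       baseline_lognormal_sd = 0.5,
                       decay = 0.5,
                       detect_floor_pct = 0.005,
                       background_pct = 0.2,
                       gating_noise_pct = 0.05,
                       n_virus = 10L,
                       virus_detect_prob = 0.4,
                       preact_detect_prob = 0.4,
                       preact_scale = 0.1,
                       novel_mean = 1.5,
                       novel_freq_range_pct = c(0.02, 0.5),
                       post_availability = 0.85,
                       timepoints = c("preACT", "TIL", "post1", "post4",
                                      "post12"),
                       donor_detect_frac = 0.05,
                       true_hr = 2.5,
                       base_rate = log(2) / 6,
                       censor_rate = 0.04) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$frac_immunogenic >= 0,
            cfg$frac_immunogenic <= 1, cfg$read_depth >= 0,
            cfg$umi_dup_rate >= 1, all(cfg$timepoints %in% timepoint_levels()),
            "TIL" %in% cfg$timepoints)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Generates, per patient: a prediction table, the selected neopeptide
#' library with an AxBy-barcoded panel (plus virus controls), per-barcode
#' baseline reagent-pool abundances, a longitudinal truth table of true
#' T-cell frequencies at every available time point (pre-infusion
#' detections, infusion-product frequencies, geometric post-infusion decay,
#' and low-frequency novel populations), reported multimer-positive
#' percentages, a sample manifest, a healthy-donor blacklist, and a
#' clinical table simulated from the infusion-product NART burden. The same
#' seed reproduces every value.
#'
#' @param config A [sim_config()].
#' @return List: `config`, `patients` (per-patient list with `panel`,
#'   `predictions`, `baseline_props`, `truth` (barcode x timepoint true
#'   frequency), `manifest` rows), `manifest` (cohort-wide), `truth`
#'   (stacked long truth table), `donor_blacklist`, `clinical`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  tp <- intersect(timepoint_levels(), config$timepoints)
  post_tp <- intersect(tp, post_timepoints())
  patients <- lapply(seq_len(config$n_patients), function(p) {
    pid <- sprintf("P%02d", p)
    lib_size <- sample(config$library_size_range[1]:
                         config$library_size_range[2], 1)
    coverage <- sample(config$hla_range[1]:config$hla_range[2], 1)
    preds <- simulate_predictions(pid, lib_size, coverage)
    lib <- suppressWarnings(select_library(preds, "high_load"))
    panel <- build_panel(lib, pid,
                         virus_epitopes = sprintf("v%02d", seq_len(config$n_virus)),
                         seed = sample.int(2^30, 1))
    nb <- nrow(panel$barcodes)
    baseline_props <- stats::rlnorm(nb, 0, config$baseline_lognormal_sd)
    baseline_props <- baseline_props / sum(baseline_props)
    names(baseline_props) <- panel$barcodes$barcode_id

    truth <- simulate_truth_frequencies(panel, tp, post_tp, config)

    # availability: the infusion product always; each other time point
    # kept with the configured probability
    others <- setdiff(tp, "TIL")
    avail <- intersect(tp, c("TIL", others[
      stats::runif(length(others)) < config$post_availability]))

    multimer <- vapply(avail, function(t) {
      tot <- sum(truth[, t]) + config$background_pct
      max(config$background_pct,
          tot + stats::rnorm(1, 0, config$gating_noise_pct))
    }, numeric(1))

    manifest <- data.frame(
      sample_id = c(paste0(pid, "_base", 1:3), paste0(pid, "_", avail)),
      patient_id = pid,
      sample_type = c(rep("baseline", 3),
                      ifelse(avail == "TIL", "TIL", "PBMC")),
      timepoint = c(rep(NA_character_, 3), avail),
      multimer_pct = c(rep(NA_real_, 3), multimer),
      baseline_group = pid,
      stringsAsFactors = FALSE
    )
    list(patient_id = pid, panel = panel, predictions = preds,
         baseline_props = baseline_props, truth = truth,
         manifest = manifest)
  })
  names(patients) <- vapply(patients, `[[`, character(1), "patient_id")

  manifest <- do.call(rbind, lapply(patients, `[[`, "manifest"))
  rownames(manifest) <- NULL

  truth_long <- do.call(rbind, lapply(patients, function(pt) {
    long <- expand.grid(barcode_id = rownames(pt$truth),
                        timepoint = colnames(pt$truth),
                        stringsAsFactors = FALSE)
    long$true_freq_pct <- as.vector(pt$truth)
    long$patient_id <- pt$patient_id
    m <- match(long$barcode_id, pt$panel$barcodes$barcode_id)
    long$peptide <- pt$panel$barcodes$peptide[m]
    long$hla <- pt$panel$barcodes$hla[m]
    long$category <- pt$panel$barcodes$category[m]
    long$mutation_id <- pt$panel$barcodes$mutation_id[m]
    long
  }))
  rownames(truth_long) <- NULL

  donor_blacklist <- do.call(rbind, lapply(patients, function(pt) {
    bc <- pt$panel$barcodes
    pick <- stats::runif(nrow(bc)) < config$donor_detect_frac
    bc[pick, c("peptide", "hla"), drop = FALSE]
  }))
  rownames(donor_blacklist) <- NULL

  til_sum_freq <- vapply(patients, function(pt) {
    neo <- pt$panel$barcodes$category == "neo"
    sum(pt$truth[neo, "TIL"])
  }, numeric(1))
  clinical <- simulate_survival(til_sum_freq, config)
  clinical$patient_id <- names(patients)
  clinical <- clinical[, c("patient_id",
                           setdiff(names(clinical), "patient_id"))]

  list(config = config, patients = patients, manifest = manifest,
       truth = truth_long, donor_blacklist = donor_blacklist,
       clinical = clinical)
}

# Prediction table with lib_size records passing the high-load thresholds
# plus ~25% rejects, spread over `coverage` HLA alleles.
simulate_predictions <- function(pid, lib_size, coverage) {
  n_reject <- ceiling(lib_size * 0.25)
  n <- lib_size + n_reject
  hla <- sprintf("HLA-%s*%02d:01", sample(c("A", "B", "C"), coverage,
                                          replace = TRUE), seq_len(coverage))
  genes <- sprintf("GENE%s%03d", pid, seq_len(n))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  pep <- vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(8:11, 1), replace = TRUE), collapse = "")
  }, character(1))
  pass <- seq_len(lib_size)
  mut_rank <- numeric(n)
  tpm <- numeric(n)
  mut_rank[pass] <- stats::runif(lib_size, 0, 0.5)
  tpm[pass] <- pmax(0.1, stats::rlnorm(lib_size, 1, 1.5))
  mut_rank[-pass] <- stats::runif(n_reject, 0.5001, 10)
  tpm[-pass] <- stats::rlnorm(n_reject, 1, 1.5)
  wt_rank <- ifelse(stats::runif(n) < 0.1, NA_real_,
                    stats::rlnorm(n, 0, 1.5))
  subs <- c("C>T", "G>A", "A>G", "T>C", "C>A", "G>T")
  no_clonality <- stats::runif(1) < 0.1  # cell-line-derived panels
  data.frame(
    peptide = pep,
    hla = sample(hla, n, replace = TRUE),
    mutation_id = paste0(genes, "_", sample(aa, n, TRUE),
                         sample(100:999, n, TRUE), sample(aa, n, TRUE)),
    gene = genes,
    mut_rank = mut_rank,
    wt_rank = wt_rank,
    tpm = tpm,
    mutation_class = sample(subs, n, replace = TRUE),
    cluster_size = if (no_clonality) NA_integer_ else
      sample(10:200, n, replace = TRUE),
    cellularity = if (no_clonality) NA_real_ else
      stats::runif(n, 50, 100),
    stringsAsFactors = FALSE
  )
}

# Barcode x timepoint matrix of true population frequencies (% of CD8+).
simulate_truth_frequencies <- function(panel, tp, post_tp, config) {
  bc <- panel$barcodes
  nb <- nrow(bc)
  truth <- matrix(0, nrow = nb, ncol = length(tp),
                  dimnames = list(bc$barcode_id, tp))
  neo <- which(bc$category == "neo")
  imm <- neo[stats::runif(length(neo)) < config$frac_immunogenic]
  lf <- log10(config$freq_range_pct)
  f_til <- 10^stats::runif(length(imm), lf[1], lf[2])
  if (sum(f_til) > 80) f_til <- f_til * 80 / sum(f_til)
  truth[imm, "TIL"] <- f_til

  if ("preACT" %in% tp && length(imm) > 0) {
    pre <- stats::runif(length(imm)) < config$preact_detect_prob
    truth[imm[pre], "preACT"] <- f_til[pre] * config$preact_scale
  }
  for (k in seq_along(post_tp)) {
    jitter <- stats::rlnorm(length(imm), 0, 0.25)
    f_k <- f_til * (config$decay^k) * jitter
    f_k[f_k < config$detect_floor_pct] <- 0
    truth[imm, post_tp[k]] <- f_k
  }

  # novel populations: first appear at a random post-infusion time point
  n_novel <- stats::rpois(1, config$novel_mean)
  cand <- setdiff(neo, imm)
  if (n_novel > 0 && length(cand) > 0 && length(post_tp) > 0) {
    nov <- sample(cand, min(n_novel, length(cand)))
    lnf <- log10(config$novel_freq_range_pct)
    for (b in nov) {
      start <- sample(seq_along(post_tp), 1)
      f0 <- 10^stats::runif(1, lnf[1], lnf[2])
      for (k in start:length(post_tp)) {
        f <- f0 * config$decay^(k - start)
        truth[b, post_tp[k]] <- if (f >= config$detect_floor_pct) f else 0
      }
    }
  }

  virus <- which(bc$category == "virus")
  vdet <- virus[stats::runif(length(virus)) < config$virus_detect_prob]
  f_v <- 10^stats::runif(length(vdet), log10(0.05), log10(5))
  for (t in tp) {
    jitter <- stats::rlnorm(length(vdet), 0, 0.2)
    truth[vdet, t] <- f_v * jitter
  }
  truth
}

#' Simulate clonally-reducible molecule counts for one screen
#'
#' Count-level model of one sorted sample plus its baseline triplicate.
#' Baseline replicate counts are negative binomial around the per-barcode
#' reagent-pool abundances. The sorted sample is a multinomial draw whose
#' composition mixes the spiked populations (proportional to their true
#' frequencies) with a multimer-positive background that mirrors the
#' baseline composition. The reported multimer-positive percentage is the
#' true total plus Gaussian gating noise, floored at the background level.
#'
#' @param baseline_props Named per-barcode reagent-pool proportions
#'   (sum 1).
#' @param true_freq_pct Named per-barcode true frequencies (percent; zeros
#'   for unspiked barcodes). Order must match `baseline_props`.
#' @param config A [sim_config()] (depth, dispersion, background, noise).
#' @param depth Molecule depth per sample; defaults to
#'   `config$read_depth / config$umi_dup_rate`.
#' @return List: `sample` (molecule counts), `baseline` (matrix, 3
#'   replicates), `multimer_pct`, `expected_fold` (per-barcode expected
#'   proportion ratio sample vs baseline), `true_freq_pct`.
#' @export
simulate_screen_counts <- function(baseline_props, true_freq_pct, config,
                                   depth = NULL) {
  stopifnot(length(baseline_props) == length(true_freq_pct))
  depth <- depth %||% round(config$read_depth / config$umi_dup_rate)
  nb <- length(baseline_props)
  size <- if (config$baseline_dispersion > 0) {
    1 / config$baseline_dispersion
  } else Inf
  baseline <- vapply(1:3, function(r) {
    mu <- depth * baseline_props
    if (is.finite(size)) {
      stats::rnbinom(nb, mu = mu, size = size)
    } else stats::rpois(nb, mu)
  }, numeric(nb))
  rownames(baseline) <- names(baseline_props)
  colnames(baseline) <- paste0("base", 1:3)

  total_pct <- sum(true_freq_pct) + config$background_pct
  mix <- (true_freq_pct + config$background_pct * baseline_props) / total_pct
  sample_counts <- as.vector(stats::rmultinom(1, depth, mix))
  names(sample_counts) <- names(baseline_props)

  multimer_pct <- max(config$background_pct,
                      sum(true_freq_pct) +
                        stats::rnorm(1, 0, config$gating_noise_pct))
  list(sample = sample_counts, baseline = baseline,
       multimer_pct = multimer_pct,
       expected_fold = as.vector(mix / baseline_props),
       true_freq_pct = true_freq_pct)
}

#' Serialize molecule counts into synthetic FASTQ reads
#'
#' Expands molecule counts into reads: every molecule receives a uniform
#' random 6-nt UMI (collisions occur at the natural 4^6 birthday rate and
#' are not corrected downstream), is PCR-duplicated a 1 + Poisson number of
#' times, serialized in the configured read layout, and subjected to
#' per-read substitution errors. Reads are shuffled before writing.
#'
#' @param counts Named molecule counts per barcode.
#' @param barcodes Barcode definition table (`barcode_id`, `a_seq`,
#'   `b_seq`).
#' @param config A [sim_config()].
#' @param layout Read layout (default [default_read_layout()]).
#' @param path If non-NULL, write a FASTQ file here and return the path;
#'   otherwise return the read sequences.
#' @param seed Integer seed for UMI/duplication/error draws.
#' @return Character vector of reads, or `path`. Attribute `n_molecules`
#'   records the pre-duplication molecule count.
#' @export
simulate_screen_reads <- function(counts, barcodes, config,
                                  layout = default_read_layout(),
                                  path = NULL, seed = 1L) {
  withr_seed(seed, {
    idx <- rep(match(names(counts), barcodes$barcode_id), counts)
    n_mol <- length(idx)
    umis <- all_umis()[sample.int(4096L, n_mol, replace = TRUE)]
    dups <- 1L + stats::rpois(n_mol, config$umi_dup_rate - 1)
    r_idx <- rep(idx, dups)
    r_umi <- rep(umis, dups)
    fixed <- layout$expected_sequence[layout$role == "fixed"]
    reads <- paste0(fixed[1], barcodes$a_seq[r_idx], r_umi,
                    fixed[2], barcodes$b_seq[r_idx])
    reads <- add_read_errors(reads, config$error_rate)
    reads <- reads[sample.int(length(reads))]
    attr(reads, "n_molecules") <- n_mol
    if (is.null(path)) return(reads)
    write_fastq(reads, path)
    attr(path, "n_molecules") <- n_mol
    path
  })
}

all_umis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                       stringsAsFactors = FALSE)
      cache <<- do.call(paste0, g)
    }
    cache
  }
})

# Per-read substitution errors: each read carries an error with probability
# 1 - (1 - rate)^L, at a uniform position, to a uniform base (which may be
# silent). A thinned one-error-per-read approximation of independent
# per-base errors, adequate at rates ~1e-3.
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads[1])
  hit <- which(stats::runif(length(reads)) < 1 - (1 - rate)^L)
  if (length(hit) > 0) {
    pos <- sample.int(L, length(hit), replace = TRUE)
    base <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    substr(reads[hit], pos, pos) <- base
  }
  reads
}

#' Write reads as a plain-text FASTQ file
#' @param reads Character vector of read sequences.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  qual <- strrep("I", nchar(reads))
  lines <- character(4L * n)
  if (n > 0) {
    lines[seq(1, by = 4, length.out = n)] <- paste0("@read", seq_len(n))
    lines[seq(2, by = 4, length.out = n)] <- reads
    lines[seq(3, by = 4, length.out = n)] <- "+"
    lines[seq(4, by = 4, length.out = n)] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a clinical outcome table from infusion-product NART burden
#'
#' Patients are split at the median of their infusion-product summed NART
#' frequency (ties to the lower group); progression-free survival is
#' exponential with the configured hazard ratio between the low and high
#' groups, with independent exponential censoring. Overall survival adds an
#' independent exponential tail after progression. RECIST labels are drawn
#' with a responder probability increasing in the summed frequency.
#'
#' @param sum_freqs Per-patient infusion-product summed NART frequencies.
#' @param config A [sim_config()] (uses `true_hr`, `base_rate`,
#'   `censor_rate`).
#' @return Data frame: `nart_group`, `recist`, `responder`, `pfs_months`,
#'   `pfs_event`, `os_months`, `os_event`.
#' @export
simulate_survival <- function(sum_freqs, config) {
  n <- length(sum_freqs)
  grp <- if (length(unique(sum_freqs)) == 1) {
    factor(rep("low", n), levels = c("low", "high"))
  } else quantile_split(sum_freqs, "median")
  rate <- ifelse(grp == "low", config$base_rate * config$true_hr,
                 config$base_rate)
  pfs_true <- stats::rexp(n, rate)
  cens <- stats::rexp(n, config$censor_rate)
  pfs_event <- pfs_true <= cens
  pfs <- pmin(pfs_true, cens)
  os_true <- pfs_true + stats::rexp(n, config$base_rate / 3)
  os_cens <- cens + stats::rexp(n, config$censor_rate)
  os_event <- os_true <= os_cens
  os <- pmin(os_true, os_cens)
  p_resp <- stats::plogis(-2 + 1.2 * log10(sum_freqs + 0.01))
  responder <- stats::runif(n) < p_resp
  recist <- ifelse(responder,
                   ifelse(stats::runif(n) < 0.45, "CR", "PR"),
                   ifelse(stats::runif(n) < 0.67, "SD", "PD"))
  data.frame(nart_group = grp, recist = recist, responder = responder,
             pfs_months = pfs, pfs_event = pfs_event,
             os_months = os, os_event = os_event,
             stringsAsFactors = FALSE)
}

#' Simulate one exponential two-group survival cohort
#'
#' Standalone helper for calibration studies of [logrank_hr()]: `n`
#' subjects split evenly into `low`/`high` groups, exponential event times
#' with the `low` group's hazard `true_hr` times the `high` group's,
#' independent exponential censoring.
#'
#' @param n Cohort size (even split).
#' @param true_hr True hazard ratio (low vs high).
#' @param base_rate High-group event rate (default log(2)/6 per month).
#' @param censor_rate Censoring rate (default 0.04).
#' @param seed Integer seed.
#' @return Data frame: `time`, `event`, `group` (factor low/high).
#' @export
simulate_survival_cohort <- function(n, true_hr = 2.5,
                                     base_rate = log(2) / 6,
                                     censor_rate = 0.04, seed = 1L) {
  withr_seed(seed, {
    grp <- factor(rep(c("low", "high"), length.out = n),
                  levels = c("low", "high"))
    rate <- ifelse(grp == "low", base_rate * true_hr, base_rate)
    t_true <- stats::rexp(n, rate)
    cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else Inf
    data.frame(time = pmin(t_true, cens), event = t_true <= cens,
               group = grp)
  })
}
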