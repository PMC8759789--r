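#' Run the full screen pipeline on a synthetic cohort
#'
#' Drives every stage end to end: simulate a cohort, serialize reads to
#' FASTQ (one sorted FASTQ per sample plus a baseline triplicate per
#' patient), decode and clonally reduce, test for enrichment against the
#' baselines, call antigen-specific populations with the frequency and
#' healthy-donor filters, classify longitudinal origin/engraftment, and
#' compute cohort statistics against the simulated clinical table. All
#' randomness derives from `config$seed`; the same seed yields
#' byte-identical output files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed). FASTQ files go to
#'   `dir/fastq`, result tables to `dir`.
#' @param keep_fastq Keep the FASTQ files after decoding (default TRUE).
#' @return Invisibly, a list with `sim`, `counts` (per patient), `calls`,
#'   `summaries`, `timelines`, `annotations`, `cohort` and the written file
#'   paths.
#' @export
run_pipeline <- function(config = sim_config(), dir = tempfile("nartscreen"),
                         keep_fastq = TRUE) {
  dir.create(file.path(dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  layout <- default_read_layout()

  calls_all <- list()
  summaries <- list()
  counts_all <- list()
  for (pt in sim$patients) {
    pid <- pt$patient_id
    man <- pt$manifest
    bc <- pt$panel$barcodes

    # molecule counts per sample (baselines shared per patient via the
    # first sorted sample's draw order: each sorted sample gets its own
    # triplicate, mirroring one PCR run per staining)
    counts_list <- list()
    man_rows <- man[man$sample_type != "baseline", , drop = FALSE]
    seed_base <- (config$seed + 104729L * match(pid, names(sim$patients))) %%
      .Machine$integer.max
    scr <- withr_seed(seed_base, {
      lapply(seq_len(nrow(man_rows)), function(i) {
        simulate_screen_counts(pt$baseline_props,
                               pt$truth[, man_rows$timepoint[i]], config)
      })
    })
    # one shared baseline triplicate per patient (first draw)
    base_counts <- scr[[1]]$baseline
    for (r in 1:3) {
      fq <- file.path(dir, "fastq", paste0(pid, "_base", r, ".fastq"))
      simulate_screen_reads(base_counts[, r], bc, config, layout, fq,
                            seed = (seed_base + r) %% .Machine$integer.max)
      dec <- decode_fastq(fq, bc, layout)
      counts_list[[paste0(pid, "_base", r)]] <-
        clonal_reduce(dec$reads, bc$barcode_id)
      if (!keep_fastq) unlink(fq)
    }
    for (i in seq_len(nrow(man_rows))) {
      sid <- man_rows$sample_id[i]
      fq <- file.path(dir, "fastq", paste0(sid, ".fastq"))
      simulate_screen_reads(scr[[i]]$sample, bc, config, layout, fq,
                            seed = (seed_base + 10L + i) %%
                              .Machine$integer.max)
      dec <- decode_fastq(fq, bc, layout)
      counts_list[[sid]] <- clonal_reduce(dec$reads, bc$barcode_id)
      if (!keep_fastq) unlink(fq)
    }
    counts <- build_count_table(man, counts_list)
    counts_all[[pid]] <- counts

    enr <- screen_enrichment(counts, man)
    enr <- merge(enr, bc[, c("barcode_id", "peptide", "hla", "category",
                             "mutation_id")], by = "barcode_id",
                 sort = FALSE)
    for (sid in man_rows$sample_id) {
      rec <- enr[enr$sample_id == sid, , drop = FALSE]
      rec$count <- counts[rec$barcode_id, sid]
      rec <- estimate_frequencies(rec,
                                  man$multimer_pct[man$sample_id == sid])
      calls <- call_narts(rec, sim$donor_blacklist)
      calls$patient_id <- pid
      calls_all[[sid]] <- calls
      if (man$timepoint[man$sample_id == sid] == "TIL") {
        s <- sample_summary(calls, pt$panel$hla_coverage,
                            cohort_mean_coverage(sim))
        s$patient_id <- pid
        summaries[[pid]] <- s
      }
    }
  }

  calls <- do.call(rbind, calls_all)
  rownames(calls) <- NULL
  til_summaries <- do.call(rbind, summaries)
  rownames(til_summaries) <- NULL

  timelines <- build_timelines(calls, sim$manifest)
  annotations <- if (nrow(timelines) > 0) annotate_timelines(timelines)
                 else NULL
  cohort <- cohort_analysis(til_summaries, sim$clinical)

  paths <- write_pipeline_outputs(dir, calls, til_summaries, timelines,
                                  annotations, cohort, counts_all)
  invisible(list(sim = sim, counts = counts_all, calls = calls,
                 summaries = til_summaries, timelines = timelines,
                 annotations = annotations, cohort = cohort, dir = dir,
                 paths = paths))
}

cohort_mean_coverage <- function(sim) {
  mean(vapply(sim$patients, function(p) p$panel$hla_coverage, numeric(1)))
}

#' Cohort-level outcome statistics for infusion-product summaries
#'
#' Joins per-patient infusion-product NART summaries to a clinical table
#' and computes the standard outcome battery: median split of normalized
#' diversity and summed frequency with log-rank/Kaplan-Meier analysis of
#' progression-free survival, and responder vs nonresponder rank
#' comparisons.
#'
#' @param summaries Per-patient summaries (one infusion-product row each,
#'   with `patient_id`, `diversity_norm`, `sum_freq_norm`).
#' @param clinical Clinical table with `patient_id`, `responder`,
#'   `pfs_months`, `pfs_event`.
#' @return List of results per endpoint; `NULL` components where group
#'   sizes do not permit a test.
#' @export
cohort_analysis <- function(summaries, clinical) {
  df <- merge(summaries, clinical, by = "patient_id")
  out <- list(n = nrow(df))
  if (nrow(df) < 2) return(out)
  for (m in c("diversity_norm", "sum_freq_norm")) {
    grp <- quantile_split(df[[m]], "median")
    res <- list(groups = table(grp))
    if (nlevels(droplevels(grp)) == 2 && all(table(grp) > 0)) {
      res$survival <- logrank_hr(df$pfs_months, df$pfs_event, grp)
    }
    if (sum(df$responder) > 0 && sum(!df$responder) > 0) {
      res$responder_test <- mann_whitney(df[[m]][df$responder],
                                         df[[m]][!df$responder])
    }
    out[[m]] <- res
  }
  out
}

write_pipeline_outputs <- function(dir, calls, summaries, timelines,
                                   annotations, cohort, counts_all) {
  p <- list(
    calls = file.path(dir, "nart_calls.tsv"),
    summaries = file.path(dir, "sample_summaries.tsv"),
    timelines = file.path(dir, "timelines.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    cohort = file.path(dir, "cohort_stats.json")
  )
  wt <- function(x, path) {
    if (is.null(x)) return()
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) signif(v, 10))
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wt(calls, p$calls)
  wt(summaries, p$summaries)
  wt(timelines, p$timelines)
  wt(annotations, p$annotations)
  cohort_json <- cohort
  for (m in c("diversity_norm", "sum_freq_norm")) {
    if (!is.null(cohort_json[[m]]$survival)) {
      cohort_json[[m]]$survival$km <- NULL
    }
    cohort_json[[m]]$groups <- as.list(cohort_json[[m]]$groups)
  }
  jsonlite::write_json(cohort_json, p$cohort, auto_unbox = TRUE, digits = 10)
  p
}
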