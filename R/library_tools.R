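#' Read a neopeptide prediction table
#'
#' Reads a MuPeXI-style tab-separated prediction table into a data frame of
#' neopeptide records. Expected columns: `peptide`, `hla`, `mutation_id`,
#' `gene`, `mut_rank`, `wt_rank`, `tpm`, `mutation_class`, `cluster_size`,
#' `cellularity`. Empty strings are read as missing (`NA`).
#'
#' @param path Path to a TSV file with a header line.
#' @return A data.frame with one row per predicted neopeptide.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("peptide", "hla", "mutation_id", "gene", "mut_rank",
                "wt_rank", "tpm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("prediction table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("mutation_class", "cluster_size", "cellularity")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  validate_predictions(df)
  df
}

validate_predictions <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 0)
  aa <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
  if (nrow(df) > 0) {
    if (any(!grepl(aa, df$peptide))) {
      stop("peptides must use the 20 canonical amino acids")
    }
    if (any(df$mut_rank < 0, na.rm = TRUE) ||
        any(df$wt_rank < 0, na.rm = TRUE) ||
        any(df$tpm < 0, na.rm = TRUE)) {
      stop("mut_rank, wt_rank and tpm must be non-negative")
    }
    if (any(is.na(df$mutation_id)) || any(!nzchar(df$mutation_id))) {
      stop("mutation_id must be non-empty")
    }
  }
  invisible(df)
}

#' Select the neopeptide library for a patient panel
#'
#' Applies the library inclusion rule used when building patient-specific
#' multimer panels. For patients with a high neoantigen load every peptide
#' with an eluted-ligand percentage rank of at most 0.5 and expression of at
#' least 0.1 TPM is included. For patients with a low neoantigen load the
#' expression floor is relaxed to 0.01 TPM and the top `target_size` peptides
#' by ascending percentage rank are taken instead.
#'
#' @param predictions Data frame of neopeptide records (see
#'   [read_predictions()]).
#' @param mode `"high_load"` or `"low_load"`.
#' @param target_size Library size cap for the low-load mode (default 200).
#' @param rank_max,tpm_min High-load thresholds (defaults 0.5 and 0.1).
#' @param tpm_min_low Low-load expression floor (default 0.01).
#' @return The selected subset, ordered by ascending `mut_rank` with ties
#'   broken lexicographically by peptide then HLA. An empty selection is
#'   returned with a warning, not an error.
#' @export
select_library <- function(predictions,
                           mode = c("high_load", "low_load"),
                           target_size = 200,
                           rank_max = 0.5, tpm_min = 0.1,
                           tpm_min_low = 0.01) {
  mode <- match.arg(mode)
  validate_predictions(predictions)
  stopifnot(nrow(predictions) > 0, target_size >= 1)
  if (mode == "high_load") {
    keep <- predictions$mut_rank <= rank_max & predictions$tpm >= tpm_min
  } else {
    keep <- predictions$tpm >= tpm_min_low
  }
  keep[is.na(keep)] <- FALSE
  sel <- predictions[keep, , drop = FALSE]
  ord <- order(sel$mut_rank, sel$peptide, sel$hla)
  sel <- sel[ord, , drop = FALSE]
  if (mode == "low_load" && nrow(sel) > target_size) {
    sel <- sel[seq_len(target_size), , drop = FALSE]
  }
  if (nrow(sel) == 0) warning("library selection is empty")
  rownames(sel) <- NULL
  sel
}

#' Classify a neopeptide as conserved or improved binder
#'
#' A neopeptide is a conserved binder (CB) when its germline counterpart is
#' itself predicted to bind the HLA (germline rank within the binder
#' threshold); otherwise the mutation has improved the predicted HLA binding
#' and the peptide is an improved binder (IB). A missing germline rank
#' (e.g. frameshift-derived peptides with no germline counterpart) is
#' classified IB. The boundary value is assigned to CB.
#'
#' @param mut_rank,wt_rank Percentage rank of the mutant and germline
#'   peptides; `wt_rank` may be `NA`.
#' @param binder_threshold Germline binder cutoff (default 0.5).
#' @return Character vector of `"CB"`/`"IB"` (vectorized over inputs).
#' @export
classify_binding <- function(mut_rank, wt_rank, binder_threshold = 0.5) {
  stopifnot(binder_threshold > 0)
  if (any(mut_rank < 0, na.rm = TRUE) || any(wt_rank < 0, na.rm = TRUE)) {
    stop("rank scores must be non-negative")
  }
  ifelse(!is.na(wt_rank) & wt_rank <= binder_threshold, "CB", "IB")
}

#' Annotate immunogenicity-related features of neopeptides
#'
#' Adds the boolean feature flags used for immunogenicity characterization:
#' whether the source gene is a known cancer driver, whether the transcript
#' is expressed above the high-expression cutoff (strictly greater than
#' 2 TPM), whether the substitution is a C>T transition on either strand
#' (C>T or G>A), and whether the mutation is clonal (PyClone-style cluster
#' size of at least 80 and cellularity of at least 90). Clonality is `NA`
#' (not `FALSE`) when cluster size or cellularity is unavailable, as for
#' panels whose exome data came from tumour cell lines.
#'
#' @param records Data frame of neopeptide records.
#' @param driver_genes Character vector of driver gene symbols.
#' @param tpm_cut High-expression cutoff, strict (default 2).
#' @param clonal_cluster_min,clonal_cellularity_min Clonal-mutation filter
#'   thresholds (defaults 80 and 90, inclusive).
#' @return `records` with logical columns `driver`, `high_expression`,
#'   `c_to_t`, `clonal` appended.
#' @export
annotate_features <- function(records, driver_genes = character(),
                              tpm_cut = 2,
                              clonal_cluster_min = 80,
                              clonal_cellularity_min = 90) {
  records$driver <- records$gene %in% driver_genes
  records$high_expression <- records$tpm > tpm_cut
  records$c_to_t <- is_c_to_t(records$mutation_class)
  records$clonal <- ifelse(
    is.na(records$cluster_size) | is.na(records$cellularity),
    NA,
    records$cluster_size >= clonal_cluster_min &
      records$cellularity >= clonal_cellularity_min
  )
  records
}

#' Default driver-gene list
#'
#' Reads the small synthetic driver-gene list shipped with the package
#' (melanoma-typical recurrently mutated genes). Intended as a placeholder:
#' real analyses should supply a catalogue-derived list, since driver
#' status is study-specific.
#'
#' @param path Optional path to a one-symbol-per-line file (lines starting
#'   with `#` are ignored); defaults to the packaged list.
#' @return Character vector of gene symbols.
#' @export
default_driver_genes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "driver_genes.txt",
                                package = "nartscreen")
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(lines, "#")])
  lines[nzchar(lines)]
}

# C>T on either reported strand (C>T or G>A); NA propagates.
is_c_to_t <- function(mutation_class) {
  cls <- toupper(gsub("\\s", "", as.character(mutation_class)))
  out <- cls %in% c("C>T", "G>A")
  out[is.na(mutation_class)] <- NA
  out
}

#' Build a barcoded patient panel from a selected library
#'
#' Assigns one double-stranded AxBy DNA barcode (two 25-mer oligo sequences)
#' to each selected neopeptide and to each virus-control epitope, producing
#' the panel table used for decoding. Barcode oligo sequences are drawn
#' reproducibly from the supplied generator seed; with 25-nt random
#' sequences, pairwise Hamming separation far exceeds the decoder's mismatch
#' tolerance with overwhelming probability, and separation is checked.
#'
#' @param library_records Selected neopeptide records ([select_library()]).
#' @param patient_id Patient identifier.
#' @param virus_epitopes Character vector of virus-control epitope labels.
#' @param seed Integer seed for barcode sequence generation.
#' @param min_separation Minimum pairwise Hamming distance (per A+B pair)
#'   below which a warning is raised; default 5 (2 x default mismatch
#'   tolerance + 1).
#' @return A list with elements `patient_id`, `hla_alleles`, `hla_coverage`
#'   and `barcodes` (data.frame: barcode_id, a_seq, b_seq, peptide, hla,
#'   category, mutation_id, gene plus any feature columns present).
#' @export
build_panel <- function(library_records, patient_id,
                        virus_epitopes = character(), seed = 1L,
                        min_separation = 5L) {
  n_neo <- nrow(library_records)
  n <- n_neo + length(virus_epitopes)
  stopifnot(n >= 1)
  seqs <- random_barcode_seqs(2L * n, seed = seed)
  ids <- sprintf("A%02dB%02d", seq_len(n), seq_len(n))
  barcodes <- data.frame(
    barcode_id = ids,
    a_seq = seqs[seq_len(n)],
    b_seq = seqs[n + seq_len(n)],
    peptide = c(library_records$peptide, virus_epitopes),
    hla = c(library_records$hla, rep(NA_character_, length(virus_epitopes))),
    category = rep(c("neo", "virus"), c(n_neo, length(virus_epitopes))),
    mutation_id = c(library_records$mutation_id,
                    rep(NA_character_, length(virus_epitopes))),
    gene = c(library_records$gene,
             rep(NA_character_, length(virus_epitopes))),
    stringsAsFactors = FALSE
  )
  check_barcode_separation(barcodes, min_separation)
  hla <- unique(stats::na.omit(library_records$hla))
  list(patient_id = patient_id, hla_alleles = hla,
       hla_coverage = length(hla), barcodes = barcodes)
}

random_barcode_seqs <- function(n, length = 25L, seed = 1L) {
  withr_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_barcode_separation <- function(barcodes, min_separation) {
  key <- paste0(barcodes$a_seq, barcodes$b_seq)
  if (anyDuplicated(barcodes$barcode_id)) {
    stop("barcode ids must be unique within a library")
  }
  if (any(nchar(barcodes$a_seq) != 25L) || any(nchar(barcodes$b_seq) != 25L)) {
    stop("barcode oligo sequences must be exactly 25 nt")
  }
  if (any(grepl("[^ACGT]", c(barcodes$a_seq, barcodes$b_seq)))) {
    stop("barcode oligo sequences must use the ACGT alphabet")
  }
  d <- hamming_cross(key, key)
  diag(d) <- NA
  if (any(d < min_separation, na.rm = TRUE)) {
    warning("some barcode pairs are closer than the decoding separation (",
            min_separation, " mismatches); ambiguous reads will be dropped")
  }
  invisible(TRUE)
}

#' Write / read a panel barcode annotation table
#'
#' The panel is serialized as a TSV (one row per barcode) with a small
#' header block (`# patient_id=`, `# hla_alleles=`) so that a panel round
#' trips through a single plain-text file.
#'
#' @param panel A panel as returned by [build_panel()].
#' @param path Output path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   panel list.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# patient_id=", panel$patient_id),
    paste0("# hla_alleles=", paste(panel$hla_alleles, collapse = ","))
  ), con)
  utils::write.table(panel$barcodes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  header <- readLines(path, n = 2L)
  pid <- sub("^# patient_id=", "", header[1])
  hla <- sub("^# hla_alleles=", "", header[2])
  hla <- if (nzchar(hla)) strsplit(hla, ",")[[1]] else character()
  barcodes <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                                na.strings = c("", "NA"))
  list(patient_id = pid, hla_alleles = hla, hla_coverage = length(hla),
       barcodes = barcodes)
}
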