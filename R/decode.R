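#' Amplicon read layout
#'
#' Describes the fixed structure of a barcode amplicon read as an ordered
#' list of segments. Each segment has a role (`fixed`, `a_barcode`,
#' `b_barcode` or `umi`), a length in nucleotides, and, for fixed segments,
#' an expected sequence. The default layout is
#' `[fixed primer 10 nt][A 25 nt][UMI 6 nt][fixed anneal 10 nt][B 25 nt]`,
#' matching a biotinylated A oligo annealed to a partially complementary B
#' oligo with a single 6-nt unique molecular identifier. Both 25-mer barcode
#' segments and at least 6 nt of UMI are required.
#'
#' @param segments Data frame with columns `role`, `length`,
#'   `expected_sequence` (NA for non-fixed segments).
#' @return A validated layout object (class `read_layout`).
#' @export
read_layout <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("role", "length") %in% names(segments)))
  if (!"expected_sequence" %in% names(segments)) {
    segments$expected_sequence <- NA_character_
  }
  roles <- segments$role
  if (sum(roles == "a_barcode") != 1L || sum(roles == "b_barcode") != 1L) {
    stop("layout must contain exactly one a_barcode and one b_barcode segment")
  }
  if (any(segments$length[roles %in% c("a_barcode", "b_barcode")] != 25L)) {
    stop("barcode segments must be 25 nt")
  }
  if (sum(segments$length[roles == "umi"]) < 6L) {
    stop("total UMI length must be at least 6 nt")
  }
  segments$start <- cumsum(c(1L, segments$length[-nrow(segments)]))
  segments$end <- segments$start + segments$length - 1L
  structure(segments, class = c("read_layout", "data.frame"))
}

#' @rdname read_layout
#' @export
default_read_layout <- function() {
  read_layout(data.frame(
    role = c("fixed", "a_barcode", "umi", "fixed", "b_barcode"),
    length = c(10L, 25L, 6L, 10L, 25L),
    expected_sequence = c("ACGTGCTAGC", NA, NA, "TTGCACGTAG", NA),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a layout as JSON
#' @param path JSON file path.
#' @param layout A `read_layout` object.
#' @return `read_layout_json` returns a layout; `write_layout_json` returns
#'   `path` invisibly.
#' @export
read_layout_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$expected_sequence[df$expected_sequence == ""] <- NA
  read_layout(df)
}

#' @rdname read_layout_json
#' @export
write_layout_json <- function(layout, path) {
  df <- as.data.frame(layout)[, c("role", "length", "expected_sequence")]
  df$expected_sequence[is.na(df$expected_sequence)] <- ""
  jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

layout_length <- function(layout) sum(layout$length)

segment_substr <- function(seqs, layout, role) {
  idx <- which(layout$role == role)
  parts <- lapply(idx, function(i) substr(seqs, layout$start[i], layout$end[i]))
  do.call(paste0, parts)
}

# Hamming distances between two character vectors of equal-length strings,
# computed by one-hot encoding and a single matrix product (no per-read loop).
hamming_cross <- function(query, subject) {
  stopifnot(length(unique(nchar(c(query, subject)))) <= 1)
  L <- nchar(query[1])
  enc <- function(x) {
    m <- matrix(unlist(strsplit(x, "")), nrow = length(x), byrow = TRUE)
    out <- matrix(0L, nrow = length(x), ncol = 4L * L)
    for (j in seq_along(c("A", "C", "G", "T"))) {
      base <- c("A", "C", "G", "T")[j]
      out[, (j - 1L) * L + seq_len(L)] <- (m == base)
    }
    out
  }
  q <- enc(query)
  s <- enc(subject)
  L - tcrossprod(q, s)
}

#' Decode barcode amplicon reads from a FASTQ file
#'
#' Parses each read according to the layout, extracts the A/B barcode
#' segments and the UMI, and assigns the read to the unique library barcode
#' minimizing the total Hamming distance over the A+B segments, provided
#' that distance is at most `2 * max_mismatch` and the minimizer is unique.
#' Reads tied between two library barcodes are counted as ambiguous and
#' dropped; reads with no barcode within tolerance are unmatched. Reads
#' shorter than the layout are counted as malformed and skipped. Base
#' qualities are parsed and ignored; no quality filtering is applied.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param library Barcode definition data frame (`barcode_id`, `a_seq`,
#'   `b_seq`), e.g. `panel$barcodes`.
#' @param layout A `read_layout` (default [default_read_layout()]).
#' @param max_mismatch Mismatch tolerance per 25-mer segment (default 2);
#'   the total A+B budget is `2 * max_mismatch`.
#' @return A list: `reads` (data.frame `barcode_id`, `umi` for matched
#'   reads) and `stats` (total, matched, unmatched, ambiguous, malformed).
#' @export
decode_fastq <- function(fastq, library, layout = default_read_layout(),
                         max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0L)
  seqs <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) stop("FASTQ parse failure in '", fastq, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  decode_reads(unname(seqs), library, layout, max_mismatch)
}

# Decode a character vector of read sequences (workhorse behind decode_fastq;
# exported for read-order/permutation testing on in-memory reads).
#' @rdname decode_fastq
#' @param reads Character vector of read sequences.
#' @export
decode_reads <- function(reads, library, layout = default_read_layout(),
                         max_mismatch = 2L) {
  total <- length(reads)
  ok_len <- nchar(reads) >= layout_length(layout)
  malformed <- sum(!ok_len)
  reads <- reads[ok_len]

  a_seg <- segment_substr(reads, layout, "a_barcode")
  b_seg <- segment_substr(reads, layout, "b_barcode")
  umi <- segment_substr(reads, layout, "umi")
  key <- paste0(a_seg, b_seg)
  lib_key <- paste0(library$a_seq, library$b_seq)

  hit <- match(key, lib_key)
  ambiguous <- 0L
  budget <- 2L * max_mismatch

  todo <- which(is.na(hit) & !grepl("[^ACGT]", key))
  if (length(todo) > 0 && budget > 0) {
    uq <- unique(key[todo])
    d <- hamming_cross(uq, lib_key)
    best <- max.col(-d, ties.method = "first")
    bestd <- d[cbind(seq_along(uq), best)]
    n_at_best <- rowSums(d == bestd)
    assign_idx <- ifelse(bestd <= budget & n_at_best == 1L, best, NA_integer_)
    amb_flag <- bestd <= budget & n_at_best > 1L
    m <- match(key[todo], uq)
    hit[todo] <- assign_idx[m]
    ambiguous <- sum(amb_flag[m])
  }

  matched <- !is.na(hit)
  list(
    reads = data.frame(barcode_id = library$barcode_id[hit[matched]],
                       umi = umi[matched], stringsAsFactors = FALSE),
    stats = data.frame(total = total, matched = sum(matched),
                       unmatched = sum(!matched) - ambiguous + 0L,
                       ambiguous = ambiguous, malformed = malformed)
  )
}

#' Clonally reduce decoded reads to UMI counts
#'
#' Collapses PCR duplicates by counting, for each barcode, the number of
#' distinct UMIs observed in one sample. Raw read multiplicity has no
#' effect: ten reads of one barcode sharing one UMI count once. UMI
#' sequencing errors are not corrected.
#'
#' @param decoded Data frame with columns `barcode_id` and `umi`
#'   (the `reads` element of [decode_fastq()]), all from one sample.
#' @param barcode_ids Full set of library barcode ids; barcodes never seen
#'   get an explicit zero.
#' @return Named integer vector of clonally reduced counts, one entry per
#'   library barcode.
#' @export
clonal_reduce <- function(decoded, barcode_ids) {
  dedup <- decoded[!duplicated(paste(decoded$barcode_id, decoded$umi,
                                     sep = "\r")), , drop = FALSE]
  tab <- table(factor(dedup$barcode_id, levels = barcode_ids))
  counts <- as.integer(tab)
  names(counts) <- barcode_ids
  counts
}

#' Assemble a barcode-by-sample count matrix
#'
#' Combines per-sample clonally reduced counts into one integer matrix with
#' a row for every library barcode (explicit zeros) and a column for every
#' sample in the manifest. The manifest's baseline replicate grouping is
#' preserved as an attribute for downstream enrichment testing.
#'
#' @param manifest Sample manifest data frame; must contain `sample_id` and
#'   `sample_type`, optionally `patient_id`, `timepoint`, `multimer_pct`,
#'   `baseline_group`.
#' @param counts_list Named list of count vectors (names = sample ids), as
#'   produced by [clonal_reduce()].
#' @return Integer matrix (barcodes x samples) with the manifest attached as
#'   attribute `manifest`.
#' @export
build_count_table <- function(manifest, counts_list) {
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicated sample_id in manifest")
  }
  missing <- setdiff(manifest$sample_id, names(counts_list))
  if (length(missing) > 0) {
    stop("no counts for samples: ", paste(missing, collapse = ", "))
  }
  barcode_ids <- names(counts_list[[1]])
  mat <- vapply(manifest$sample_id, function(s) {
    v <- counts_list[[s]]
    if (!identical(names(v), barcode_ids)) {
      stop("all samples must be decoded against the same library")
    }
    as.integer(v)
  }, integer(length(barcode_ids)))
  mat <- matrix(mat, nrow = length(barcode_ids),
                dimnames = list(barcode_ids, manifest$sample_id))
  attr(mat, "manifest") <- manifest
  mat
}

#' Read / write a count matrix as TSV
#' @param counts Integer count matrix (barcodes x samples).
#' @param path TSV path; first column `barcode_id`.
#' @return `read_count_table` returns a matrix; `write_count_table` returns
#'   `path` invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(barcode_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$barcode_id
  storage.mode(mat) <- "integer"
  mat
}
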