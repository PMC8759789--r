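# Small fixture builders shared across tests.

make_predictions <- function(n = 10, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  data.frame(
    peptide = vapply(seq_len(n), function(i)
      paste(sample(aa, 9, TRUE), collapse = ""), character(1)),
    hla = sample(c("HLA-A*01:01", "HLA-B*08:01"), n, TRUE),
    mutation_id = sprintf("GENE%02d_P%dL", seq_len(n), 100 + seq_len(n)),
    gene = sprintf("GENE%02d", seq_len(n)),
    mut_rank = runif(n, 0, 2),
    wt_rank = runif(n, 0, 5),
    tpm = rlnorm(n, 0, 1),
    mutation_class = sample(c("C>T", "G>A", "A>G"), n, TRUE),
    cluster_size = sample(50:150, n, TRUE),
    cellularity = runif(n, 70, 100),
    stringsAsFactors = FALSE
  )
}

make_tiny_panel <- function(n_neo = 5, n_virus = 2, seed = 7) {
  preds <- make_predictions(n_neo, seed = seed)
  preds$mut_rank <- runif(n_neo, 0, 0.4)
  preds$tpm <- pmax(preds$tpm, 0.2)
  lib <- select_library(preds, "high_load")
  build_panel(lib, "PT", virus_epitopes = sprintf("v%02d", seq_len(n_virus)),
              seed = seed)
}

# Serialize reads for chosen (barcode index, umi) pairs in the default
# layout, without errors.
make_reads <- function(panel, idx, umis, layout = default_read_layout()) {
  fixed <- layout$expected_sequence[layout$role == "fixed"]
  paste0(fixed[1], panel$barcodes$a_seq[idx], umis, fixed[2],
         panel$barcodes$b_seq[idx])
}

all_umis_test <- function() {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                   stringsAsFactors = FALSE)
  do.call(paste0, g)
}

random_counts_matrix <- function(n_barcodes, n_samples, lambda = 50) {
  matrix(rpois(n_barcodes * n_samples, lambda) + 1L,
         nrow = n_barcodes,
         dimnames = list(paste0("b", seq_len(n_barcodes)),
                         paste0("s", seq_len(n_samples))))
}
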