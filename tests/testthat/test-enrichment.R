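test_that("TMM factors match the brute-force oracle and edgeR", {
  set.seed(21)
  for (i in 1:20) {
    m <- random_counts_matrix(sample(20:60, 1), sample(2:5, 1),
                              lambda = sample(c(20, 100, 500), 1))
    f <- tmm_factors(m)
    expect_equal(unname(f), oracle_tmm(m), tolerance = 1e-9)
  }
  skip_if_not_installed("edgeR")
  set.seed(22)
  for (i in 1:10) {
    m <- random_counts_matrix(sample(50:200, 1), sample(3:6, 1), 100)
    f <- tmm_factors(m)
    fe <- edgeR::calcNormFactors(m, method = "TMM")
    expect_equal(unname(f), unname(fe), tolerance = 1e-8)
  }
})

test_that("TMM is invariant to depth and trivial on identical columns", {
  m <- random_counts_matrix(50, 2, 80)
  m[, 2] <- m[, 1]
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)
  # doubling one column changes only depth, not composition
  m2 <- cbind(m[, 1], 2L * m[, 1])
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM handles disjoint support with a warning", {
  m <- matrix(c(5L, 5L, 0L, 0L, 0L, 0L, 7L, 7L), ncol = 2,
              dimnames = list(paste0("b", 1:4), c("s1", "s2")))
  expect_warning(f <- tmm_factors(m), "no positive barcode")
  expect_true(all(f > 0))
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(31)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("null self-comparison yields flat fold changes and no signal", {
  set.seed(41)
  base_col <- rpois(200, 80) + 1L
  baseline <- cbind(base_col, base_col, base_col)
  res <- enrichment_test(base_col, baseline)
  expect_true(all(abs(res$log2fc) < 1e-8))
  expect_true(all(res$pvalue > 0.001))
  expect_equal(sum(res$read_fraction_pct), 100, tolerance = 1e-9)
})

test_that("a spiked barcode shows the closed-form fold change and is called", {
  set.seed(42)
  nb <- 300
  mu <- rep(100, nb)
  baseline <- cbind(rpois(nb, mu), rpois(nb, mu), rpois(nb, mu))
  smp <- rpois(nb, mu)
  smp[7] <- 100 * 100  # 100x its baseline mean
  rownames(baseline) <- paste0("b", 1:nb)
  res <- enrichment_test(smp, baseline)
  # equal depths are only approximate after the spike inflates the total;
  # compare against the prior-moderated closed form on equalized counts
  expect_gt(res$log2fc[7], 6)
  expect_lt(res$log2fc[7], 7)
  called <- call_enriched(res)
  expect_true(called$enriched[7])
  expect_lt(mean(called$enriched[-7]), 0.01)
})

test_that("zero-dispersion p-values match the exact Poisson split test", {
  set.seed(43)
  cases <- expand.grid(y1 = c(0, 1, 3, 10, 25), y2 = c(0, 2, 9, 30))
  for (i in seq_len(nrow(cases))) {
    y1 <- cases$y1[i]; y2 <- cases$y2[i]
    p <- nartscreen:::exact_split_pvalue(y1, y2, n_rep = 3, dispersion = 0)
    expect_equal(p, oracle_poisson_split(y1, y2, 3), tolerance = 1e-12)
  }
  # small positive dispersion converges to the Poisson limit
  p_nb <- nartscreen:::exact_split_pvalue(10, 9, 3, dispersion = 1e-9)
  expect_equal(p_nb, oracle_poisson_split(10, 9, 3), tolerance = 1e-5)
})

test_that("all-zero barcodes get log2fc 0 and pvalue 1", {
  baseline <- matrix(5L, nrow = 3, ncol = 3)
  baseline[2, ] <- 0L
  res <- enrichment_test(c(5L, 0L, 5L), baseline)
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$pvalue[2], 1)
})

test_that("p-values are invariant to global count rescaling at fixed reference size", {
  set.seed(44)
  nb <- 100
  baseline <- cbind(rpois(nb, 50), rpois(nb, 50), rpois(nb, 50)) + 1L
  smp <- rpois(nb, 50) + 1L
  smp[3] <- 500L
  r1 <- enrichment_test(smp, baseline, dispersion = 0.05,
                        effective_size = 5000)
  r2 <- enrichment_test(smp * 7L, baseline * 7L, dispersion = 0.05,
                        effective_size = 5000)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-9)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-9)
})

test_that("dispersion estimation is a floored pooled method of moments", {
  set.seed(45)
  nb <- 2000
  # Poisson data -> dispersion near zero (floored at exactly zero often)
  pois <- cbind(rpois(nb, 100), rpois(nb, 100), rpois(nb, 100))
  expect_lt(estimate_dispersion(pois), 0.01)
  # strongly overdispersed data -> estimate near the truth
  nb_counts <- cbind(rnbinom(nb, mu = 100, size = 10),
                     rnbinom(nb, mu = 100, size = 10),
                     rnbinom(nb, mu = 100, size = 10))
  est <- estimate_dispersion(nb_counts)
  expect_gt(est, 0.05)
  expect_lt(est, 0.2)
})

test_that("enrichment gate applies all three thresholds with strict/inclusive bounds", {
  rec <- data.frame(
    barcode_id = paste0("b", 1:5),
    log2fc = c(3, 3, 3, -2, 3),
    pvalue = rep(1e-6, 5),
    p_adj = c(0.0005, 0.0005, 0.001, 0.0005, 0.002),
    read_fraction_pct = c(0.5, 0.05, 0.5, 0.5, 0.5)
  )
  out <- call_enriched(rec)
  expect_identical(out$enriched, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # read fraction exactly at 0.1% is inclusive
  rec$read_fraction_pct <- 0.1
  expect_true(call_enriched(rec)$enriched[1])
})

test_that("screen_enrichment tests each sorted sample against its run's triplicate", {
  set.seed(46)
  nb <- 150
  ids <- paste0("b", seq_len(nb))
  man <- data.frame(
    sample_id = c("base1", "base2", "base3", "tilA", "tilB"),
    patient_id = "P", sample_type = c(rep("baseline", 3), "TIL", "PBMC"),
    baseline_group = "P", stringsAsFactors = FALSE
  )
  mu <- rlnorm(nb, log(60), 0.3)
  counts <- sapply(1:5, function(i) rpois(nb, mu))
  counts[9, 4] <- counts[9, 4] + 3000L
  dimnames(counts) <- list(ids, man$sample_id)
  res <- screen_enrichment(counts, man)
  expect_setequal(unique(res$sample_id), c("tilA", "tilB"))
  hitA <- res[res$sample_id == "tilA" & res$barcode_id == "b9", ]
  expect_true(hitA$enriched)
  expect_false(any(res$enriched[res$sample_id == "tilB"]))
})
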