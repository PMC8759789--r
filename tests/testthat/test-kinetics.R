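det <- function(...) {
  tp <- timepoint_levels()
  v <- setNames(rep(FALSE, length(tp)), tp)
  v[c(...)] <- TRUE
  v
}

test_that("origin annotation follows first appearance", {
  expect_identical(annotate_origin(det("preACT", "TIL", "post1")), "pre_TIL")
  expect_identical(annotate_origin(det("preACT", "TIL")), "pre_TIL")
  expect_identical(annotate_origin(det("preACT")), "preACT_only")
  expect_identical(annotate_origin(det("preACT", "post4")), "preACT_only")
  expect_identical(annotate_origin(det("TIL")), "TIL")
  expect_identical(annotate_origin(det("TIL", "post12")), "TIL")
  expect_identical(annotate_origin(det("post4")), "novel_post4")
  expect_identical(annotate_origin(det("post1", "post24")), "novel_post1")
  expect_true(is.na(annotate_origin(det())))
})

test_that("engraftment needs the infusion product plus one post sample; persistence needs two post samples", {
  expect_identical(engraftment_flags(det("TIL", "post1")),
                   c(engrafted = TRUE, persisting = FALSE))
  expect_identical(engraftment_flags(det("TIL", "post1", "post4")),
                   c(engrafted = TRUE, persisting = TRUE))
  expect_identical(engraftment_flags(det("TIL")),
                   c(engrafted = FALSE, persisting = FALSE))
  expect_identical(engraftment_flags(det("post1", "post12")),
                   c(engrafted = FALSE, persisting = TRUE))
  # non-consecutive post detections still persist
  expect_identical(engraftment_flags(det("TIL", "post1", "post48")),
                   c(engrafted = TRUE, persisting = TRUE))
})

test_that("classification over all detection patterns matches the independent reference", {
  tps <- c("preACT", "TIL", "post1", "post4", "post12")
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(patterns) <- tps
  n_checked <- 0
  for (i in seq_len(nrow(patterns))) {
    d <- unlist(patterns[i, ])
    ref <- oracle_kinetics(d)
    flags <- engraftment_flags(d)
    expect_identical(annotate_origin(d), ref$category)
    expect_identical(unname(flags["engrafted"]), ref$engrafted)
    expect_identical(unname(flags["persisting"]), ref$persisting)
    # structural invariants
    if (!is.na(ref$category)) {
      n_checked <- n_checked + 1
      if (startsWith(ref$category, "novel_")) expect_false(d[["TIL"]])
      if (flags[["engrafted"]]) {
        expect_true(ref$category %in% c("pre_TIL", "TIL"))
      }
    }
  }
  expect_equal(n_checked, 31)  # origin categories partition all detections
})

test_that("mutation-level collapse keeps the most frequent epitope per mutation", {
  calls <- data.frame(
    mutation_id = c(rep("AKAP9_P1796L", 7), "X_1", "Y_2"),
    peptide = paste0("P", 1:9),
    est_freq_pct = c(2, 1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.3, NA)
  )
  out <- collapse_mutations(calls)
  expect_equal(nrow(out), 3)
  akap <- out[out$mutation_id == "AKAP9_P1796L", ]
  expect_equal(akap$est_freq_pct, 2)
  expect_true(is.na(out$est_freq_pct[out$mutation_id == "Y_2"]))
  # identity when no mutation is shared
  solo <- calls[7:9, ]
  expect_equal(nrow(collapse_mutations(solo)), 3)
  # pigeonhole: collapsed diversity never exceeds original
  expect_lte(nrow(out), nrow(calls))
})

make_toy_calls <- function() {
  # patient with samples at preACT, TIL, post1, post4 (post12 missing);
  # spec A detected preACT+TIL+post1, spec B TIL only, spec C novel post4
  samples <- c(preACT = "S_pre", TIL = "S_til", post1 = "S_p1",
               post4 = "S_p4")
  man <- data.frame(sample_id = unname(samples), patient_id = "P1",
                    sample_type = c("PBMC", "TIL", "PBMC", "PBMC"),
                    timepoint = names(samples), stringsAsFactors = FALSE)
  row <- function(sid, pep, freq) {
    data.frame(sample_id = sid, peptide = pep, hla = "HLA-A*01:01",
               category = "neo", mutation_id = paste0(pep, "_mut"),
               est_freq_pct = freq, passes = TRUE,
               stringsAsFactors = FALSE)
  }
  calls <- rbind(row("S_pre", "A", 0.1), row("S_til", "A", 2),
                 row("S_p1", "A", 1), row("S_til", "B", 0.5),
                 row("S_p4", "C", 0.05))
  list(calls = calls, manifest = man)
}

test_that("timelines record availability and detections per time point", {
  toy <- make_toy_calls()
  tl <- build_timelines(toy$calls, toy$manifest)
  a <- tl[tl$peptide == "A", ]
  expect_true(all(a$available[a$timepoint %in%
                                c("preACT", "TIL", "post1", "post4")]))
  expect_false(any(a$available[a$timepoint %in% c("post12", "post24")]))
  expect_identical(a$detected[match(c("preACT", "TIL", "post1", "post4"),
                                    as.character(a$timepoint))],
                   c(TRUE, TRUE, TRUE, FALSE))
  ann <- annotate_timelines(tl)
  expect_identical(ann$category_origin[ann$peptide == "A"], "pre_TIL")
  expect_identical(ann$category_origin[ann$peptide == "B"], "TIL")
  expect_identical(ann$category_origin[ann$peptide == "C"], "novel_post4")
  expect_true(ann$engrafted[ann$peptide == "A"])
  expect_false(ann$persisting[ann$peptide == "A"])
})

test_that("timecourse summaries yield NA at unsampled time points, zero at sampled ones", {
  toy <- make_toy_calls()
  tl <- build_timelines(toy$calls, toy$manifest)
  tc <- timecourse_summary(tl, hla_coverage = 4, cohort_mean_coverage = 4.4)
  expect_true(is.na(tc$diversity[tc$timepoint == "post12"]))
  expect_false(tc$available[tc$timepoint == "post12"])
  expect_equal(tc$diversity[tc$timepoint == "TIL"], 2)
  expect_equal(tc$sum_freq[tc$timepoint == "TIL"], 2.5)
  expect_equal(tc$sum_freq_norm[tc$timepoint == "TIL"], 2.5 * 4.4 / 4)
  # all detections vanished by post4 except the novel one
  expect_equal(tc$diversity[tc$timepoint == "post4"], 1)
})
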