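test_that("hotspot classification follows the WRC / GYW motif definitions", {
  # C at position 4 of TAGCA: context AGC = (W)(R)C -> hotspot
  expect_equal(classify_mutation("TAGCA", 4), "CG_WRC")
  # G at position 1 of GCTAA: triplet GCT = G(Y)(W) -> bottom-strand hotspot
  expect_equal(classify_mutation("GCTAA", 1), "CG_WRC")
  # C in a CCC context has no W in the first slot
  expect_equal(classify_mutation("CCCCC", 3), "CG_nonWRC")
  expect_equal(classify_mutation("TAGCA", 2), "AT")
  # context running off the end: non-hotspot with a warning
  expect_warning(cls <- classify_mutation("CATGC", 1), "context")
  expect_equal(cls, "CG_nonWRC")
  expect_error(classify_mutation("ACGT", 9), "range")
})

test_that("site classes partition the reference and match per-position classification", {
  ref <- random_reference(200, seed = 10)
  cls <- shm_site_classes(ref)
  expect_length(cls, 200)
  bases <- strsplit(ref, "")[[1]]
  expect_true(all(cls[bases %in% c("A", "T")] == "AT"))
  expect_true(all(cls[bases %in% c("C", "G")] %in% c("CG_WRC", "CG_nonWRC")))
})

test_that("alignment of identical and singly-substituted clones behaves as forced", {
  al0 <- align_clone("ACGTACGT", "ACGTACGT")
  rec0 <- call_mutations(al0, "c0")
  expect_equal(nrow(rec0$records), 0)

  al1 <- align_clone("ACGTACGT", "ACGAACGT")
  rec1 <- call_mutations(al1, "c1")
  expect_equal(rec1$records$position, 4L)
  expect_equal(rec1$records$ref_base, "T")
  expect_equal(rec1$records$obs_base, "A")
})

test_that("a diverged clone is rejected at the identity threshold", {
  ref <- random_reference(120, seed = 30)
  other <- random_reference(120, seed = 31)
  al <- align_clone(ref, other)
  expect_true(al$rejected)
  expect_error(call_mutations(al, "bad"), "rejected")
  res <- shm_analyze(tibble::tibble(clone_id = "bad", sequence = other), ref)
  expect_equal(res$rejected, "bad")
  expect_equal(res$spectrum$n_sequences, 0)
})

test_that("indels are excluded from substitution records but counted as events", {
  ref <- random_reference(100, seed = 12)
  clone <- paste0(substr(ref, 1, 40), substr(ref, 44, 100))  # 3-bp deletion
  al <- align_clone(ref, clone)
  rec <- call_mutations(al, "cdel")
  expect_equal(nrow(rec$records), 0)
  expect_equal(rec$n_indel_events, 1)
})

test_that("N bases are excluded from calls and tallied for the denominator", {
  ref <- "ACGTACGTACGT"
  clone <- "ACGTNCGTACGT"
  rec <- call_mutations(align_clone(ref, clone), "cN")
  expect_equal(nrow(rec$records), 0)
  expect_equal(rec$n_excluded, 1)
})

test_that("round trip: the analysis recovers the generator's planted truth exactly", {
  ref <- random_reference(300, seed = 14)
  sim <- sim_shm_clones(ref, n_clones = 20, per_base_rate = 5e-3,
                        hotspot_multiplier = 5, seed = 15)
  res <- shm_analyze(sim$clones, sim$reference)
  truth <- dplyr::arrange(sim$truth, clone_id, position)
  got <- dplyr::arrange(res$records[names(truth)], clone_id, position)
  expect_equal(as.data.frame(got), as.data.frame(truth))
})

test_that("spectrum summary arithmetic and degenerate cases", {
  recs <- tibble::tibble(
    clone_id = rep(sprintf("c%02d", 1:15), 1), position = 1:15,
    ref_base = "C", obs_base = "T",
    mut_class = rep(c("CG_WRC", "CG_nonWRC", "AT"), 5))
  sp <- summarize_spectrum(recs, sprintf("c%02d", 1:30), 500)
  expect_equal(sp$frequency, 1e-3)
  expect_equal(sum(sp$class_table$count), 15)
  expect_equal(sum(sp$load_histogram$proportion), 1)

  sp0 <- summarize_spectrum(recs[0, ], c("c1", "c2"), 100)
  expect_equal(sp0$frequency, 0)
  expect_equal(sp0$load_histogram$proportion[sp0$load_histogram$n_mutations == 0], 1)
  expect_error(summarize_spectrum(recs, character(), 100), "sequences")
})

test_that("the full pipeline is invariant under reverse complement", {
  ref <- random_reference(300, seed = 18)
  sim <- sim_shm_clones(ref, n_clones = 25, per_base_rate = 4e-3,
                        hotspot_multiplier = 4, seed = 19)
  fwd <- shm_analyze(sim$clones, ref)
  rc_clones <- dplyr::mutate(sim$clones, sequence = revcomp(sequence))
  rev <- shm_analyze(rc_clones, revcomp(ref))
  expect_equal(rev$spectrum$frequency, fwd$spectrum$frequency)
  expect_equal(rev$spectrum$n_mutations, fwd$spectrum$n_mutations)
  expect_equal(rev$spectrum$load_histogram, fwd$spectrum$load_histogram)
  expect_equal(rev$spectrum$class_table$count, fwd$spectrum$class_table$count)
})

test_that("hotspot enrichment in generated clones is recovered at the per-site level", {
  ref <- random_reference(600, seed = 22)
  sim <- sim_shm_clones(ref, n_clones = 300, per_base_rate = 2e-3,
                        hotspot_multiplier = 5, seed = 23)
  # edge-context mutations warn by design; irrelevant to the rate comparison
  res <- suppressWarnings(shm_analyze(sim$clones, ref))
  cls <- shm_site_classes(ref)
  n_hot <- sum(cls == "CG_WRC")
  n_cold <- sum(cls == "CG_nonWRC")
  ct <- table(factor(res$records$mut_class, levels = c("CG_WRC", "CG_nonWRC", "AT")))
  ratio <- (ct[["CG_WRC"]] / n_hot) / (ct[["CG_nonWRC"]] / n_cold)
  expect_gt(ratio, 5 * 0.7)
  expect_lt(ratio, 5 * 1.4)
})
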