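test_that("BirA* normalisation divides by the per-sample anchor and is idempotent", {
  fx <- tiny_counts(list(p1 = c(12, 8), BirA = c(4, 2)), n_replicates = 1,
                    baits = c("WT", "MUT1"))
  nm <- normalize_to_birA(fx$counts)
  expect_equal(nm$WT.1[nm$prey_id == "p1"], 3)
  expect_equal(nm$MUT1.1[nm$prey_id == "p1"], 4)
  expect_equal(as.numeric(nm[nm$prey_id == "BirA", -1]), c(1, 1))
  # idempotence
  nm2 <- normalize_to_birA(nm)
  expect_equal(nm2, nm)
})

test_that("normalisation is invariant to per-sample scaling and errors on zero BirA*", {
  sim <- sim_bioid(n_preys = 20, n_planted = 0, seed = 2)
  nm1 <- normalize_to_birA(sim$counts)
  scaled <- sim$counts
  scaled[[2]] <- scaled[[2]] * 2L          # whole sample, BirA included
  expect_equal(normalize_to_birA(scaled), nm1)

  bad <- sim$counts
  bad[bad$prey_id == "BirA", "WT.2"] <- 0L
  expect_error(normalize_to_birA(bad), "WT\\.2")
})

test_that("duplicate prey ids are rejected case-insensitively", {
  fx <- tiny_counts(list(Abc = 1, ABC = 2), n_replicates = 1)
  expect_error(normalize_to_birA(fx$counts), "duplicate")
})

test_that("fold enrichment: arithmetic, identity and reciprocal symmetry", {
  fx <- tiny_counts(list(p1 = 1, p2 = 1), n_replicates = 2)
  nm <- normalize_to_birA(fx$counts)
  # overwrite normalised values by hand for exact arithmetic
  nm[nm$prey_id == "p1", c("WT.1", "WT.2")] <- list(2.0, 4.0)
  nm[nm$prey_id == "p1", c("MUT1.1", "MUT1.2")] <- list(1.0, 1.0)
  f <- fold_enrichment(nm, fx$meta, "WT", "MUT1", pseudocount = 0)
  expect_equal(f$fold[f$prey_id == "p1"], 3.0)

  sim <- sim_bioid(n_preys = 30, n_planted = 0, seed = 5)
  nms <- normalize_to_birA(sim$counts)
  fab <- fold_enrichment(nms, sim$meta, "WT", "MUT1", pseudocount = 0.3)
  fba <- fold_enrichment(nms, sim$meta, "MUT1", "WT", pseudocount = 0.3)
  expect_equal(fab$fold * fba$fold, rep(1, nrow(fab)))
  # A = B gives fold 1
  faa <- fold_enrichment(nms, sim$meta, "WT", "WT", pseudocount = 0.3)
  expect_equal(faa$fold, rep(1, nrow(faa)))
  expect_error(fold_enrichment(nms, sim$meta, "WT", "NOPE"), "bait")
})

test_that("fold-method thresholds are joint over both mutants plus the control filter, inclusive", {
  folds <- tibble::tibble(
    prey_id = c("called", "fails_one_mutant", "boundary", "nonspecific"),
    fold_mut1 = c(5, 2.4, 2.5, 6),
    fold_mut2 = c(3, 10, 2.5, 6),
    fold_a2 = c(6, 10, 5.0, 4.9)
  )
  res <- call_fold(folds)
  expect_equal(res$called,
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("global Z-scores use the sample sd and flag only at >= 2 sd above the mean", {
  d <- tibble::tibble(prey_id = paste0("p", 1:5), log_fold = c(1, 1, 1, 1, 6))
  res <- call_normz(d)
  expect_equal(res$z[5], 4 / sqrt(5), tolerance = 1e-12)
  expect_false(res$flagged[5])          # 1.789 < 2
  # standardisation identity
  sim <- withr::with_seed(1, tibble::tibble(prey_id = paste0("p", 1:50),
                                            log_fold = rnorm(50)))
  z <- call_normz(sim)$z
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # degenerate constant vector: warning, no flags
  const <- tibble::tibble(prey_id = paste0("p", 1:4), log_fold = rep(2, 4))
  expect_warning(res0 <- call_normz(const), "zero")
  expect_false(any(res0$flagged))
  expect_error(call_normz(const[1:2, ]), "3 finite")
})

test_that("Maz window size has the minimum-window floor and needs enough preys", {
  d <- withr::with_seed(2, tibble::tibble(prey_id = sprintf("p%02d", 1:20),
                                          ratio = rnorm(20), intensity = rnorm(20)))
  # w = max(5, ceiling(0.1 * 20)) = 5: windows of 5 reproduce by brute force
  res <- call_maz(d, window_frac = 0.10, min_window = 5)
  i <- 7
  win <- order(abs(d$intensity - d$intensity[i]), rank(d$prey_id))[1:5]
  expect_equal(res$local_z[i],
               (d$ratio[i] - mean(d$ratio[win])) / stats::sd(d$ratio[win]))
  expect_error(call_maz(d[1:4, ]), "window")
})

test_that("Maz with a full window equals the global Z-score exactly", {
  d <- withr::with_seed(3, tibble::tibble(prey_id = sprintf("p%03d", 1:80),
                                          ratio = rnorm(80),
                                          intensity = rnorm(80)))
  maz <- call_maz(d, window_frac = 1.0)
  normz <- call_normz(dplyr::rename(d, log_fold = "ratio"))
  expect_identical(maz$local_z, normz$z)
  expect_identical(maz$flagged, normz$flagged)
})

test_that("consensus counts methods per prey and applies the >=1 / >=2 rules", {
  preys <- c("a", "b", "c", "d")
  mk <- function(called) tibble::tibble(prey_id = preys, called = called)
  cons <- consensus(list(
    Fold = mk(c(TRUE, TRUE, FALSE, FALSE)),
    Normz = mk(c(TRUE, FALSE, FALSE, FALSE)),
    Maz = mk(c(FALSE, FALSE, FALSE, FALSE)),
    Deseq = mk(c(TRUE, FALSE, TRUE, FALSE))
  ))
  expect_equal(cons$n_methods, c(3L, 1L, 1L, 0L))
  expect_equal(cons$in_union, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cons$in_core, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cons$methods_calling[1], "Fold,Normz,Deseq")
  expect_true(all(cons$in_core <= cons$in_union))
  # empty call sets give empty union and core
  cons0 <- consensus(list(Fold = mk(rep(FALSE, 4)), Normz = mk(rep(FALSE, 4))))
  expect_equal(sum(cons0$in_union), 0)
  # mismatched universes are an error
  expect_error(consensus(list(
    Fold = mk(rep(TRUE, 4)),
    Normz = tibble::tibble(prey_id = c("a", "b"), called = c(TRUE, TRUE))
  )), "universe")
})

test_that("bioid_diff recovers planted interactors and its accessors are coherent", {
  sim <- sim_bioid(n_preys = 150, n_planted = 8, effect_size = 8, seed = 13)
  res <- bioid_diff(sim$counts, sim$meta)
  cons <- tidy(res)
  core <- cons$prey_id[cons$in_core]
  expect_gte(mean(sim$truth$planted_preys %in% core), 0.9)
  g <- glance(res)
  expect_equal(g$n_core, sum(cons$in_core))
  expect_lte(g$n_core, g$n_union)
  expect_lte(g$n_union, g$n_preys)
  expect_s3_class(autoplot(res), "ggplot")
  expect_output(print(res), "core")
})
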