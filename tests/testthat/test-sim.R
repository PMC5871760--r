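test_that("sim_bioid is deterministic under a fixed seed and validates config", {
  a <- sim_bioid(n_preys = 40, n_planted = 5, seed = 7)
  b <- sim_bioid(n_preys = 40, n_planted = 5, seed = 7)
  expect_identical(a, b)
  c <- sim_bioid(n_preys = 40, n_planted = 5, seed = 8)
  expect_false(identical(a$counts, c$counts))

  expect_error(sim_bioid(n_preys = 10, n_planted = 11), "n_planted")
  expect_error(sim_bioid(effect_size = 0.5), "effect_size")
  expect_error(sim_bioid(base_mean = 0), "means")
})

test_that("sim_bioid structure: all four baits, BirA row present and nonzero", {
  sim <- sim_bioid(n_preys = 30, n_planted = 3, n_replicates = 3, seed = 1)
  expect_setequal(unique(sim$meta$bait), c("WT", "MUT1", "MUT2", "A2"))
  expect_equal(nrow(sim$meta), 12)
  expect_true("BirA" %in% sim$counts$prey_id)
  birA <- as.numeric(sim$counts[sim$counts$prey_id == "BirA", -1])
  expect_true(all(birA > 0))
  expect_true(all(sim$truth$planted_preys %in% sim$counts$prey_id))
})

test_that("planted preys show the configured fold-reduction in both mutants", {
  sim <- sim_bioid(n_preys = 500, n_planted = 20, effect_size = 8,
                   base_mean = 50, dispersion = 0.05, n_replicates = 3,
                   seed = 1)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$prey_id
  planted <- sim$truth$planted_preys
  wt_cols <- sim$meta$sample_id[sim$meta$bait == "WT"]
  mut_cols <- sim$meta$sample_id[sim$meta$bait %in% c("MUT1", "MUT2")]
  ratio <- sum(m[planted, wt_cols]) / length(wt_cols) /
    (sum(m[planted, mut_cols]) / length(mut_cols))
  expect_gt(ratio, 8 * 0.75)
  expect_lt(ratio, 8 * 1.25)
})

test_that("sim_bioid null case: effect_size 1 leaves planted preys unmarked in expectation", {
  sim <- sim_bioid(n_preys = 200, n_planted = 20, effect_size = 1,
                   base_mean = 50, n_replicates = 3, seed = 11)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$prey_id
  wt_cols <- sim$meta$sample_id[sim$meta$bait == "WT"]
  mut_cols <- sim$meta$sample_id[sim$meta$bait %in% c("MUT1", "MUT2")]
  planted <- sim$truth$planted_preys
  ratio <- sum(m[planted, wt_cols]) / length(wt_cols) /
    (sum(m[planted, mut_cols]) / length(mut_cols))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("sim_bioid marginal counts match the NB mean-variance relation", {
  # constant per-prey mean so all draws share one NB(mu, alpha) marginal
  sim <- sim_bioid(n_preys = 3000, n_planted = 0, base_mean = 50,
                   dispersion = 0.05, n_replicates = 4, mean_sdlog = 0,
                   seed = 21)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$prey_id
  wt <- as.vector(m[rownames(m) != "BirA",
                    sim$meta$sample_id[sim$meta$bait == "WT"]])
  expect_equal(mean(wt), 50, tolerance = 0.02)
  expect_equal(stats::var(wt), 50 + 0.05 * 50^2, tolerance = 0.1)
})

test_that("sim_shm_clones: zero rate gives reference clones, hotspot symmetry at multiplier 1", {
  ref <- random_reference(400)
  sim0 <- sim_shm_clones(ref, n_clones = 10, per_base_rate = 0, seed = 3)
  expect_true(all(sim0$clones$sequence == ref))
  expect_equal(nrow(sim0$truth), 0)

  sim1 <- sim_shm_clones(ref, n_clones = 400, per_base_rate = 0.01,
                         hotspot_multiplier = 1, seed = 4)
  cls <- shm_site_classes(ref)
  hits <- table(factor(shm_site_classes(ref)[sim1$truth$position],
                       levels = c("CG_WRC", "CG_nonWRC", "AT")))
  site_n <- table(factor(cls, levels = c("CG_WRC", "CG_nonWRC", "AT")))
  rate_hot <- hits[["CG_WRC"]] / (site_n[["CG_WRC"]] * 400)
  rate_cold <- hits[["CG_nonWRC"]] / (site_n[["CG_nonWRC"]] * 400)
  expect_equal(rate_hot / rate_cold, 1, tolerance = 0.35)
  expect_error(sim_shm_clones(ref, per_base_rate = 0.3, hotspot_multiplier = 5),
               "rate")
})

test_that("sim_fluctuation: zero frequency gives all-zero Rif-R; median estimator is consistent", {
  z <- sim_fluctuation(0, n_cultures = 20, seed = 5)
  expect_true(all(z$rifR == 0))
  expect_identical(sim_fluctuation(300, seed = 9), sim_fluctuation(300, seed = 9))

  big <- sim_fluctuation(300, n_cultures = 200, ampR_mean = 1e8, seed = 6)
  est <- rifR_frequency(big)$median_freq_per_1e9
  expect_gt(est, 300 * 0.85)
  expect_lt(est, 300 * 1.15)
})

test_that("sim_qpcr: ten-fold dilution at perfect efficiency steps Ct by log2(10)", {
  sim <- sim_qpcr(c(a = 1), efficiency = 2, noise_sd = 0,
                  dilutions = c(1, 0.1, 0.01), seed = 1)
  std <- sim$plate[sim$plate$sample_kind == "standard", ]
  expect_equal(diff(std$ct), rep(log2(10), 2), tolerance = 1e-10)
  expect_error(sim_qpcr(c(a = 1), efficiency = 2.5), "efficiency")
  expect_error(sim_qpcr(c(a = -1)), "true_percent")
})
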