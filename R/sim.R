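#' Simulate a BioID spectral-count experiment with planted differential preys
#'
#' Generates a prey-by-sample table of raw spectral counts for four baits:
#' the wild-type deaminase fusion (`WT`), two loss-of-interaction mutants
#' (`MUT1`, `MUT2`) and the paralogue control bait (`A2`), each with
#' `n_replicates` samples. Counts are negative-binomial draws
#' (variance = mu + dispersion * mu^2). A subset of preys is "planted": their
#' expected BirA*-normalised abundance is reduced `effect_size`-fold in both
#' mutants relative to WT; all other preys share their mean across WT and the
#' mutants. Every prey's A2 mean is `a2_background_frac` times its WT mean,
#' emulating nonspecific background labelling by the control bait. A dedicated
#' BirA* self-biotinylation row (the normalisation anchor) is present in every
#' sample and is resampled away from zero, as the bait fusion always labels
#' itself.
#'
#' Per-prey expected WT counts are drawn log-normally around `base_mean`
#' (`mean_sdlog` on the log scale) so prey abundances span a realistic range
#' and the ratio-intensity plot used by the local Z-score method is
#' non-degenerate.
#'
#' @param n_preys Number of candidate preys (excluding the BirA* row).
#' @param n_planted Number of preys with a planted fold-reduction.
#' @param effect_size Fold-reduction (>= 1) applied in both mutant baits.
#' @param base_mean Median expected raw spectral count of a prey in WT.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param n_replicates Replicates per bait.
#' @param birA_mean Expected spectral count of the BirA* row.
#' @param a2_background_frac Fraction of the WT signal present in the A2
#'   control bait.
#' @param mean_sdlog Log-scale s.d. of per-prey expected counts.
#' @param seed Integer seed; identical seed gives identical output.
#' @return List with `counts` (tibble: prey_id then one column per sample
#'   named bait.replicate), `meta` (tibble: sample_id, bait, replicate),
#'   `birA_prey_id`, and `truth` (list with `planted_preys`).
#' @export
sim_bioid <- function(n_preys = 500, n_planted = 20, effect_size = 8,
                      base_mean = 50, dispersion = 0.05, n_replicates = 3,
                      birA_mean = 200, a2_background_frac = 0.1,
                      mean_sdlog = 0.8, seed = 1) {
  if (n_planted > n_preys) rlang::abort("n_planted must be <= n_preys")
  if (effect_size < 1) rlang::abort("effect_size must be >= 1")
  if (dispersion < 0) rlang::abort("dispersion must be >= 0")
  if (base_mean <= 0 || birA_mean <= 0 || a2_background_frac <= 0) {
    rlang::abort("all means must be > 0")
  }
  withr::with_seed(seed, {
    prey_ids <- sprintf("prey_%04d", seq_len(n_preys))
    planted <- if (n_planted > 0) sample(prey_ids, n_planted) else character()

    mu_wt <- stats::rlnorm(n_preys, meanlog = log(base_mean), sdlog = mean_sdlog)
    names(mu_wt) <- prey_ids
    mu_mut <- mu_wt
    mu_mut[planted] <- mu_wt[planted] / effect_size
    mu_a2 <- a2_background_frac * mu_wt

    baits <- c("WT", "MUT1", "MUT2", "A2")
    meta <- tidyr::expand_grid(bait = baits, replicate = seq_len(n_replicates)) |>
      dplyr::mutate(sample_id = paste(.data$bait, .data$replicate, sep = ".")) |>
      dplyr::select("sample_id", "bait", "replicate")

    rnb <- function(mu) {
      if (dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else stats::rpois(length(mu), mu)
    }
    draw <- function(bait) {
      mu <- switch(bait, WT = mu_wt, MUT1 = mu_mut, MUT2 = mu_mut, A2 = mu_a2)
      rnb(mu)
    }
    counts <- matrix(0L, nrow = n_preys + 1L, ncol = nrow(meta),
                     dimnames = list(c(prey_ids, "BirA"), meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      counts[seq_len(n_preys), j] <- draw(meta$bait[j])
      b <- rnb(birA_mean)
      while (b == 0) b <- rnb(birA_mean)   # the bait always self-biotinylates
      counts[n_preys + 1L, j] <- b
    }
    list(
      counts = tibble::as_tibble(counts, rownames = "prey_id"),
      meta = meta,
      birA_prey_id = "BirA",
      truth = list(planted_preys = sort(planted))
    )
  })
}

#' Simulate point-mutated clone sequences with WRC/GYW hotspot bias
#'
#' Each clone is the reference with independent per-site substitutions. The
#' substitution probability is `per_base_rate` except at hotspot sites
#' (C in WRC or G in GYW context, classified by [shm_site_classes()], the same
#' classifier the analysis uses) where it is multiplied by
#' `hotspot_multiplier`. Substituted bases are drawn uniformly from the three
#' alternatives. The returned truth lists every introduced change.
#'
#' @param reference DNA string over A/C/G/T.
#' @param n_clones Number of clones.
#' @param per_base_rate Substitution probability at non-hotspot sites.
#' @param hotspot_multiplier Rate multiplier at hotspot sites.
#' @param seed Integer seed.
#' @return List with `clones` (tibble: clone_id, sequence), `reference`, and
#'   `truth` (tibble: clone_id, position, ref_base, obs_base).
#' @export
sim_shm_clones <- function(reference, n_clones = 50, per_base_rate = 1e-3,
                           hotspot_multiplier = 5, seed = 1) {
  reference <- toupper(reference)
  cls <- shm_site_classes(reference)
  rates <- ifelse(cls == "CG_WRC", per_base_rate * hotspot_multiplier,
                  per_base_rate)
  if (any(rates > 1) || any(rates < 0)) {
    rlang::abort("effective per-site rate outside [0, 1]")
  }
  bases <- strsplit(reference, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(n_clones), function(i) {
      hit <- which(stats::runif(length(bases)) < rates)
      seq_i <- bases
      obs <- character(length(hit))
      for (k in seq_along(hit)) {
        alt <- setdiff(acgt, bases[hit[k]])
        obs[k] <- sample(alt, 1)
        seq_i[hit[k]] <- obs[k]
      }
      list(sequence = paste(seq_i, collapse = ""),
           truth = tibble::tibble(
             clone_id = sprintf("clone_%03d", i),
             position = as.integer(hit),
             ref_base = bases[hit], obs_base = obs))
    })
    list(
      clones = tibble::tibble(
        clone_id = sprintf("clone_%03d", seq_len(n_clones)),
        sequence = purrr::map_chr(out, "sequence")),
      reference = reference,
      truth = purrr::map(out, "truth") |> purrr::list_rbind()
    )
  })
}

#' Simulate a rifampicin-resistance fluctuation experiment
#'
#' Parallel independent cultures plated for total viable (ampicillin-
#' resistant) and mutant (rifampicin-resistant) colony-forming units. Each
#' culture's viable count is Poisson around `ampR_mean`; its Rif-R count is
#' Poisson with mean `freq_per_1e9 * ampR / 1e9`.
#'
#' @param freq_per_1e9 True mutation frequency per 1e9 viable cells.
#' @param n_cultures Number of independent cultures.
#' @param ampR_mean Expected viable cfu per culture.
#' @param construct Construct label carried into the table.
#' @param experiment Experiment identifier.
#' @param seed Integer seed.
#' @return Tibble: construct, experiment, culture, rifR, ampR.
#' @export
sim_fluctuation <- function(freq_per_1e9, n_cultures = 5, ampR_mean = 1e8,
                            construct = "AID", experiment = "exp1", seed = 1) {
  if (freq_per_1e9 < 0) rlang::abort("freq_per_1e9 must be >= 0")
  withr::with_seed(seed, {
    ampR <- stats::rpois(n_cultures, ampR_mean)
    rifR <- stats::rpois(n_cultures, freq_per_1e9 * ampR / 1e9)
    tibble::tibble(construct = construct, experiment = experiment,
                   culture = seq_len(n_cultures),
                   rifR = rifR, ampR = ampR)
  })
}

#' Simulate a ChIP-qPCR plate with input standard curves
#'
#' For each amplicon, an input dilution series (quantity 1 is the undiluted
#' input aliquot, itself `input_fraction` of the chromatin used per IP) plus
#' one IP and one IgG-control measurement. Ct values follow the log-linear
#' amplification model Ct = intercept - log(q) / log(efficiency) + noise.
#'
#' @param true_percent Named numeric: true percent-input recovered by the IP
#'   for each amplicon.
#' @param efficiency Amplification factor per cycle, in (1, 2].
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param input_fraction Fraction of the IP chromatin in the undiluted input.
#' @param dilutions Input dilution series (quantities relative to undiluted).
#' @param intercept Ct of quantity 1.
#' @param igg_percent Percent-input recovered by the IgG control (scalar or
#'   named per amplicon).
#' @param seed Integer seed.
#' @return List with `plate` (tibble: amplicon, sample_kind in
#'   standard/IP/IgG, dilution, ct) and `truth` (the `true_percent` input).
#' @export
sim_qpcr <- function(true_percent, efficiency = 2, noise_sd = 0,
                     input_fraction = 0.1,
                     dilutions = c(1, 0.1, 0.01, 0.001),
                     intercept = 20, igg_percent = 0.05, seed = 1) {
  if (efficiency <= 1 || efficiency > 2) rlang::abort("efficiency must be in (1, 2]")
  if (any(true_percent <= 0)) rlang::abort("true_percent must be > 0")
  if (is.null(names(true_percent))) {
    names(true_percent) <- sprintf("amplicon_%d", seq_along(true_percent))
  }
  igg <- rep_len(igg_percent, length(true_percent))
  names(igg) <- names(true_percent)
  ct_of <- function(q) intercept - log(q) / log(efficiency)
  withr::with_seed(seed, {
    plate <- purrr::map(names(true_percent), function(a) {
      q_ip <- (true_percent[[a]] / 100) / input_fraction
      q_igg <- (igg[[a]] / 100) / input_fraction
      tibble::tibble(
        amplicon = a,
        sample_kind = c(rep("standard", length(dilutions)), "IP", "IgG"),
        dilution = c(dilutions, NA, NA),
        ct = ct_of(c(dilutions, q_ip, q_igg))
      )
    }) |> purrr::list_rbind()
    plate$ct <- plate$ct + stats::rnorm(nrow(plate), 0, noise_sd)
    list(plate = plate, truth = true_percent)
  })
}
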