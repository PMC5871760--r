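validate_sc <- function(counts, meta = NULL, birA = "BirA") {
  stopifnot(is.data.frame(counts), "prey_id" %in% names(counts))
  prey <- trimws(counts$prey_id)
  dup <- prey[duplicated(tolower(prey))]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate prey ids (case-insensitive): ",
                        paste(unique(dup), collapse = ", ")))
  }
  vals <- as.matrix(counts[setdiff(names(counts), "prey_id")])
  if (any(vals < 0)) rlang::abort("negative counts")
  if (!is.null(meta)) {
    missing <- setdiff(colnames(vals), meta$sample_id)
    if (length(missing) > 0) {
      rlang::abort(paste0("samples missing from metadata: ",
                          paste(missing, collapse = ", ")))
    }
  }
  if (!tolower(birA) %in% tolower(prey)) {
    rlang::abort(sprintf("BirA* row '%s' not found among prey ids", birA))
  }
  invisible(counts)
}

sc_matrix <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "prey_id")])
  rownames(m) <- counts$prey_id
  m
}

#' Normalise spectral counts to the BirA* self-biotinylation level
#'
#' Divides every prey's count by the BirA* count of the same sample, putting
#' all samples on the scale of bait-fusion labelling activity. The BirA* row
#' becomes exactly 1 in every sample, so the operation is idempotent.
#'
#' @param counts Tibble: `prey_id` plus one integer column per sample.
#' @param birA Prey id of the BirA* row (case-insensitive after trimming).
#' @return Tibble of the same shape with normalised (double) values.
#' @export
normalize_to_birA <- function(counts, birA = "BirA") {
  validate_sc(counts, birA = birA)
  m <- sc_matrix(counts)
  bi <- which(tolower(trimws(rownames(m))) == tolower(trimws(birA)))
  bvals <- m[bi, ]
  zero <- colnames(m)[bvals == 0]
  if (length(zero) > 0) {
    rlang::abort(paste0("BirA* count is zero in sample(s): ",
                        paste(zero, collapse = ", ")))
  }
  nm <- sweep(m, 2, bvals, "/")
  tibble::as_tibble(nm, rownames = "prey_id")
}

bait_means <- function(nm, meta, bait) {
  m <- sc_matrix(nm)
  cols <- meta$sample_id[meta$bait == bait]
  if (length(cols) == 0) rlang::abort(sprintf("unknown or absent bait '%s'", bait))
  rowMeans(m[, cols, drop = FALSE])
}

default_pseudocount <- function(nm) {
  m <- sc_matrix(nm)
  pos <- m[m > 0]
  if (length(pos) == 0) return(0.5)
  0.5 * min(pos)
}

#' Fold enrichment between two baits on normalised counts
#'
#' fold(p) = (mean_A(p) + c) / (mean_B(p) + c) over each bait's replicates,
#' with pseudocount c. The default pseudocount is half the smallest nonzero
#' normalised value in the matrix, since zero spectral counts are common.
#'
#' @param nm Normalised tibble from [normalize_to_birA()].
#' @param meta Sample metadata tibble (`sample_id`, `bait`, `replicate`).
#' @param bait_a,bait_b Bait labels (numerator, denominator).
#' @param pseudocount Pseudocount c; `NULL` for the data-driven default.
#' @return Tibble: `prey_id`, `fold`.
#' @export
fold_enrichment <- function(nm, meta, bait_a, bait_b, pseudocount = NULL) {
  c0 <- if (is.null(pseudocount)) default_pseudocount(nm) else pseudocount
  a <- bait_means(nm, meta, bait_a)
  b <- bait_means(nm, meta, bait_b)
  tibble::tibble(prey_id = nm$prey_id, fold = unname((a + c0) / (b + c0)))
}

#' Call differential preys by joint fold-enrichment thresholds
#'
#' A prey is called reduced-in-both-mutants when its WT-over-mutant fold
#' enrichment is at least `t_mut` for both mutants AND its WT-over-control
#' (APOBEC2) fold is at least `t_a2` (the specificity filter). Thresholds are
#' inclusive. The opposite direction (at least `t_mut`-fold enrichment in both
#' mutants over WT) is reported as `increased` but is not a consensus call.
#'
#' @param folds Tibble with columns `prey_id`, `fold_mut1`, `fold_mut2`
#'   (WT over each mutant) and `fold_a2` (WT over control bait).
#' @param t_mut Fold threshold versus each mutant (default 2.5).
#' @param t_a2 Fold threshold versus the control bait (default 5).
#' @return Input tibble plus logical `reduced_mut1`, `reduced_mut2`,
#'   `specific`, `called`, `increased`.
#' @export
call_fold <- function(folds, t_mut = 2.5, t_a2 = 5) {
  stopifnot(all(c("prey_id", "fold_mut1", "fold_mut2", "fold_a2") %in% names(folds)))
  dplyr::mutate(
    folds,
    reduced_mut1 = .data$fold_mut1 >= t_mut,
    reduced_mut2 = .data$fold_mut2 >= t_mut,
    specific = .data$fold_a2 >= t_a2,
    called = .data$reduced_mut1 & .data$reduced_mut2 & .data$specific,
    increased = .data$fold_mut1 <= 1 / t_mut & .data$fold_mut2 <= 1 / t_mut
  )
}

#' Global Z-scores on log fold-enrichment values
#'
#' Standardises the per-prey log2 fold enrichments (WT over one mutant) with
#' the sample standard deviation (n - 1) and flags preys at `z_thresh` or more
#' standard deviations above the mean, i.e. WT-enriched.
#'
#' @param data Tibble with `prey_id` and `log_fold` (log2 fold, WT over
#'   mutant).
#' @param z_thresh Z-score threshold (default 2).
#' @return Input tibble plus `z` and logical `flagged`.
#' @export
call_normz <- function(data, z_thresh = 2) {
  stopifnot(all(c("prey_id", "log_fold") %in% names(data)))
  x <- data$log_fold
  if (sum(is.finite(x)) < 3) rlang::abort("need at least 3 finite log-fold values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    rlang::warn("zero standard deviation of log folds; all Z-scores set to 0")
    z <- rep(0, length(x))
  } else {
    z <- (x - mean(x)) / s
  }
  dplyr::mutate(data, z = z, flagged = z >= z_thresh)
}

maz_window <- function(intensity, order_key, i, w) {
  d <- abs(intensity - intensity[i])
  order(d, order_key)[seq_len(w)]
}

#' Local Z-scores in a sliding window on the ratio-intensity plot
#'
#' For each prey, takes the `w` preys nearest in intensity (log2 mean
#' abundance), with `w = max(min_window, ceiling(window_frac * n))`, candidate
#' included and intensity ties broken by prey-id order; standardises the
#' candidate's ratio (log2 fold) against the window with the sample standard
#' deviation; flags local Z at or above `z_thresh`. With `window_frac = 1`
#' this reduces exactly to the global Z-score of [call_normz()].
#'
#' @param data Tibble with `prey_id`, `ratio` (log2 fold, WT over mutant) and
#'   `intensity` (log2 mean abundance).
#' @param window_frac Window size as a fraction of all preys (default 0.10).
#' @param z_thresh Z threshold (default 2).
#' @param min_window Minimum window size (default 5).
#' @return Input tibble plus `local_z` and logical `flagged`.
#' @export
call_maz <- function(data, window_frac = 0.10, z_thresh = 2, min_window = 5) {
  stopifnot(all(c("prey_id", "ratio", "intensity") %in% names(data)))
  n <- nrow(data)
  if (n < min_window) rlang::abort("fewer preys than the minimum window size")
  w <- max(min_window, ceiling(window_frac * n))
  w <- min(w, n)
  key <- order(data$prey_id)          # rank by prey id for tie-breaking
  rank_key <- match(seq_len(n), key)
  zero_sd <- FALSE
  local_z <- vapply(seq_len(n), function(i) {
    win <- maz_window(data$intensity, rank_key, i, w)
    r <- data$ratio[win]
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) {
      zero_sd <<- TRUE
      return(0)
    }
    (data$ratio[i] - mean(r)) / s
  }, numeric(1))
  if (zero_sd) rlang::warn("zero local standard deviation for some preys; their local Z set to 0")
  dplyr::mutate(data, local_z = local_z, flagged = local_z >= z_thresh)
}

#' Combine per-method calls into the consensus table
#'
#' A method "calls" a prey when its reduced-in-both-mutants criterion passes.
#' The union is every prey with at least one calling method; the core set is
#' every prey called by at least two of the four methods.
#'
#' @param calls Named list of tibbles, one per method, each with `prey_id`
#'   and logical `called`; all on the same prey universe.
#' @return Tibble: `prey_id`, `methods_calling` (comma-separated), `n_methods`,
#'   `in_union`, `in_core`.
#' @export
consensus <- function(calls) {
  stopifnot(is.list(calls), length(calls) >= 1, !is.null(names(calls)))
  universes <- purrr::map(calls, ~ sort(.x$prey_id))
  if (!all(purrr::map_lgl(universes, identical, universes[[1]]))) {
    rlang::abort("methods were computed on different prey universes")
  }
  wide <- purrr::imap(calls, function(d, nm) {
    stats::setNames(d[c("prey_id", "called")], c("prey_id", nm))
  }) |> purrr::reduce(dplyr::inner_join, by = "prey_id")
  method_names <- names(calls)
  flags <- as.matrix(wide[method_names])
  flags[is.na(flags)] <- FALSE
  tibble::tibble(
    prey_id = wide$prey_id,
    methods_calling = apply(flags, 1, function(f) paste(method_names[f], collapse = ",")),
    n_methods = as.integer(rowSums(flags)),
  ) |>
    dplyr::mutate(in_union = .data$n_methods >= 1L, in_core = .data$n_methods >= 2L)
}

#' Four-method differential-interactome analysis of a BioID experiment
#'
#' Runs the complete consensus procedure on a raw spectral-count table:
#' BirA* normalisation; (Fold) joint fold-enrichment thresholds with a
#' control-bait specificity filter; (Normz) global Z-scores on log2 fold
#' enrichments per mutant; (Maz) local Z-scores in a sliding intensity window
#' per mutant; (Deseq) a negative-binomial Wald test of WT against the pooled
#' mutants on raw counts with Benjamini-Hochberg correction. Fold, Normz and
#' Maz require their criterion versus both mutants; the NB test uses the
#' pooled-mutant contrast with the mutants as reference level. Preys called by
#' at least one method form the union; by at least two, the core consensus.
#'
#' @param counts Raw spectral-count tibble (`prey_id` + sample columns).
#' @param meta Sample metadata tibble (`sample_id`, `bait`, `replicate`).
#' @param birA Prey id of the BirA* normalisation row.
#' @param wt,mutants,control Bait labels (defaults WT, MUT1/MUT2, A2).
#' @param fold_thresh,a2_fold_thresh Fold-method thresholds (2.5, 5).
#' @param z_thresh Z threshold for Normz and Maz (2).
#' @param window_frac Maz window fraction (0.10).
#' @param alpha BH-adjusted p-value cutoff for the NB test (0.1).
#' @param pseudocount Pseudocount for folds; `NULL` for the default.
#' @return Object of class `bioid_consensus`: per-method tables, the
#'   consensus table and the parameters used. `tidy()` returns the consensus
#'   table, `glance()` a one-row summary, `autoplot()` the ratio-intensity
#'   plot coloured by number of calling methods.
#' @export
bioid_diff <- function(counts, meta, birA = "BirA", wt = "WT",
                       mutants = c("MUT1", "MUT2"), control = "A2",
                       fold_thresh = 2.5, a2_fold_thresh = 5, z_thresh = 2,
                       window_frac = 0.10, alpha = 0.1, pseudocount = NULL) {
  validate_sc(counts, meta, birA = birA)
  stopifnot(length(mutants) == 2)
  nm <- normalize_to_birA(counts, birA = birA)
  c0 <- if (is.null(pseudocount)) default_pseudocount(nm) else pseudocount

  f1 <- fold_enrichment(nm, meta, wt, mutants[1], c0)
  f2 <- fold_enrichment(nm, meta, wt, mutants[2], c0)
  fa <- fold_enrichment(nm, meta, wt, control, c0)
  folds <- tibble::tibble(prey_id = nm$prey_id, fold_mut1 = f1$fold,
                          fold_mut2 = f2$fold, fold_a2 = fa$fold)
  fold_tab <- call_fold(folds, t_mut = fold_thresh, t_a2 = a2_fold_thresh)

  # Normz and Maz work on log2 folds vs each mutant separately; both must flag
  wt_means <- bait_means(nm, meta, wt)
  per_mutant <- purrr::map(mutants, function(mu) {
    mu_means <- bait_means(nm, meta, mu)
    lf <- unname(log2((wt_means + c0) / (mu_means + c0)))
    intensity <- unname(log2((wt_means + mu_means) / 2 + c0))
    tibble::tibble(prey_id = nm$prey_id, log_fold = lf,
                   ratio = lf, intensity = intensity)
  })
  normz_tabs <- purrr::map(per_mutant, ~ call_normz(.x[c("prey_id", "log_fold")],
                                                    z_thresh = z_thresh))
  maz_tabs <- purrr::map(per_mutant,
                         ~ call_maz(.x[c("prey_id", "ratio", "intensity")],
                                    window_frac = window_frac, z_thresh = z_thresh))
  both <- function(tabs) {
    tibble::tibble(prey_id = tabs[[1]]$prey_id,
                   called = tabs[[1]]$flagged & tabs[[2]]$flagged)
  }

  nb_tab <- call_nb(counts, meta, wt = wt, mutants = mutants, alpha = alpha,
                    birA = birA)

  cons <- consensus(list(
    Fold = tibble::tibble(prey_id = fold_tab$prey_id, called = fold_tab$called),
    Normz = both(normz_tabs),
    Maz = both(maz_tabs),
    Deseq = tibble::tibble(prey_id = nb_tab$prey_id,
                           called = dplyr::coalesce(nb_tab$flagged, FALSE))
  ))

  structure(list(
    consensus = cons,
    fold = fold_tab,
    normz = stats::setNames(normz_tabs, mutants),
    maz = stats::setNames(maz_tabs, mutants),
    nb = nb_tab,
    normalized = nm,
    meta = meta,
    params = list(birA = birA, wt = wt, mutants = mutants, control = control,
                  fold_thresh = fold_thresh, a2_fold_thresh = a2_fold_thresh,
                  z_thresh = z_thresh, window_frac = window_frac, alpha = alpha,
                  pseudocount = c0, log_base = 2)
  ), class = "bioid_consensus")
}

#' @export
print.bioid_consensus <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "BioID differential interactome: %d preys\n  union (>=1 method): %d\n  core (>=2 methods): %d\n",
    g$n_preys, g$n_union, g$n_core))
  cat(sprintf("  per method: Fold %d, Normz %d, Maz %d, Deseq %d\n",
              g$n_fold, g$n_normz, g$n_maz, g$n_deseq))
  invisible(x)
}

#' @rdname bioid_diff
#' @param x A `bioid_consensus` object.
#' @param ... Unused.
#' @export
tidy.bioid_consensus <- function(x, ...) x$consensus

#' @rdname bioid_diff
#' @export
glance.bioid_consensus <- function(x, ...) {
  called_in <- function(m) sum(grepl(m, x$consensus$methods_calling, fixed = TRUE))
  tibble::tibble(
    n_preys = nrow(x$consensus),
    n_union = sum(x$consensus$in_union),
    n_core = sum(x$consensus$in_core),
    n_fold = called_in("Fold"),
    n_normz = called_in("Normz"),
    n_maz = called_in("Maz"),
    n_deseq = called_in("Deseq")
  )
}
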