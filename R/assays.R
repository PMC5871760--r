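#' Rifampicin-resistance mutation frequency from a fluctuation experiment
#'
#' Per culture, frequency = Rif-R cfu / Amp-R cfu x 1e9 (mutants per 1e9
#' viable cells); the per-construct summary is the median over cultures (mean
#' of the two central order statistics for even n). Optional per-culture
#' dilution factors multiply the raw cfu before the ratio is taken.
#'
#' @param cultures Tibble with columns `rifR`, `ampR` and optionally
#'   `construct`, `experiment`, `rifR_dilution`, `ampR_dilution`.
#' @return Tibble grouped by construct/experiment (when present) with
#'   `median_freq_per_1e9`, `n_cultures`, and a `frequencies` list-column of
#'   per-culture values.
#' @export
rifR_frequency <- function(cultures) {
  stopifnot(all(c("rifR", "ampR") %in% names(cultures)))
  if (any(cultures$ampR <= 0)) rlang::abort("ampR cfu must be > 0")
  if (any(cultures$rifR < 0)) rlang::abort("counts must be >= 0")
  dil <- function(col) if (col %in% names(cultures)) cultures[[col]] else 1
  rif <- cultures$rifR * dil("rifR_dilution")
  amp <- cultures$ampR * dil("ampR_dilution")
  d <- dplyr::mutate(cultures, freq_per_1e9 = rif / amp * 1e9)
  keys <- intersect(c("construct", "experiment"), names(d))
  dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))),
    median_freq_per_1e9 = stats::median(.data$freq_per_1e9),
    n_cultures = dplyr::n(),
    frequencies = list(.data$freq_per_1e9),
    .groups = "drop"
  )
}

#' Normalise per-construct summary statistics to a reference construct
#'
#' Within each experiment, divides every construct's statistic by the
#' reference construct's statistic; when a construct appears in several
#' experiments, the cross-experiment mean of its normalised values is
#' reported. This is the "normalised to wild-type" convention used for
#' mutation frequencies, IgM-loss and similar per-construct medians.
#'
#' @param summaries Tibble with columns `construct`, `statistic` and
#'   optionally `experiment`.
#' @param reference Label of the reference construct.
#' @return Tibble: `construct`, `normalized` (cross-experiment mean),
#'   `n_experiments`.
#' @export
normalize_to_reference <- function(summaries, reference) {
  stopifnot(all(c("construct", "statistic") %in% names(summaries)))
  d <- summaries
  if (!"experiment" %in% names(d)) d$experiment <- "exp1"
  per_exp <- d |>
    dplyr::group_by(.data$experiment) |>
    dplyr::group_modify(function(g, key) {
      ref <- g$statistic[g$construct == reference]
      if (length(ref) != 1) {
        rlang::abort(sprintf("reference construct '%s' absent (or duplicated) in experiment %s",
                             reference, key$experiment))
      }
      if (ref == 0) rlang::abort("reference statistic is zero; cannot normalise")
      dplyr::mutate(g, normalized = .data$statistic / ref)
    }) |>
    dplyr::ungroup()
  per_exp |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(normalized = mean(.data$normalized),
                     n_experiments = dplyr::n(), .groups = "drop")
}

#' Background-subtracted percent positive
#'
#' Subtracts the empty-vector (background) percentage from the observed one;
#' negative differences are floored at zero and flagged.
#'
#' @param pct_positive,pct_background Percentages in \[0, 100\] (vectorised).
#' @return Tibble: `percent`, `floored` (logical).
#' @export
background_subtracted_percent <- function(pct_positive, pct_background) {
  if (any(pct_positive < 0 | pct_positive > 100) ||
      any(pct_background < 0 | pct_background > 100)) {
    rlang::abort("percentages must be in [0, 100]")
  }
  diff <- pct_positive - pct_background
  tibble::tibble(percent = pmax(diff, 0), floored = diff < 0)
}

#' Normalise a competitive-growth ratio series
#'
#' Divides the GFP+/GFP- ratio series either by its first (day-0) value or by
#' its maximum.
#'
#' @param ratios Numeric GFP+/GFP- ratios ordered by timepoint.
#' @param mode `"relative_day0"` or `"relative_max"`.
#' @return Numeric normalised series.
#' @export
competitive_growth <- function(ratios, mode = c("relative_day0", "relative_max")) {
  mode <- match.arg(mode)
  if (length(ratios) < 2) rlang::abort("need at least 2 timepoints")
  norm <- switch(mode, relative_day0 = ratios[1], relative_max = max(ratios))
  if (!is.finite(norm) || norm <= 0) rlang::abort("normaliser must be > 0")
  ratios / norm
}

#' Proportion of signal in the nucleus
#'
#' 100 x nuclear signal / total signal, per cell.
#'
#' @param nuclear_signal,total_signal Non-negative signals (vectorised);
#'   nuclear must not exceed total.
#' @return Percentages.
#' @export
nuclear_fraction <- function(nuclear_signal, total_signal) {
  if (any(total_signal <= 0)) rlang::abort("total signal must be > 0")
  if (any(nuclear_signal < 0 | nuclear_signal > total_signal)) {
    rlang::abort("nuclear signal must be in [0, total]")
  }
  100 * nuclear_signal / total_signal
}

#' Proportion of cells with at least k foci
#'
#' @param foci_counts Per-cell focus counts (non-negative integers).
#' @param k Threshold (default 5, the usual damage-foci cutoff).
#' @return Percentage of cells with `foci_counts >= k`.
#' @export
foci_positive_fraction <- function(foci_counts, k = 5) {
  if (length(foci_counts) == 0) rlang::abort("empty input")
  if (any(foci_counts < 0)) rlang::abort("counts must be >= 0")
  100 * mean(foci_counts >= k)
}
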