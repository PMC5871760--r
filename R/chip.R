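#' Fit a qPCR standard curve from an input dilution series
#'
#' Least-squares fit of Ct = intercept + slope * log10(quantity). The
#' amplification efficiency is 10^(-1/slope) - 1 (1.0 means perfect
#' doubling). Warnings are emitted when the efficiency falls outside
#' \[0.8, 1.1\] or r-squared drops below 0.98; these are quality warnings, not
#' errors.
#'
#' @param standards Tibble with columns `quantity` (> 0, on the per-plate
#'   scale where 1 is the undiluted input aliquot) and `ct`.
#' @return Object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `ct_range`, `n_points`.
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("quantity", "ct") %in% names(standards)))
  q <- standards$quantity
  ct <- standards$ct
  if (length(unique(q)) < 3) rlang::abort("need at least 3 distinct standard quantities")
  if (any(q <= 0) || any(ct <= 0)) rlang::abort("quantities and Ct must be > 0")
  fit <- stats::lm(ct ~ log10(q))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) rlang::abort("non-negative standard-curve slope; dilution series is not amplifying")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  eff <- 10^(-1 / slope) - 1
  if (eff < 0.8 || eff > 1.1) {
    rlang::warn(sprintf("amplification efficiency %.2f outside [0.8, 1.1]", eff))
  }
  if (r2 < 0.98) rlang::warn(sprintf("standard curve r-squared %.3f below 0.98", r2))
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, efficiency = eff, ct_range = range(ct),
                 quantities = sort(unique(q)), n_points = length(q)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, intercept %.2f, r2 %.4f, efficiency %.2f\n",
              x$slope, x$intercept, x$r2, x$efficiency))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 efficiency = x$efficiency, n_points = x$n_points)
}

#' Percent input from an IP Ct and a standard curve
#'
#' Interpolates the IP quantity on the standard curve
#' (q = 10^((ct - intercept) / slope)) and expresses it as a percentage of
#' the chromatin used per IP:
#' percent = 100 * (q / q_unit) * input_fraction, where q_unit is the
#' largest standard quantity (the undiluted input aliquot). Anchoring on the
#' standards makes the result invariant to the per-plate quantity scale.
#' Ct values more than 3 cycles outside the standard range trigger an
#' extrapolation warning.
#'
#' @param ip_ct IP Ct value(s).
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param input_fraction Fraction of the IP chromatin in the undiluted input
#'   aliquot, in (0, 1].
#' @return Percent input (vectorised).
#' @export
percent_input <- function(ip_ct, curve, input_fraction) {
  stopifnot(inherits(curve, "standard_curve"))
  if (input_fraction <= 0 || input_fraction > 1) {
    rlang::abort("input_fraction must be in (0, 1]")
  }
  lo <- curve$ct_range[1] - 3
  hi <- curve$ct_range[2] + 3
  if (any(ip_ct < lo | ip_ct > hi)) {
    rlang::warn("Ct outside the standard range by more than 3 cycles; extrapolating")
  }
  q <- 10^((ip_ct - curve$intercept) / curve$slope)
  100 * (q / max(curve$quantities)) * input_fraction
}

#' Subtract the IgG-control percent input
#'
#' Reports the raw difference; negative values are retained (not clamped) and
#' flagged.
#'
#' @param sample_percent,igg_percent Percent-input values for the same
#'   amplicon (vectorised).
#' @return Tibble: `net_percent`, `negative` (logical flag).
#' @export
subtract_igg <- function(sample_percent, igg_percent) {
  if (length(igg_percent) == 0 || any(is.na(igg_percent))) {
    rlang::abort("missing IgG percent for amplicon")
  }
  d <- sample_percent - igg_percent
  tibble::tibble(net_percent = d, negative = d < 0)
}

#' Quantify a ChIP-qPCR plate
#'
#' Per amplicon: fits the standard curve from the input dilution series,
#' converts every IP and IgG Ct to percent input, and subtracts the IgG
#' control from each IP.
#'
#' @param plate Tibble with columns `amplicon`, `sample_kind` (one of
#'   `standard`, `IP`, `IgG`), `dilution` (for standards) and `ct`.
#' @param input_fraction Fraction of the IP chromatin in the undiluted input.
#' @return Object of class `chip_quant`: `results` (tibble: amplicon,
#'   percent_input, igg_percent, net_percent, negative) and `curves` (named
#'   list of `standard_curve`).
#' @export
chip_quantify <- function(plate, input_fraction) {
  stopifnot(all(c("amplicon", "sample_kind", "ct") %in% names(plate)))
  amplicons <- unique(plate$amplicon)
  curves <- list()
  rows <- purrr::map(amplicons, function(a) {
    pa <- plate[plate$amplicon == a, ]
    std <- pa[pa$sample_kind == "standard", ]
    if (nrow(std) < 3) rlang::abort(sprintf("amplicon '%s': fewer than 3 standard points", a))
    span <- log10(max(std$dilution) / min(std$dilution))
    if (span < 2) rlang::warn(sprintf("amplicon '%s': standards span under 2 logs", a))
    curve <- fit_standard_curve(tibble::tibble(quantity = std$dilution, ct = std$ct))
    curves[[a]] <<- curve
    ip <- pa[pa$sample_kind == "IP", ]
    igg <- pa[pa$sample_kind == "IgG", ]
    if (nrow(ip) == 0) return(NULL)
    if (nrow(igg) == 0) rlang::abort(sprintf("amplicon '%s': IP present but no IgG control", a))
    ip_pct <- percent_input(ip$ct, curve, input_fraction)
    igg_pct <- mean(percent_input(igg$ct, curve, input_fraction))
    net <- subtract_igg(ip_pct, igg_pct)
    tibble::tibble(amplicon = a, percent_input = ip_pct, igg_percent = igg_pct,
                   net_percent = net$net_percent, negative = net$negative)
  })
  structure(list(results = purrr::list_rbind(purrr::compact(rows)),
                 curves = curves, input_fraction = input_fraction),
            class = "chip_quant")
}

#' @export
print.chip_quant <- function(x, ...) {
  cat(sprintf("ChIP-qPCR quantification (%d amplicons, input fraction %g)\n",
              length(x$curves), x$input_fraction))
  print(x$results)
  invisible(x)
}

#' @rdname chip_quantify
#' @param x A `chip_quant` object.
#' @param ... Unused.
#' @export
tidy.chip_quant <- function(x, ...) x$results
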