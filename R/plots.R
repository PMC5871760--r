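#' Ratio-intensity plot of a BioID consensus result
#'
#' Scatter of log2 fold (WT over mutant) against log2 mean abundance, one
#' facet per mutant, coloured by the number of consensus methods calling each
#' prey.
#'
#' @param object A `bioid_consensus` from [bioid_diff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bioid_consensus <- function(object, ...) {
  d <- purrr::imap(object$maz, function(tab, mutant) {
    dplyr::mutate(tab, mutant = mutant)
  }) |> purrr::list_rbind() |>
    dplyr::left_join(object$consensus[c("prey_id", "n_methods")], by = "prey_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity, y = .data$ratio,
                                  colour = factor(.data$n_methods))) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::facet_wrap(~mutant) +
    ggplot2::labs(x = "log2 mean normalised abundance",
                  y = "log2 fold (WT / mutant)",
                  colour = "methods\ncalling") +
    ggplot2::theme_bw()
}

#' Mutation-load and hotspot-class panels of a spectrum
#'
#' Left: proportion of sequences carrying k mutations. Right: proportion of
#' mutations at hotspot (WRC/GYW) C:G, other C:G, and A:T sites.
#'
#' @param object An `shm_spectrum` from [summarize_spectrum()] (or the
#'   `spectrum` element of [shm_analyze()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shm_spectrum <- function(object, ...) {
  load_d <- dplyr::mutate(object$load_histogram, panel = "mutations per sequence",
                          x = as.character(.data$n_mutations))
  class_d <- dplyr::mutate(object$class_table, panel = "mutation class",
                           x = .data$mut_class)
  d <- dplyr::bind_rows(load_d[c("panel", "x", "proportion")],
                        class_d[c("panel", "x", "proportion")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.shm_spectrum
#' @export
autoplot.shm_result <- function(object, ...) autoplot(object$spectrum, ...)

#' Standard-curve plot
#'
#' Dilution-series points with the fitted log-linear line and the derived
#' efficiency in the subtitle.
#'
#' @param object A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- tibble::tibble(
    log_q = log10(object$quantities),
    ct = object$intercept + object$slope * log10(object$quantities)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_q, y = .data$ct)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log10 input quantity", y = "Ct",
                  subtitle = sprintf("slope %.3f, efficiency %.2f, r2 %.3f",
                                     object$slope, object$efficiency, object$r2)) +
    ggplot2::theme_bw()
}
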