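#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Verdict map of a parentage analysis
#'
#' One tile per offspring and locus, coloured by the Mendelian verdict;
#' father-mismatch tiles that are single-step slippage candidates are
#' outlined. Families are shown as facets.
#'
#' @param object An `msat_parentage` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msat_parentage
#' @export
autoplot.msat_parentage <- function(object, ...) {
  v <- object$verdicts
  v$verdict <- factor(v$verdict,
    levels = c("compatible", "father_mismatch", "mother_mismatch", "untestable")
  )
  ggplot2::ggplot(v, ggplot2::aes(
    x = factor(.data$locus, levels = unique(.data$locus)),
    y = .data$offspring, fill = .data$verdict
  )) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_point(
      data = dplyr::filter(v, .data$near_miss),
      shape = 1, size = 2
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family), scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(
        compatible = "#4d9e79", father_mismatch = "#d1495b",
        mother_mismatch = "#e0a020", untestable = "grey85"
      ),
      drop = FALSE
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "verdict") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-locus differentiation plot
#'
#' Bar chart of the per-locus Weir-Cockerham theta with the multi-locus
#' estimate as a reference line.
#'
#' @param object An `msat_fst` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msat_fst
#' @export
autoplot.msat_fst <- function(object, ...) {
  ggplot2::ggplot(object$per_locus, ggplot2::aes(
    x = stats::reorder(.data$locus, .data$theta), y = .data$theta
  )) +
    ggplot2::geom_col(fill = "#2e6f95") +
    ggplot2::geom_hline(yintercept = object$theta, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = expression(theta),
      subtitle = sprintf("multi-locus theta = %.4f", object$theta)
    ) +
    ggplot2::theme_minimal()
}

#' Allele frequency spectra
#'
#' Per-locus bar charts of sample allele frequencies (fragment size on the
#' x axis), optionally split by population.
#'
#' @inheritParams allele_frequencies
#' @param loci Optional subset of loci to show.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(x, loci = NULL, by = NULL, unrelated_only = FALSE) {
  f <- allele_frequencies(x, by = by, unrelated_only = unrelated_only)
  if (!is.null(loci)) f <- dplyr::filter(f, .data$locus %in% loci)
  p <- ggplot2::ggplot(f, ggplot2::aes(x = .data$allele, y = .data$freq))
  p <- if (is.null(by)) {
    p + ggplot2::geom_col(fill = "#2e6f95")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data[[by]]), position = "dodge")
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$locus), scales = "free_x") +
    ggplot2::labs(x = "fragment size (bp)", y = "frequency") +
    ggplot2::theme_minimal()
}
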