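#' Plot a metagene profile
#'
#' Line plot of mean normalized footprint 5'-end signal against offset from
#' the anchor codon.
#'
#' @param profile An `mrs_metagene` from [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  stopifnot(inherits(profile, "mrs_metagene"))
  anchor <- attr(profile, "anchor")
  ggplot2::ggplot(tibble::as_tibble(profile),
                  ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = sprintf("Offset from %s codon (nt)", anchor),
      y = "Mean normalized 5'-end signal",
      title = sprintf("Metagene profile (%d genes)", attr(profile, "n_genes_used"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metagene
#' @param object,... `autoplot` method arguments.
#' @method autoplot mrs_metagene
#' @export
autoplot.mrs_metagene <- function(object, ...) plot_metagene(object)

#' Plot reading-frame periodicity
#'
#' Bar chart of the three codon-frame fractions of in-ORF footprint 5' ends.
#'
#' @param periodicity One-row tibble from [frame_periodicity()].
#' @return A ggplot object.
#' @export
plot_periodicity <- function(periodicity) {
  df <- tibble::tibble(
    frame = factor(0:2),
    fraction = c(periodicity$frac0, periodicity$frac1, periodicity$frac2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = "Reading frame", y = "Fraction of 5' ends",
                  subtitle = sprintf("chi-square = %.1f, p = %.3g",
                                     periodicity$chi2, periodicity$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot taxon abundance composition
#'
#' Stacked bar of per-taxon read fractions (typically after [group_other()]).
#'
#' @param abundance Tibble with `taxon` and `fraction` columns, or a named
#'   list of them (one per assay).
#' @return A ggplot object.
#' @export
plot_taxon_abundance <- function(abundance) {
  if (is.data.frame(abundance)) abundance <- list(sample = abundance)
  df <- purrr::imap_dfr(abundance, function(a, nm) {
    a$assay <- nm
    a
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assay, y = .data$fraction,
                                   fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of classified reads", fill = "Taxon") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential test
#'
#' @param object An `mrs_diff` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrs_diff
#' @export
autoplot.mrs_diff <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "navy",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = sprintf("Contrast: %s", df$contrast[1])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
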