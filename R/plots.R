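#' Plot the distributions of fitted evolutionary parameters
#'
#' Density plot of the per-genome mutational bias and the strand-averaged
#' transcription- and translation-associated scaled selection coefficients,
#' split by basepair type — the package's analogue of the headline
#' parameter-distribution figure.
#'
#' @param object A `skew_fit` from [fit_skew_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skew_fit <- function(object, ...) {
  d <- object$params |>
    dplyr::filter(.data$quantity %in% c("mu_io", "s_rna", "s_aa"),
                  .data$strand == "mean" | .data$quantity == "mu_io",
                  is.finite(.data$value))
  labels <- c(mu_io = "mutational bias (interoperonic)",
              s_rna = "S_RNA (transcription)",
              s_aa = "S_AA (translation)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  colour = .data$quantity,
                                  linetype = .data$pair)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::scale_colour_discrete(labels = labels) +
    ggplot2::labs(x = "estimate", y = "density",
                  colour = NULL, linetype = "basepair") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Amplification of mutational bias in transcribed regions
#'
#' Scatter of the fourfold-site mutational bias against the interoperonic
#' bias per genome, with the fitted regression through the origin whose
#' slope is the global amplification factor tau.
#'
#' @param fit A `skew_fit`.
#' @return A ggplot object.
#' @export
plot_tau_fit <- function(fit) {
  wide <- fit$params |>
    dplyr::filter(.data$quantity %in% c("mu_io", "mu_4s")) |>
    tidyr::pivot_wider(id_cols = c("genome_id", "pair"),
                       names_from = "quantity", values_from = "value")
  taus <- fit$global[, c("pair", "tau")]
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$mu_io, y = .data$mu_4s)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(data = taus,
                         ggplot2::aes(slope = .data$tau, intercept = 0),
                         colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair), scales = "free") +
    ggplot2::labs(x = "mutational bias, interoperonic",
                  y = "mutational bias, fourfold sites") +
    ggplot2::theme_minimal()
}

#' Plot the codon-table cost trade-off grid
#'
#' Mean amino-acid cost against mean nucleotide cost over the simulated
#' GC-content-by-skew grid, coloured by GC content: the negative
#' relationship is the trade-off by which expensive nucleotides encode
#' cheap amino acids.
#'
#' @param grid Output of [simulate_tradeoff_grid()].
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$mean_nt_cost,
                                     y = .data$mean_aa_cost,
                                     colour = .data$gc)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "GC content") +
    ggplot2::labs(x = "mean nucleotide cost (ATP units)",
                  y = "mean amino-acid cost (ATP units)") +
    ggplot2::theme_minimal()
}

#' Plot null-simulation skew distributions
#'
#' Per-site-class distributions of the skews of random no-selection
#' genomes; the nonsynonymous classes sit slightly above zero purely
#' because stop-codon exclusion is asymmetric in base composition.
#'
#' @param null Output of [simulate_null_genomes()].
#' @return A ggplot object.
#' @export
plot_null_skews <- function(null) {
  d <- dplyr::filter(null, .data$site_class %in% c("4s", "ns"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site_class, y = .data$skew)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "site class", y = "skew") +
    ggplot2::theme_minimal()
}
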