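#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of a differential time-course result
#'
#' One panel per contrast; selected features are highlighted.
#'
#' @param object A `senomics_da` from [test_differential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot senomics_da
#' @export
autoplot.senomics_da <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change vs reference",
                  y = "-log10 adjusted p", colour = "selected") +
    ggplot2::theme_minimal()
}

#' Module trajectory plot
#'
#' Mean z-scored group-mean profile per module across timepoints, one line
#' per module.
#'
#' @param x Tibble with `feature_id` plus sample columns (normalized values).
#' @param design A [sample_design()].
#' @param modules Module assignment from [cluster_modules()].
#' @return A ggplot object.
#' @export
plot_trajectory_modules <- function(x, design, modules) {
  gm <- group_means(x, design)
  tps <- levels(design$timepoint)
  vals <- as.matrix(gm[tps])
  z <- t(apply(vals, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  d <- tibble::as_tibble(z) |>
    dplyr::mutate(feature_id = gm$feature_id) |>
    dplyr::inner_join(modules, by = "feature_id") |>
    tidyr::pivot_longer(dplyr::all_of(tps), names_to = "timepoint",
                        values_to = "z") |>
    dplyr::summarise(z = mean(.data$z), n = dplyr::n_distinct(.data$feature_id),
                     .by = c("module", "timepoint")) |>
    dplyr::mutate(timepoint = factor(.data$timepoint, levels = tps))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$z,
                                  group = factor(.data$module),
                                  colour = factor(.data$module))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "passage", y = "mean z-scored level", colour = "module") +
    ggplot2::theme_minimal()
}

#' Aggregate footprint profile plot
#'
#' Mean strand-averaged coverage around the motif, with the motif body
#' shaded.
#'
#' @param object A [footprint_profile()] (or a named list of them, drawn as
#'   separate lines).
#' @param ... Further profiles given as named arguments, overlaid.
#' @return A ggplot object.
#' @method autoplot footprint_profile
#' @export
autoplot.footprint_profile <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, TRUE, "footprint_profile")]
  profs <- c(list(profile = object), extra)
  L <- attr(object, "motif_length")
  d <- purrr::imap_dfr(profs, function(p, nm) {
    tibble::tibble(position = p$position, coverage = p$coverage, track = nm)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$coverage,
                                  colour = .data$track)) +
    ggplot2::annotate("rect", xmin = 0, xmax = L - 1, ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to motif start",
                  y = "mean normalized coverage") +
    ggplot2::theme_minimal()
}

#' Ranked motif enrichment plot
#'
#' @param object A [motif_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_enrichment
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                  y = -log10(pmax(.data$p_adj, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$family)) +
    ggplot2::geom_text(data = utils::head(d, 5),
                       ggplot2::aes(label = .data$motif),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "motif rank", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' ECDF plot of the promoter-accessibility shift
#'
#' @param object A [promoter_shift_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot promoter_shift
#' @export
autoplot.promoter_shift <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = .data$log2_fc, colour = .data$class)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "promoter peak log2 fold change",
                  y = "cumulative fraction", colour = "gene class") +
    ggplot2::theme_minimal()
}
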