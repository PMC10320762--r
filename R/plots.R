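# ggplot2 displays for trajectories, survival and scan results.

#' Plot mean allele-frequency trajectories
#'
#' Average pooled alternative-allele frequency per replicate across sampling
#' days, with the day-23 points separated by size group.
#'
#' @param trajectory Result of [mean_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectory) {
  df <- trajectory |>
    dplyr::mutate(
      replicate_id = paste0("F", .data$female, ".M", .data$male, ".R",
                            dplyr::coalesce(.data$replicate, 0L)),
      size_group = dplyr::coalesce(.data$size_group, "pooled")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$mean_alt_af,
                                   colour = .data$replicate_id,
                                   shape = .data$size_group)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$size_group == "pooled"),
                       alpha = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "day", y = "mean alternative-allele frequency",
                  colour = "replicate", shape = "day-23 group") +
    ggplot2::theme_minimal()
}

#' Plot larval survival curves
#'
#' Survivor counts over the sampling days per replicate, on a log scale —
#' the signature of type-III survivorship is the steep early drop.
#'
#' @param phenotypes Phenotype tibble (`female`, `male`, `replicate`, `day`,
#'   `survival_count`).
#' @return A ggplot object.
#' @export
plot_survival <- function(phenotypes) {
  df <- dplyr::mutate(phenotypes,
                      replicate_id = paste0("F", .data$female, ".M", .data$male,
                                            ".R", .data$replicate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$survival_count,
                                   colour = .data$replicate_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "survivors", colour = "replicate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style display of a marker scan
#'
#' @param object A `viability_scan` or `size_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot viability_scan
#' @export
autoplot.viability_scan <- function(object, ...) {
  df <- dplyr::mutate(object,
                      replicate_id = paste0("F", .data$female, ".M", .data$male,
                                            ".R", .data$replicate),
                      logp = -log10(pmax(.data$p_big, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_id, y = .data$logp,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(.data$alpha)),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~replicate_id) +
    ggplot2::labs(x = NULL, y = "-log10 p (D0 vs D23Big)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname autoplot.viability_scan
#' @method autoplot size_scan
#' @export
autoplot.size_scan <- function(object, ...) {
  df <- dplyr::mutate(object,
                      replicate_id = paste0("F", .data$female, ".M", .data$male,
                                            ".R", .data$replicate),
                      logp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_id, y = .data$logp,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(.data$alpha)),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~replicate_id) +
    ggplot2::labs(x = NULL, y = "-log10 p (Big vs Small)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
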