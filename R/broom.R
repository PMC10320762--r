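# broom-style tidiers for scan results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a viability scan into one row per marker x comparison
#'
#' @param x A `viability_scan` result.
#' @param ... Unused.
#' @return A long tibble: `unit`, `comparison`, `statistic`, `p_value`,
#'   `significant`, `direction`.
#' @method tidy viability_scan
#' @export
tidy.viability_scan <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("statistic_big", "p_big", "statistic_small", "p_small"),
      names_to = c(".value", "comparison"),
      names_pattern = "(statistic|p)_(big|small)"
    ) |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::transmute(
      .data$female, .data$male, .data$replicate,
      unit = .data$marker_id,
      comparison = paste0("D0-vs-D23", ifelse(.data$comparison == "big",
                                              "Big", "Small")),
      .data$statistic, p_value = .data$p, .data$alpha,
      .data$significant, .data$direction)
}

#' @rdname tidy.viability_scan
#' @method tidy size_scan
#' @export
tidy.size_scan <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::transmute(.data$female, .data$male, .data$replicate,
                     unit = .data$marker_id, comparison = "D23Big-vs-D23Small",
                     .data$statistic, .data$p_value, .data$alpha,
                     .data$significant, .data$direction)
}

#' One-row-per-replicate summaries of scan results
#'
#' @param x A scan result.
#' @param ... Unused.
#' @return A tibble with marker counts, significant counts and the adjusted
#'   threshold per replicate.
#' @method glance viability_scan
#' @export
glance.viability_scan <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(x),
                   n_markers = dplyr::n(),
                   n_significant = sum(.data$significant),
                   alpha = .data$alpha[1],
                   .by = c("female", "male", "replicate"))
}

#' @rdname glance.viability_scan
#' @method glance size_scan
#' @export
glance.size_scan <- glance.viability_scan

#' @rdname glance.viability_scan
#' @method glance haplotype_scan
#' @export
glance.haplotype_scan <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(x),
                   n_markers = dplyr::n(),
                   n_significant = sum(.data$significant),
                   .by = c("female", "male", "replicate"))
}

#' @rdname glance.viability_scan
#' @method glance contig_scan
#' @export
glance.contig_scan <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(x),
                   n_contigs = dplyr::n(),
                   n_sig_d0_d23 = sum(.data$sig_d0_d23),
                   n_sig_d16_d23 = sum(.data$sig_d16_d23),
                   n_selected = sum(.data$selected),
                   .by = c("female", "male", "replicate"))
}
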