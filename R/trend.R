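# Consistent-trend marker selection and the Monte-Carlo chance-of-drift null.

delta_signs <- function(d11, d16, dbig, dsmall, method) {
  if (method == "delta") {
    # Each post-day-0 time point compared to day 0: four (or three, when the
    # Small group is absent) day-0-normalized deltas must share a strict sign.
    cbind(d11, d16, dbig, dsmall)
  } else {
    # Chain of successive comparisons D0->D11->D16->{Big, Small}.
    cbind(d11, d16 - d11, dbig - d16, dsmall - d16)
  }
}

consistent_from_deltas <- function(d11, d16, dbig, dsmall, method) {
  cmp <- delta_signs(d11, d16, dbig, dsmall, method)
  n_avail <- rowSums(!is.na(cmp))
  pos <- rowSums(cmp > 0, na.rm = TRUE)
  neg <- rowSums(cmp < 0, na.rm = TRUE)
  consistent <- n_avail > 0 & (pos == n_avail | neg == n_avail)
  direction <- ifelse(!consistent, "none",
                      ifelse(pos == n_avail, "increasing", "decreasing"))
  list(consistent = consistent, direction = direction, n_comparisons = n_avail)
}

#' Select markers with consistent allele-frequency change
#'
#' From the markers belonging to contigs flagged by [contig_scan()], selects
#' those whose allele-frequency change is uniform in direction at each of the
#' four time points: the day-0-normalized deltas at day 11, day 16, day 23Big
#' and day 23Small must all share one strict sign (`method = "delta"`, the
#' default, whose neutral-sampling null probability is `2 * (1/2)^4` with
#' four comparisons — the anchor the chance-of-drift model reproduces). Any
#' tie breaks consistency. When the Small group is absent only three deltas
#' are available. `method = "chain"` instead requires the successive steps
#' D0->D11, D11->D16, D16->Big and D16->Small to share one sign (a strict
#' monotone trajectory).
#'
#' @param deltas Result of [normalize_to_day0()].
#' @param contigs Result of [contig_scan()], or a character vector of contig
#'   ids to restrict to (use `NULL` to evaluate every marker).
#' @param method `"delta"` (uniform direction versus day 0) or `"chain"`
#'   (monotone successive steps).
#' @return A tibble of class `trend_result`: one row per marker x replicate
#'   with the four deltas, the number of available comparisons, `direction`
#'   (`increasing`/`decreasing`/`none`) and the `consistent` flag.
#' @export
consistent_trend_markers <- function(deltas, contigs = NULL,
                                     method = c("delta", "chain")) {
  method <- match.arg(method)
  wide <- deltas |>
    dplyr::filter(!.data$missing) |>
    dplyr::mutate(slot = dplyr::case_when(
      .data$day == 11 ~ "d11",
      .data$day == 16 ~ "d16",
      .data$day == 23 & .data$size_group %in% "Big" ~ "d23big",
      .data$day == 23 & .data$size_group %in% "Small" ~ "d23small"
    )) |>
    dplyr::filter(!is.na(.data$slot)) |>
    dplyr::select("marker_id", "contig", "female", "male", "replicate",
                  "slot", "delta_af") |>
    tidyr::pivot_wider(names_from = "slot", values_from = "delta_af",
                       names_prefix = "delta_")
  for (col in c("delta_d11", "delta_d16", "delta_d23big", "delta_d23small")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  if (!is.null(contigs)) {
    if (inherits(contigs, "contig_scan")) {
      sel <- contigs[contigs$selected,
                     c("female", "male", "replicate", "contig")]
      wide <- dplyr::inner_join(wide, sel,
                                by = c("female", "male", "replicate", "contig"))
    } else {
      wide <- wide[wide$contig %in% contigs, , drop = FALSE]
    }
  }
  res <- consistent_from_deltas(wide$delta_d11, wide$delta_d16,
                                wide$delta_d23big, wide$delta_d23small, method)
  out <- wide |>
    dplyr::mutate(n_comparisons = res$n_comparisons,
                  direction = res$direction,
                  consistent = res$consistent) |>
    dplyr::filter(.data$n_comparisons > 0)
  class(out) <- c("trend_result", class(out))
  out
}

#' Monte-Carlo chance of drift for a marker's trajectory
#'
#' Probability, under a sampling-noise-only null, that a marker whose true
#' frequency never changes would still show a direction-consistent trajectory.
#' Alternative read counts at each post-day-0 time point are drawn
#' independently as Binomial(depth_t, p0) with the day-0 frequency `p0` held
#' fixed as the reference; the simulated trajectory counts as consistent
#' under the same rule as [consistent_trend_markers()]. With four
#' comparisons and deep coverage the delta rule converges to
#' `2 * (1/2)^4 = 0.125`; finite depth can only lower the estimate, because
#' ties break consistency.
#'
#' @param p0 Day-0 alternative-allele frequency, in \[0, 1\]. Degenerate
#'   frequencies 0 and 1 return 0 with a warning (no two-sided variation).
#' @param depths Read depths at the compared time points (day 11, day 16, day
#'   23Big, day 23Small); a scalar is recycled. Use length 3 for replicates
#'   without a Small group.
#' @param n_sims Number of Monte-Carlo trajectories (>= 1000).
#' @param seed Optional seed; the estimate is deterministic given a seed.
#' @param method As in [consistent_trend_markers()].
#' @return A one-row tibble: `p0`, `n_comparisons`, `chance_of_drift`,
#'   `n_sims`, `seed`.
#' @export
#' @examples
#' chance_of_drift(0.5, depths = 1e6, n_sims = 2e4, seed = 1)
chance_of_drift <- function(p0, depths = c(100, 100, 100, 100),
                            n_sims = 1e5, seed = NULL,
                            method = c("delta", "chain")) {
  method <- match.arg(method)
  if (length(p0) != 1 || is.na(p0) || p0 < 0 || p0 > 1) {
    stopf("`p0` must be a single frequency in [0, 1]",
          class = "larvascan_parameter_error")
  }
  if (n_sims < 1000) {
    stopf("`n_sims` must be at least 1000", class = "larvascan_parameter_error")
  }
  if (length(depths) == 1) depths <- rep(depths, 4)
  if (!length(depths) %in% 3:4 || any(depths <= 0)) {
    stopf("`depths` must be 3 or 4 positive values",
          class = "larvascan_parameter_error")
  }
  k <- length(depths)
  if (p0 %in% c(0, 1)) {
    warn("p0 is fixed (0 or 1); chance of drift is 0")
    return(tibble::tibble(p0 = p0, n_comparisons = k, chance_of_drift = 0,
                          n_sims = as.integer(n_sims),
                          seed = seed %||% NA_integer_))
  }
  chance <- with_seed(seed, {
    f <- vapply(depths, function(d) rbinom(n_sims, d, p0) / d,
                numeric(n_sims))
    d11 <- f[, 1] - p0
    d16 <- f[, 2] - p0
    dbig <- f[, 3] - p0
    dsmall <- if (k == 4) f[, 4] - p0 else rep(NA_real_, n_sims)
    # chain method compares successive time points, still anchored at p0
    if (method == "chain") {
      res <- consistent_from_deltas(d11, d16, dbig, dsmall, "chain")
    } else {
      res <- consistent_from_deltas(d11, d16, dbig, dsmall, "delta")
    }
    mean(res$consistent)
  })
  tibble::tibble(p0 = p0, n_comparisons = k, chance_of_drift = chance,
                 n_sims = as.integer(n_sims), seed = seed %||% NA_integer_)
}

#' Chance of drift for a set of markers
#'
#' Applies [chance_of_drift()] to each marker's observed day-0 frequency and
#' per-time-point depths, and reports the per-marker values plus their mean —
#' the summary used to argue that consistent trajectories are unlikely under
#' drift alone.
#'
#' @param freqs Result of [compute_allele_freq()].
#' @param markers Character vector of marker ids (e.g. trend-consistent
#'   viability SNPs).
#' @param n_sims,seed,method Passed to [chance_of_drift()].
#' @return A tibble of per-marker estimates (mean value as attribute
#'   `mean_chance`).
#' @export
drift_report <- function(freqs, markers, n_sims = 1e5, seed = NULL,
                         method = "delta") {
  slots <- freqs |>
    dplyr::filter(!.data$missing, .data$marker_id %in% markers) |>
    dplyr::mutate(slot = dplyr::case_when(
      .data$day == 0 ~ "d0",
      .data$day == 11 ~ "d11",
      .data$day == 16 ~ "d16",
      .data$day == 23 & .data$size_group %in% "Big" ~ "d23big",
      .data$day == 23 & .data$size_group %in% "Small" ~ "d23small"
    )) |>
    dplyr::filter(!is.na(.data$slot))
  slot_order <- c("d11", "d16", "d23big", "d23small")
  d0 <- slots |>
    dplyr::filter(.data$slot == "d0") |>
    dplyr::select("marker_id", "female", "male", p0 = "alt_af")
  out <- slots |>
    dplyr::filter(.data$slot != "d0") |>
    dplyr::summarise(
      depths = {
        ord <- order(match(.data$slot, slot_order))
        list((.data$ref_count + .data$alt_count)[ord])
      },
      .by = c("marker_id", "female", "male", "replicate")
    ) |>
    dplyr::inner_join(d0, by = c("marker_id", "female", "male")) |>
    dplyr::filter(!is.na(.data$p0))
  ests <- purrr::pmap_dbl(
    list(out$p0, out$depths, seq_len(nrow(out))),
    function(p0, depths, i) {
      chance_of_drift(p0, depths, n_sims = n_sims,
                      seed = if (is.null(seed)) NULL else seed + i,
                      method = method)$chance_of_drift
    })
  out <- dplyr::mutate(out, chance_of_drift = ests, n_sims = as.integer(n_sims))
  attr(out, "mean_chance") <- mean(ests)
  out
}

#' Joint probability that drift explains every replicate
#'
#' Product of per-replicate chance-of-drift probabilities under independence
#' across replicate cultures.
#'
#' @param probs Numeric vector of probabilities in [0, 1].
#' @return A single probability.
#' @export
#' @examples
#' joint_drift_probability(rep(0.125, 8)) # ~5.96e-08
joint_drift_probability <- function(probs) {
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stopf("probabilities must lie in [0, 1]", class = "larvascan_parameter_error")
  }
  prod(probs)
}
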