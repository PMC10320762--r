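# Pooled allele frequencies, day-0-normalized trajectories, parental
# haplotype frequencies, heterozygosity and divergence direction.

#' Compute pooled allele frequencies from read counts
#'
#' The reference-allele frequency of a pool is its reference read count over
#' the summed reference and alternative read counts (`ref-AF = r.rc / s.arc`),
#' and likewise for the alternative allele, so `ref_af + alt_af = 1` wherever
#' counts are present. Missing cells propagate missing frequencies.
#'
#' @param counts A pooled count tibble.
#' @return The tibble with `ref_af` and `alt_af` columns appended.
#' @export
#' @examples
#' tibble::tibble(marker_id = "m", contig = "c", position = 1L,
#'                female = 1L, male = 1L, replicate = NA_integer_, day = 0L,
#'                size_group = NA_character_, ref_count = 30L, alt_count = 70L,
#'                missing = FALSE) |>
#'   compute_allele_freq()
compute_allele_freq <- function(counts) {
  counts <- validate_pool_counts(counts)
  total <- counts$ref_count + counts$alt_count
  if (any(!counts$missing & total == 0)) {
    stopf("zero total depth on a nonmissing cell; filter such cells first",
          class = "larvascan_computation_error")
  }
  counts$ref_af <- ifelse(counts$missing, NA_real_, counts$ref_count / total)
  counts$alt_af <- ifelse(counts$missing, NA_real_, counts$alt_count / total)
  counts
}

#' Normalize allele-frequency trajectories to day 0
#'
#' For each marker within a replicate's series, the day 11, day 16, day
#' 23Big and day 23Small alternative-allele frequencies are expressed as
#' differences from the family's day-0 frequency
#' (`delta_af = alt_af(day) - alt_af(day 0)`), so day 0 maps to exactly zero
#' and deltas stay within [-1, 1]. Markers without a nonmissing day-0
#' frequency are excluded (with a message).
#'
#' @param freqs Result of [compute_allele_freq()].
#' @return A tibble with one row per marker x replicate x (day, size group)
#'   carrying `alt_af`, `alt_af_d0` and `delta_af`.
#' @export
normalize_to_day0 <- function(freqs) {
  if (!"alt_af" %in% names(freqs)) {
    stopf("run compute_allele_freq() first", class = "larvascan_validation_error")
  }
  d0 <- freqs |>
    dplyr::filter(.data$day == 0, !.data$missing) |>
    dplyr::select("marker_id", "female", "male", alt_af_d0 = "alt_af")
  out <- freqs |>
    dplyr::filter(.data$day > 0) |>
    dplyr::inner_join(d0, by = c("marker_id", "female", "male")) |>
    dplyr::mutate(delta_af = .data$alt_af - .data$alt_af_d0)
  lost <- dplyr::anti_join(
    unique(freqs[freqs$day > 0, c("marker_id", "female", "male")]),
    d0, by = c("marker_id", "female", "male"))
  if (nrow(lost)) {
    inform(sprintf(
      "%d marker/family pair(s) lack a day-0 frequency; excluded from trends",
      nrow(lost)))
  }
  out
}

#' Mean allele-frequency trajectory across markers
#'
#' The per-day (and, on day 23, per size group) average pooled
#' alternative-allele frequency, computed as the arithmetic mean over all
#' nonmissing markers of the supplied set.
#'
#' @param freqs Result of [compute_allele_freq()].
#' @param markers Optional character vector restricting the marker set (e.g.
#'   the heterozygous-filtered markers of a replicate).
#' @return A tibble keyed by `female`, `male`, `replicate`, `day`,
#'   `size_group` with `mean_alt_af` and the marker count `n_markers`.
#' @export
mean_trajectory <- function(freqs, markers = NULL) {
  if (!is.null(markers)) {
    freqs <- freqs[freqs$marker_id %in% markers, , drop = FALSE]
  }
  freqs |>
    dplyr::filter(!.data$missing) |>
    dplyr::summarise(mean_alt_af = mean(.data$alt_af),
                     n_markers = dplyr::n(),
                     .by = c("female", "male", "replicate", "day", "size_group")) |>
    dplyr::arrange(.data$female, .data$male, .data$replicate, .data$day,
                   .data$size_group)
}

#' Parental haplotype frequencies at informative markers
#'
#' At an informative marker the two parental haplotypes are distinguishable:
#' the female-haplotype frequency is the pooled frequency of whichever allele
#' the female is homozygous for, and the male-haplotype frequency is its
#' complement, so the two sum to one at every marker.
#'
#' @param freqs Result of [compute_allele_freq()].
#' @param parents Parental genotype tibble.
#' @return `freqs` restricted to informative markers, with `female_af` and
#'   `male_af` columns (plus `female_count`/`male_count` haplotype read
#'   counts) appended.
#' @export
haplotype_frequencies <- function(freqs, parents) {
  if (!"informative" %in% names(parents)) {
    parents$informative <- is_informative(parents$female_gt, parents$male_gt)
  }
  joined <- dplyr::inner_join(
    freqs, parents[c("female", "male", "marker_id", "female_gt", "informative")],
    by = c("female", "male", "marker_id"))
  if (any(!joined$informative)) {
    stopf("non-informative marker(s) passed to haplotype_frequencies()",
          class = "larvascan_validation_error")
  }
  fem_ref <- joined$female_gt == "0/0"
  joined$female_af <- ifelse(fem_ref, joined$ref_af, joined$alt_af)
  joined$male_af <- 1 - joined$female_af
  joined$female_count <- ifelse(fem_ref, joined$ref_count, joined$alt_count)
  joined$male_count <- ifelse(fem_ref, joined$alt_count, joined$ref_count)
  dplyr::select(joined, -"informative", -"female_gt")
}

#' Per-pool expected heterozygosity
#'
#' Heterozygosity at a locus is the product of the reference and alternative
#' allele frequencies, `h = ref_af * alt_af`, which lies in [0, 0.25] and is
#' maximal at a 50/50 pool.
#'
#' @param freqs Result of [compute_allele_freq()].
#' @return `freqs` with a `heterozygosity` column appended.
#' @export
heterozygosity <- function(freqs) {
  freqs$heterozygosity <- freqs$ref_af * freqs$alt_af
  freqs
}

#' Mean heterozygosity of a marker set per sample
#'
#' @param freqs Result of [compute_allele_freq()].
#' @param markers Character vector of marker ids (e.g. the viability SNPs of
#'   a replicate).
#' @return A tibble keyed by sample with `mean_heterozygosity` and
#'   `n_markers`.
#' @export
heterozygosity_summary <- function(freqs, markers = NULL) {
  h <- heterozygosity(freqs)
  if (!is.null(markers)) h <- h[h$marker_id %in% markers, , drop = FALSE]
  h |>
    dplyr::filter(!.data$missing) |>
    dplyr::summarise(mean_heterozygosity = mean(.data$heterozygosity),
                     n_markers = dplyr::n(),
                     .by = c("female", "male", "replicate", "day", "size_group")) |>
    dplyr::arrange(.data$female, .data$male, .data$replicate, .data$day,
                   .data$size_group)
}

#' Direction of sequence divergence at an endpoint versus day 0
#'
#' Partitions a marker set by the sign of the alternative-allele frequency
#' change between the family's day-0 pool and an endpoint sample: an increase
#' in alternative-allele frequency is an increase in sequence divergence
#' (a shift toward the paternal haplotype). Ties are counted separately,
#' never forced into either class.
#'
#' @param freqs Result of [compute_allele_freq()].
#' @param markers Character vector of marker ids to classify.
#' @param endpoint_day,endpoint_size Endpoint sample (default day 23, Big).
#' @return A tibble per replicate with `n_increase`, `n_decrease`, `n_tie`.
#' @export
divergence_direction <- function(freqs, markers, endpoint_day = 23,
                                 endpoint_size = "Big") {
  d0 <- freqs |>
    dplyr::filter(.data$day == 0, !.data$missing,
                  .data$marker_id %in% markers) |>
    dplyr::select("marker_id", "female", "male", alt_af_d0 = "alt_af")
  end <- freqs |>
    dplyr::filter(.data$day == endpoint_day, !.data$missing,
                  .data$marker_id %in% markers)
  if (!is.na(endpoint_size) && endpoint_day == 23) {
    end <- end[!is.na(end$size_group) & end$size_group == endpoint_size, ]
  }
  end |>
    dplyr::inner_join(d0, by = c("marker_id", "female", "male")) |>
    dplyr::summarise(
      n_increase = sum(.data$alt_af > .data$alt_af_d0),
      n_decrease = sum(.data$alt_af < .data$alt_af_d0),
      n_tie = sum(.data$alt_af == .data$alt_af_d0),
      .by = c("female", "male", "replicate")
    )
}
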