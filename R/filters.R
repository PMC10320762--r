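# Depth, zero-recovery and heterozygosity filters for pooled count tables.
#
# Filter order matters and follows the analysis design: parental depth first,
# then the zero-recovery masking, then the per-replicate 20x both-allele rule
# that defines the heterozygous marker set (nHet) every alpha computation
# consumes. All filters are idempotent.

#' Filter markers on parental sequencing depth
#'
#' Drops markers where either parent's genotype call is supported by fewer
#' than `min_depth` reads (or has no recorded depth). The threshold is
#' inclusive: a depth of exactly `min_depth` is retained. Families whose
#' entire marker set fails are removed with a warning, mirroring how
#' replicates without adequately covered parents are discarded outright.
#'
#' @param parents A parental genotype tibble (see [read_parental_vcf()]).
#' @param min_depth Minimum per-parent depth, default 40.
#' @return The filtered parental tibble.
#' @export
filter_parental_depth <- function(parents, min_depth = 40) {
  keep <- !is.na(parents$female_depth) & !is.na(parents$male_depth) &
    parents$female_depth >= min_depth & parents$male_depth >= min_depth
  out <- parents[keep, , drop = FALSE]
  lost <- dplyr::anti_join(unique(parents[c("female", "male")]),
                           unique(out[c("female", "male")]),
                           by = c("female", "male"))
  if (nrow(lost)) {
    warn(sprintf("family(ies) dropped entirely by the parental depth filter: %s",
                 paste(sample_key(lost$female, lost$male, NA, 0), collapse = ", ")))
  }
  if (!nrow(out)) warn("no markers pass the parental depth filter")
  out
}

#' Mask biologically impossible zero-then-recovered allele counts
#'
#' Within each marker's time series (family day-0 pool followed by each
#' replicate's day 11/16/23 samples), an allele count of zero at one time
#' point followed by a nonzero count at any *later* day is biologically
#' impossible — an allele absent from the cohort cannot reappear — so the
#' marker's counts at the zero time point are converted to missing data.
#' Terminal zeros are untouched. Both alleles of the offending cell are
#' masked. Because the day-0 pool precedes the replicate split it is shared
#' by all replicates; a day-0 zero is masked if the allele reappears in any
#' replicate.
#'
#' @param counts A pooled count tibble.
#' @return The tibble with offending cells set missing. Idempotent.
#' @export
apply_zero_recovery_rule <- function(counts) {
  counts <- validate_pool_counts(counts)
  live <- !counts$missing
  # Last day on which each allele is seen (count > 0) per marker x lineage.
  # Day-0 rows join every lineage of their family.
  later_seen <- function(allele_count) {
    seen <- counts[live & !is.na(allele_count) & allele_count > 0,
                   c("marker_id", "female", "male", "replicate", "day")]
    if (!nrow(seen)) {
      empty <- seen[c("marker_id", "female", "male")]
      empty$last_seen_fam <- integer()
      rep_empty <- seen[c("marker_id", "female", "male", "replicate")]
      rep_empty$last_seen_rep <- integer()
      return(list(fam = empty, rep = rep_empty))
    }
    fam_level <- seen |>
      dplyr::summarise(last_seen_fam = max(.data$day),
                       .by = c("marker_id", "female", "male"))
    rep_level <- seen |>
      dplyr::filter(!is.na(.data$replicate)) |>
      dplyr::summarise(last_seen_rep = max(.data$day),
                       .by = c("marker_id", "female", "male", "replicate"))
    list(fam = fam_level, rep = rep_level)
  }
  mask_for <- function(allele_count) {
    ls <- later_seen(allele_count)
    zero <- counts |>
      dplyr::mutate(.row = dplyr::row_number(), .count = allele_count) |>
      dplyr::filter(!.data$missing, !is.na(.data$.count), .data$.count == 0)
    zero <- zero |>
      dplyr::left_join(ls$fam, by = c("marker_id", "female", "male")) |>
      dplyr::left_join(ls$rep, by = c("marker_id", "female", "male", "replicate"))
    reappears <- ifelse(is.na(zero$replicate),
                        # day-0 cell: any later sighting in the family
                        !is.na(zero$last_seen_fam) & zero$last_seen_fam > zero$day,
                        !is.na(zero$last_seen_rep) & zero$last_seen_rep > zero$day)
    zero$.row[reappears]
  }
  bad <- union(mask_for(counts$ref_count), mask_for(counts$alt_count))
  if (length(bad)) {
    counts$missing[bad] <- TRUE
    counts$ref_count[bad] <- NA_integer_
    counts$alt_count[bad] <- NA_integer_
  }
  counts
}

#' Select heterozygous markers and count nHet per replicate
#'
#' A marker enters a replicate's analysis set when (i) its parents are
#' opposite homozygotes (so every F1 is heterozygous and reads are phased to
#' the parental haplotypes) and (ii) at every nonmissing time point of that
#' replicate's series — the family day-0 pool plus the replicate's day
#' 11/16/23 samples, including both size groups — both the reference and the
#' alternative allele have at least `min_allele_depth` reads. Cells masked by
#' [apply_zero_recovery_rule()] are exempt, as are time points the replicate
#' simply lacks. The per-replicate retained-marker count is `nHet`, the
#' denominator of the `0.05/nHet` significance threshold.
#'
#' @param counts A pooled count tibble (run [apply_zero_recovery_rule()]
#'   first).
#' @param parents Parental genotype tibble.
#' @param min_allele_depth Minimum per-allele read count, default 20
#'   (inclusive).
#' @return A tibble of retained `(female, male, replicate, marker_id)` rows
#'   with class `het_markers`; `n_het()` tabulates it per replicate.
#' @export
select_heterozygous_markers <- function(counts, parents, min_allele_depth = 20) {
  counts <- validate_pool_counts(counts)
  info <- parents
  if (!"informative" %in% names(info)) {
    info$informative <- is_informative(info$female_gt, info$male_gt)
  }
  info <- info[info$informative, c("female", "male", "marker_id")]
  unknown <- dplyr::anti_join(
    unique(counts[c("female", "male", "marker_id")]),
    parents[c("female", "male", "marker_id")],
    by = c("female", "male", "marker_id"))
  if (nrow(unknown)) {
    inform(sprintf("%d marker/family pair(s) absent from the parental table; excluded",
                   nrow(unknown)))
  }
  reps <- unique(counts[!is.na(counts$replicate),
                        c("female", "male", "replicate")])
  # Attach the shared day-0 rows to every replicate of the family.
  # the shared day-0 pool legitimately fans out to every replicate
  d0 <- dplyr::inner_join(counts[is.na(counts$replicate), ], reps,
                          by = c("female", "male"), suffix = c("", ".rep"),
                          relationship = "many-to-many") |>
    dplyr::mutate(replicate = .data$replicate.rep) |>
    dplyr::select(-"replicate.rep")
  series <- dplyr::bind_rows(counts[!is.na(counts$replicate), ], d0)
  ok <- series |>
    dplyr::filter(!.data$missing) |>
    dplyr::summarise(
      deep = all(.data$ref_count >= min_allele_depth &
                   .data$alt_count >= min_allele_depth),
      .by = c("female", "male", "replicate", "marker_id")
    ) |>
    dplyr::filter(.data$deep) |>
    dplyr::select(-"deep") |>
    dplyr::inner_join(info, by = c("female", "male", "marker_id")) |>
    dplyr::arrange(.data$female, .data$male, .data$replicate, .data$marker_id)
  class(ok) <- c("het_markers", class(ok))
  ok
}

#' Number of heterozygous markers (nHet) per replicate
#'
#' @param markers Result of [select_heterozygous_markers()].
#' @return A tibble of `female`, `male`, `replicate`, `n_het`.
#' @export
n_het <- function(markers) {
  dplyr::count(tibble::as_tibble(markers),
               .data$female, .data$male, .data$replicate, name = "n_het")
}

#' Summarise a filtering step as a report
#'
#' @param before,after Count tibbles (or parental tibbles) before and after a
#'   filter.
#' @param reasons Optional named list of reason counts.
#' @return A list `markers_in`, `markers_out`, `reason_counts`, suitable for
#'   `jsonlite::write_json()`.
#' @export
filter_report <- function(before, after, reasons = list()) {
  list(markers_in = length(unique(before$marker_id)),
       markers_out = length(unique(after$marker_id)),
       reason_counts = reasons)
}
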