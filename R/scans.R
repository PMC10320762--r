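# The four chi-square scan procedures and overlap set logic.

# Wide per-replicate cell table: one row per marker x replicate with the
# day-0 (family) counts and the day-23 Big/Small counts attached.
scan_cells <- function(counts, markers) {
  counts <- validate_pool_counts(counts)
  base <- tibble::as_tibble(markers)[c("female", "male", "replicate", "marker_id")]
  pick <- function(day, size = NA_character_, suffix) {
    sel <- counts$day == day & !counts$missing &
      (if (is.na(size)) TRUE else !is.na(counts$size_group) & counts$size_group == size)
    cols <- counts[sel, c("marker_id", "female", "male", "replicate",
                          "ref_count", "alt_count")]
    names(cols)[5:6] <- paste0(c("ref_", "alt_"), suffix)
    cols
  }
  d0 <- pick(0, suffix = "d0")[, -4] # day 0 is family-level (replicate NA)
  d16 <- pick(16, suffix = "d16")
  big <- pick(23, "Big", "big")
  small <- pick(23, "Small", "small")
  base |>
    dplyr::left_join(d0, by = c("female", "male", "marker_id")) |>
    dplyr::left_join(d16, by = c("female", "male", "replicate", "marker_id")) |>
    dplyr::left_join(big, by = c("female", "male", "replicate", "marker_id")) |>
    dplyr::left_join(small, by = c("female", "male", "replicate", "marker_id"))
}

#' Scan for viability-associated SNPs (day 0 versus day 23)
#'
#' For every heterozygous marker of a replicate, a 2x2 contingency table of
#' reference/alternative read counts by day is tested between the family
#' day-0 pool and the day-23 Big survivors, and — when the replicate has a
#' Small group — a second test against day-23 Small. The per-replicate
#' significance threshold is `alpha_base / nHet`. A marker is a
#' viability-associated SNP when every available test falls below the
#' threshold; replicates without a Small group are decided by the Big test
#' alone. Replicates lacking any day-23 sample raise an error.
#'
#' @param counts A pooled count tibble (filtered).
#' @param markers [select_heterozygous_markers()] result (defines nHet).
#' @param alpha_base Family-wise base level, default 0.05.
#' @param yates Apply the continuity correction?
#' @return A tibble of class `viability_scan`: one row per marker x replicate
#'   with statistics, p-values, the adjusted `alpha`, the `significant` flag
#'   and the `direction` of the day-0 to day-23Big frequency change.
#' @export
viability_scan <- function(counts, markers, alpha_base = 0.05, yates = FALSE) {
  cells <- scan_cells(counts, markers)
  has23 <- cells |>
    dplyr::summarise(
      any23 = any(!is.na(.data$ref_big)) || any(!is.na(.data$ref_small)),
      .by = c("female", "male", "replicate"))
  if (any(!has23$any23)) {
    stopf("replicate without any day-23 sample: %s",
          paste(sample_key(has23$female[!has23$any23],
                           has23$male[!has23$any23],
                           has23$replicate[!has23$any23], 23),
                collapse = ", "),
          class = "larvascan_scan_error")
  }
  tb <- chisq_2x2_vec(cells$ref_d0, cells$alt_d0, cells$ref_big,
                      cells$alt_big, yates)
  ts <- chisq_2x2_vec(cells$ref_d0, cells$alt_d0, cells$ref_small,
                      cells$alt_small, yates)
  out <- cells |>
    dplyr::mutate(
      statistic_big = tb$statistic, p_big = tb$p_value,
      statistic_small = ts$statistic, p_small = ts$p_value
    ) |>
    dplyr::left_join(n_het(markers), by = c("female", "male", "replicate")) |>
    dplyr::mutate(
      alpha = alpha_base / .data$n_het,
      significant = !is.na(.data$p_big) & .data$p_big < .data$alpha &
        (is.na(.data$p_small) | .data$p_small < .data$alpha),
      af_big = .data$alt_big / (.data$ref_big + .data$alt_big),
      af_d0 = .data$alt_d0 / (.data$ref_d0 + .data$alt_d0),
      direction = dplyr::case_when(
        is.na(.data$af_big) | is.na(.data$af_d0) ~ NA_character_,
        .data$af_big > .data$af_d0 ~ "increase",
        .data$af_big < .data$af_d0 ~ "decrease",
        TRUE ~ "tie")
    ) |>
    dplyr::select("female", "male", "replicate", "marker_id",
                  "statistic_big", "p_big", "statistic_small", "p_small",
                  "n_het", "alpha", "significant", "direction")
  class(out) <- c("viability_scan", class(out))
  out
}

#' Scan parental-haplotype read counts with q-value control
#'
#' Per informative marker, the reads supporting the female and male
#' haplotypes are compared between the day-0 pool and each day-23 group in a
#' 2x2 table. Within each replicate x comparison family the p-values are
#' converted to q-values; a marker is reported when `q < q_threshold` for
#' every available comparison (Big and Small when both exist). The statistic
#' is invariant to the parental orientation of the marker.
#'
#' @inheritParams viability_scan
#' @param parents Parental genotype tibble (for haplotype orientation).
#' @param q_threshold Significance level on the q-value scale, default 0.05.
#' @param fdr `"storey"` or `"bh"`.
#' @return A tibble of class `haplotype_scan` with per-comparison p- and
#'   q-values and the combined `significant` flag.
#' @export
haplotype_scan <- function(counts, parents, markers, q_threshold = 0.05,
                           fdr = c("bh", "storey"), yates = FALSE) {
  fdr <- match.arg(fdr)
  cells <- scan_cells(counts, markers)
  orient <- parents[c("female", "male", "marker_id", "female_gt")]
  cells <- dplyr::inner_join(cells, orient,
                             by = c("female", "male", "marker_id"))
  # female haplotype reads = ref reads when the female is hom-ref
  fem_ref <- cells$female_gt == "0/0"
  fm <- function(ref, alt) list(f = ifelse(fem_ref, ref, alt),
                                m = ifelse(fem_ref, alt, ref))
  h0 <- fm(cells$ref_d0, cells$alt_d0)
  hb <- fm(cells$ref_big, cells$alt_big)
  hs <- fm(cells$ref_small, cells$alt_small)
  tb <- chisq_2x2_vec(h0$f, h0$m, hb$f, hb$m, yates)
  ts <- chisq_2x2_vec(h0$f, h0$m, hs$f, hs$m, yates)
  out <- cells |>
    dplyr::mutate(statistic_big = tb$statistic, p_big = tb$p_value,
                  statistic_small = ts$statistic, p_small = ts$p_value) |>
    dplyr::mutate(
      q_big = safe_qvalues(.data$p_big, fdr),
      q_small = safe_qvalues(.data$p_small, fdr),
      .by = c("female", "male", "replicate")
    ) |>
    dplyr::mutate(
      significant = !is.na(.data$q_big) & .data$q_big < q_threshold &
        (is.na(.data$q_small) | .data$q_small < q_threshold)
    ) |>
    dplyr::select("female", "male", "replicate", "marker_id",
                  "statistic_big", "p_big", "q_big",
                  "statistic_small", "p_small", "q_small", "significant")
  class(out) <- c("haplotype_scan", class(out))
  out
}

# q-values over the nonmissing entries of one comparison family.
safe_qvalues <- function(p, method) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- qvalues(p[ok], method)
  q
}

#' Contig-level parental-haplotype scan
#'
#' Haplotype-supporting read counts are summed over every informative marker
#' of a contig, giving one female and one male total per contig and sample;
#' the summed 2x2 table is then tested exactly as a single marker would be
#' (the contig statistic equals [chisq_2x2()] on the summed table). Two
#' comparisons are run per replicate: day 0 versus day 23 (Big and Small
#' each, both required significant when both exist) and day 16 versus day
#' 23Big. Each comparison family is converted to q-values; the reported
#' contig set is the intersection of the two comparisons' significant
#' contigs. Contigs with no informative markers are skipped.
#'
#' @inheritParams haplotype_scan
#' @return A tibble of class `contig_scan`: one row per contig x replicate
#'   with per-comparison q-values, significance flags and the combined
#'   `selected` flag.
#' @export
contig_scan <- function(counts, parents, markers, q_threshold = 0.05,
                        fdr = c("bh", "storey"), yates = FALSE) {
  fdr <- match.arg(fdr)
  cells <- scan_cells(counts, markers)
  orient <- parents[c("female", "male", "marker_id", "female_gt", "contig")]
  cells <- dplyr::inner_join(cells, orient,
                             by = c("female", "male", "marker_id"))
  fem_ref <- cells$female_gt == "0/0"
  hap <- function(ref, alt) {
    list(f = ifelse(fem_ref, ref, alt), m = ifelse(fem_ref, alt, ref))
  }
  h0 <- hap(cells$ref_d0, cells$alt_d0)
  h16 <- hap(cells$ref_d16, cells$alt_d16)
  hb <- hap(cells$ref_big, cells$alt_big)
  hs <- hap(cells$ref_small, cells$alt_small)
  cells <- cells |>
    dplyr::mutate(f_d0 = h0$f, m_d0 = h0$m, f_d16 = h16$f, m_d16 = h16$m,
                  f_big = hb$f, m_big = hb$m, f_small = hs$f, m_small = hs$m)
  totals <- cells |>
    dplyr::summarise(dplyr::across(dplyr::starts_with(c("f_", "m_")),
                                   ~sum(.x, na.rm = TRUE)),
                     n_markers = dplyr::n(),
                     .by = c("female", "male", "replicate", "contig"))
  tb <- chisq_2x2_vec(totals$f_d0, totals$m_d0, totals$f_big, totals$m_big, yates)
  ts <- chisq_2x2_vec(totals$f_d0, totals$m_d0,
                      totals$f_small, totals$m_small, yates)
  t16 <- chisq_2x2_vec(totals$f_d16, totals$m_d16, totals$f_big, totals$m_big, yates)
  out <- totals |>
    dplyr::mutate(p_d0_big = tb$p_value, p_d0_small = ts$p_value,
                  p_d16_big = t16$p_value) |>
    dplyr::mutate(
      q_d0_big = safe_qvalues(.data$p_d0_big, fdr),
      q_d0_small = safe_qvalues(.data$p_d0_small, fdr),
      q_d16_big = safe_qvalues(.data$p_d16_big, fdr),
      .by = c("female", "male", "replicate")
    ) |>
    dplyr::mutate(
      sig_d0_d23 = !is.na(.data$q_d0_big) & .data$q_d0_big < q_threshold &
        (is.na(.data$q_d0_small) | .data$q_d0_small < q_threshold),
      sig_d16_d23 = !is.na(.data$q_d16_big) & .data$q_d16_big < q_threshold,
      selected = .data$sig_d0_d23 & .data$sig_d16_d23
    ) |>
    dplyr::select("female", "male", "replicate", "contig", "n_markers",
                  dplyr::starts_with("f_"), dplyr::starts_with("m_"),
                  dplyr::starts_with("p_"), dplyr::starts_with("q_"),
                  "sig_d0_d23", "sig_d16_d23", "selected")
  class(out) <- c("contig_scan", class(out))
  out
}

#' Scan for size-associated SNPs (day-23 Big versus Small)
#'
#' For every heterozygous marker of a replicate with both size groups, the
#' reference/alternative read counts of the Big and Small day-23 pools form a
#' 2x2 table; markers with `p < alpha_base / nHet` are size-associated SNPs.
#' Replicates lacking a size group raise an error.
#'
#' @inheritParams viability_scan
#' @return A tibble of class `size_scan` with `statistic`, `p_value`,
#'   `alpha`, `significant` and the Big-versus-Small `direction`.
#' @export
size_scan <- function(counts, markers, alpha_base = 0.05, yates = FALSE) {
  cells <- scan_cells(counts, markers)
  both <- cells |>
    dplyr::summarise(
      ok = any(!is.na(.data$ref_big)) && any(!is.na(.data$ref_small)),
      .by = c("female", "male", "replicate"))
  if (any(!both$ok)) {
    stopf("replicate without both day-23 size groups: %s",
          paste(sample_key(both$female[!both$ok], both$male[!both$ok],
                           both$replicate[!both$ok], 23), collapse = ", "),
          class = "larvascan_scan_error")
  }
  tt <- chisq_2x2_vec(cells$ref_big, cells$alt_big,
                      cells$ref_small, cells$alt_small, yates)
  out <- cells |>
    dplyr::mutate(statistic = tt$statistic, p_value = tt$p_value) |>
    dplyr::left_join(n_het(markers), by = c("female", "male", "replicate")) |>
    dplyr::mutate(
      alpha = alpha_base / .data$n_het,
      significant = !is.na(.data$p_value) & .data$p_value < .data$alpha,
      af_big = .data$alt_big / (.data$ref_big + .data$alt_big),
      af_small = .data$alt_small / (.data$ref_small + .data$alt_small),
      direction = dplyr::case_when(
        is.na(.data$af_big) | is.na(.data$af_small) ~ NA_character_,
        .data$af_big > .data$af_small ~ "increase",
        .data$af_big < .data$af_small ~ "decrease",
        TRUE ~ "tie")
    ) |>
    dplyr::select("female", "male", "replicate", "marker_id", "statistic",
                  "p_value", "n_het", "alpha", "significant", "direction")
  class(out) <- c("size_scan", class(out))
  out
}

#' Intersect significant-marker sets across replicates
#'
#' Exact set intersection by id, with a per-set and pairwise overlap report —
#' the "common loci across replicates" step that guards against
#' replicate-specific noise.
#'
#' @param ... Two or more character vectors (or a single list of them),
#'   ideally named.
#' @return A list with `intersection`, per-set `sizes` and a tibble of
#'   `pairwise` overlap counts.
#' @export
#' @examples
#' overlap_sets(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"), r3 = "c")
overlap_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.character(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2) {
    stopf("need at least 2 sets", class = "larvascan_validation_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  pairs <- utils::combn(names(sets), 2)
  pairwise <- tibble::tibble(
    set_a = pairs[1, ], set_b = pairs[2, ],
    overlap = apply(pairs, 2, function(p) {
      length(intersect(sets[[p[1]]], sets[[p[2]]]))
    })
  )
  list(intersection = sort(Reduce(intersect, sets)),
       sizes = vapply(sets, length, integer(1)),
       pairwise = pairwise)
}
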