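# Summary-table assembly, percentages, phenotype correlation, pipeline runner.

#' Percentage with half-up rounding to the printed precision
#'
#' `100 * numerator / denominator`, rounded half away from zero at `decimals`
#' digits — the convention of printed summary tables.
#'
#' @param numerator,denominator Numeric (vectorized); the denominator must be
#'   positive.
#' @param decimals Printed decimal places.
#' @return Numeric percentages.
#' @export
#' @examples
#' percent(192, 5516, 3) # 3.481
percent <- function(numerator, denominator, decimals = 2) {
  if (any(is.na(denominator)) || any(denominator <= 0)) {
    stopf("denominator must be positive", class = "larvascan_parameter_error")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Assemble the per-replicate summary table
#'
#' One row per replicate combining the scan outputs: the heterozygous marker
#' count (nHet), per-comparison significant-marker counts, the
#' viability-associated SNP count and its percentage of nHet (3 decimals),
#' consistent-trend counts split by direction with their percentage (2
#' decimals), the size-associated SNP count with its percentage of nHet (2
#' decimals), per-day mean heterozygosity of the viability SNPs and day-23
#' divergence-direction counts. Missing upstream pieces yield NA cells, not
#' failures. Every percentage is recomputed from its own numerator and
#' denominator columns before returning (self-consistency audit); a mismatch
#' is an error.
#'
#' @param viability [viability_scan()] result.
#' @param size [size_scan()] result, or NULL when no replicate has both size
#'   groups.
#' @param trend [consistent_trend_markers()] result, or NULL.
#' @param freqs [compute_allele_freq()] result (for heterozygosity and
#'   divergence blocks), or NULL.
#' @return A `summary_table` tibble.
#' @export
build_summary <- function(viability, size = NULL, trend = NULL, freqs = NULL) {
  base <- viability |>
    dplyr::summarise(
      n_het = .data$n_het[1],
      d0_vs_d23big = sum(!is.na(.data$p_big) & .data$p_big < .data$alpha),
      d0_vs_d23small = if (all(is.na(.data$p_small))) NA_integer_ else
        sum(!is.na(.data$p_small) & .data$p_small < .data$alpha),
      viability_snps = sum(.data$significant),
      .by = c("female", "male", "replicate")
    ) |>
    dplyr::mutate(pct_viability = percent(.data$viability_snps, .data$n_het, 3))
  if (!is.null(trend)) {
    tr <- trend |>
      dplyr::summarise(
        trend_increasing = sum(.data$consistent & .data$direction == "increasing"),
        trend_decreasing = sum(.data$consistent & .data$direction == "decreasing"),
        .by = c("female", "male", "replicate"))
    base <- dplyr::left_join(base, tr, by = c("female", "male", "replicate")) |>
      dplyr::mutate(
        trend_increasing = dplyr::coalesce(.data$trend_increasing, 0L),
        trend_decreasing = dplyr::coalesce(.data$trend_decreasing, 0L),
        pct_trend = percent(.data$trend_increasing + .data$trend_decreasing,
                            .data$n_het, 2))
  } else {
    base$trend_increasing <- NA_integer_
    base$trend_decreasing <- NA_integer_
    base$pct_trend <- NA_real_
  }
  if (!is.null(size)) {
    sz <- size |>
      dplyr::summarise(size_snps = sum(.data$significant),
                       .by = c("female", "male", "replicate"))
    base <- dplyr::left_join(base, sz, by = c("female", "male", "replicate")) |>
      dplyr::mutate(pct_size = ifelse(is.na(.data$size_snps), NA_real_,
                                      percent(dplyr::coalesce(.data$size_snps, 0L),
                                              .data$n_het, 2)))
  } else {
    base$size_snps <- NA_integer_
    base$pct_size <- NA_real_
  }
  if (!is.null(freqs) &&
      nrow(viability[viability$significant, ]) > 0) {
    vsnps <- viability[viability$significant,
                       c("female", "male", "replicate", "marker_id")]
    het <- vsnps |>
      dplyr::group_by(.data$female, .data$male, .data$replicate) |>
      dplyr::group_modify(function(g, key) {
        fam_freqs <- freqs[freqs$female == key$female & freqs$male == key$male &
                             (is.na(freqs$replicate) |
                                freqs$replicate == key$replicate), ]
        h <- heterozygosity_summary(fam_freqs, g$marker_id)
        dv <- divergence_direction(fam_freqs, g$marker_id)
        slot <- paste0("het_d", h$day,
                       ifelse(is.na(h$size_group), "",
                              tolower(substr(h$size_group, 1, 1))))
        out <- tibble::as_tibble(as.list(setNames(h$mean_heterozygosity, slot)))
        if (nrow(dv)) {
          out$div_increase <- dv$n_increase[1]
          out$div_decrease <- dv$n_decrease[1]
          out$pct_div_increase <- percent(dv$n_increase[1],
                                          dv$n_increase[1] + dv$n_decrease[1] +
                                            dv$n_tie[1], 2)
        }
        out
      }) |>
      dplyr::ungroup()
    base <- dplyr::left_join(base, het, by = c("female", "male", "replicate"))
  }
  audit_percentages(base)
  class(base) <- c("summary_table", class(base))
  base
}

# Recompute every percentage column from its numerator/denominator and fail
# on mismatch (printed tables whose percentages cannot be reproduced from
# their own columns are flagged this way).
audit_percentages <- function(summary) {
  chk <- function(shown, num, den, decimals, label) {
    ok <- is.na(shown) | abs(shown - percent(num, den, decimals)) < 1e-9
    if (!all(ok)) {
      stopf("summary audit failed for %s in %d row(s)", label, sum(!ok),
            class = "larvascan_audit_error")
    }
  }
  chk(summary$pct_viability, summary$viability_snps, summary$n_het, 3,
      "pct_viability")
  if ("pct_trend" %in% names(summary)) {
    chk(summary$pct_trend,
        summary$trend_increasing + summary$trend_decreasing,
        summary$n_het, 2, "pct_trend")
  }
  if ("pct_size" %in% names(summary)) {
    chk(summary$pct_size, summary$size_snps, summary$n_het, 2, "pct_size")
  }
  invisible(summary)
}

#' Pearson correlation between day-23 survival and mean size
#'
#' Replicate-level test of the survival-growth trade-off. Outlier exclusion
#' is explicit and logged — never automatic: pass the replicates to drop as
#' `Fx.Mx.Rx` keys. Fewer than 3 points after exclusion is an error; zero
#' variance in either variable yields an NA estimate, reported as undefined.
#'
#' @param phenotypes Tibble with `female`, `male`, `replicate`, `day`,
#'   `survival_count`, `mean_size_um`.
#' @param exclude Character vector of `Fx.Mx.Rx` replicate keys to exclude.
#' @param day Phenotyping day to correlate at, default 23.
#' @return A one-row tibble: `estimate`, `p_value`, `n`, `excluded`.
#' @export
survival_size_correlation <- function(phenotypes, exclude = NULL, day = 23) {
  chk <- phenotypes |>
    dplyr::arrange(.data$female, .data$male, .data$replicate, .data$day) |>
    dplyr::summarise(ok = !is.unsorted(rev(.data$survival_count)),
                     .by = c("female", "male", "replicate"))
  if (any(!chk$ok)) {
    warn(sprintf("survival increases over time in %d replicate(s)", sum(!chk$ok)))
  }
  d <- phenotypes[phenotypes$day == day, ]
  key <- paste0("F", d$female, ".M", d$male, ".R", d$replicate)
  if (!is.null(exclude)) {
    inform(sprintf("excluding replicate(s): %s", paste(exclude, collapse = ", ")))
    d <- d[!key %in% exclude, ]
  }
  if (any(d$mean_size_um <= 0, na.rm = TRUE)) {
    stopf("sizes must be positive", class = "larvascan_validation_error")
  }
  if (nrow(d) < 3) {
    stopf("need at least 3 replicates after exclusion",
          class = "larvascan_parameter_error")
  }
  if (sd(d$survival_count) == 0 || sd(d$mean_size_um) == 0) {
    warn("zero variance; correlation undefined")
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_,
                          n = nrow(d), excluded = length(exclude %||% character())))
  }
  ht <- cor.test(d$survival_count, d$mean_size_um, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate), p_value = ht$p.value,
                 n = nrow(d), excluded = length(exclude %||% character()))
}

#' Run the full analysis pipeline
#'
#' Filter -> allele dynamics -> scans -> trend -> summary, from either a
#' simulated study ([simulate_pool_study()]) or a counts + parents pair. The
#' returned manifest records every threshold and seed, so a rerun with the
#' same inputs reproduces every output exactly.
#'
#' @param counts A pooled count tibble, or a `pool_study`.
#' @param parents Parental genotype tibble (ignored when `counts` is a
#'   `pool_study`).
#' @param min_parent_depth,min_allele_depth Filter thresholds (40x / 20x).
#' @param alpha_base Base significance level for the `alpha_base / nHet`
#'   rules.
#' @param q_threshold q-value threshold for haplotype/contig scans.
#' @param fdr `"bh"` or `"storey"`.
#' @param yates Continuity correction flag passed to every scan.
#' @param trend_method Consistency rule, see [consistent_trend_markers()].
#' @return A list of stage outputs (`counts`, `markers`, `freqs`, `deltas`,
#'   `viability`, `haplotype`, `contigs`, `trend`, `size`, `summary`,
#'   `manifest`).
#' @export
run_pipeline <- function(counts, parents = NULL,
                         min_parent_depth = 40, min_allele_depth = 20,
                         alpha_base = 0.05, q_threshold = 0.05,
                         fdr = c("bh", "storey"), yates = FALSE,
                         trend_method = "delta") {
  fdr <- match.arg(fdr)
  seed <- NULL
  if (inherits(counts, "pool_study")) {
    parents <- counts$parents
    seed <- counts$config$seed
    counts <- counts$counts
  }
  if (is.null(parents)) {
    stopf("`parents` is required", class = "larvascan_validation_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
            class = "larvascan_pipeline_error")
    })
  }
  parents_f <- stage("parental_depth", filter_parental_depth(parents, min_parent_depth))
  counts_f <- stage("zero_recovery", apply_zero_recovery_rule(counts))
  markers <- stage("heterozygous_markers",
                   select_heterozygous_markers(counts_f, parents_f, min_allele_depth))
  freqs <- stage("allele_freq", compute_allele_freq(counts_f))
  deltas <- stage("normalize", normalize_to_day0(freqs))
  viability <- stage("viability_scan",
                     viability_scan(counts_f, markers, alpha_base, yates))
  haplotype <- stage("haplotype_scan",
                     haplotype_scan(counts_f, parents_f, markers, q_threshold,
                                    fdr, yates))
  contigs <- stage("contig_scan",
                   contig_scan(counts_f, parents_f, markers, q_threshold,
                               fdr, yates))
  trend <- stage("trend", consistent_trend_markers(deltas, contigs, trend_method))
  has_small <- any(counts_f$day == 23 & !is.na(counts_f$size_group) &
                     counts_f$size_group == "Small")
  size <- if (has_small) {
    stage("size_scan", size_scan(counts_f, markers, alpha_base, yates))
  } else NULL
  summary <- stage("summary", build_summary(viability, size, trend, freqs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("larvascan")),
    seed = seed, min_parent_depth = min_parent_depth,
    min_allele_depth = min_allele_depth, alpha_base = alpha_base,
    q_threshold = q_threshold, fdr = fdr, yates = yates,
    trend_method = trend_method,
    n_markers_in = length(unique(counts$marker_id)),
    n_het = n_het(markers)
  )
  list(counts = counts_f, markers = markers, freqs = freqs, deltas = deltas,
       viability = viability, haplotype = haplotype, contigs = contigs,
       trend = trend, size = size, summary = summary, manifest = manifest)
}
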