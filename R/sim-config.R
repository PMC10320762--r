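#' Configure a synthetic pooled larval study
#'
#' Builds the parameter set for the synthetic-data generator. Defaults emulate
#' the hatchery design the package targets: a full-factorial NC-II cross of 4
#' females by 2 males, 3 replicate tanks per family, 120,000 fertilized embryos
#' per replicate, and type-III survivorship with staged mortality across
#' sampling days 0, 11, 16 and 23 compounding to roughly 9% survival (the
#' biologically typical 2-20% window). Day-23 survivors are split into Big and
#' Small fractions at a sieve quantile, and pooled read counts are drawn per
#' marker at a configurable depth.
#'
#' Selected ("planted") loci are organised into whole contigs and are
#' *segregating*: individual allele dosages at those markers are drawn from
#' Binomial(2, `start_freq`), emulating residual segregating variation at
#' selected sites, which is the only structure under which selection can move
#' a within-family pooled frequency. Neutral informative markers stay fully
#' heterozygous in the F1, as the cross dictates.
#'
#' @param n_females,n_males Cross dimensions (NC-II factorial).
#' @param n_replicates Replicate tanks per family.
#' @param n_markers Total markers on the panel.
#' @param markers_per_contig Markers per contig; `n_markers` must be a
#'   multiple.
#' @param start_cohort_size Fertilized embryos per replicate tank at day 0.
#' @param survival_schedule Named per-stage survival fractions for
#'   D0->D11->D16->D23, each in (0, 1].
#' @param n_viability_loci,n_size_loci Numbers of planted viability and size
#'   loci (placed on disjoint whole contigs at the start of the panel).
#' @param viability_s Selection coefficient magnitude for planted viability
#'   loci: a scalar applied at every stage, or a length-3 vector of
#'   stage-specific magnitudes (D0->D11, D11->D16, D16->D23), since larval
#'   selection is typically stage-specific (strongest around metamorphosis).
#' @param viability_regime `"directional"` (constant s; alternating sign
#'   across loci so both directions occur), `"fluctuating"` (s flips sign
#'   between stages), or `"balancing"` (heterozygote advantage `1 + s` for the
#'   heterozygote).
#' @param viability_start_freq Day-0 alternative-allele frequency of planted
#'   viability loci. Defaults to 0.5 for directional/fluctuating regimes and
#'   0.2 for the balancing regime (so heterozygosity has room to rise).
#' @param size_effect_scale Per-allele liability effect of each planted size
#'   locus, in units of the unit-variance environmental noise. The default
#'   0.55 yields an expected Big-Small allele-frequency gap of about 0.2 at a
#'   median sieve split.
#' @param sieve_quantile Liability quantile of the sieve: the top
#'   `1 - sieve_quantile` of day-23 survivors are labelled Big.
#' @param pool_sample_size Individuals sampled into the DNA pool on each
#'   phenotyping day (the study's pools ranged from dozens to ~10^4).
#' @param mean_depth Mean sequencing depth (reads) per marker per pool.
#' @param depth_dispersion Negative-binomial overdispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson depth.
#' @param parental_mean_depth Mean depth of the parental genotype calls.
#' @param survival_jitter_sd Replicate-level lognormal-ish jitter of the
#'   survival schedule (tank effects).
#' @param size_tradeoff Strength of the negative replicate-level coupling
#'   between survival and mean size (0 removes the trade-off).
#' @param size_mean_um,size_sd_um Day-23 mean larval size scale (micrometres).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration and seed.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_markers = 50, markers_per_contig = 5,
#'                   start_cohort_size = 2000, seed = 1)
sim_config <- function(n_females = 4,
                       n_males = 2,
                       n_replicates = 3,
                       n_markers = 200,
                       markers_per_contig = 5,
                       start_cohort_size = 120000,
                       survival_schedule = c(d11 = 0.40, d16 = 0.45, d23 = 0.50),
                       n_viability_loci = 0,
                       n_size_loci = 0,
                       viability_s = 0.3,
                       viability_regime = c("directional", "fluctuating", "balancing"),
                       viability_start_freq = NULL,
                       size_effect_scale = 0.55,
                       sieve_quantile = 0.5,
                       pool_sample_size = 5000,
                       mean_depth = 100,
                       depth_dispersion = 0,
                       parental_mean_depth = 100,
                       survival_jitter_sd = 0.1,
                       size_tradeoff = 0.7,
                       size_mean_um = 150,
                       size_sd_um = 15,
                       seed = 1L) {
  viability_regime <- match.arg(viability_regime)
  if (is.null(viability_start_freq)) {
    viability_start_freq <- if (viability_regime == "balancing") 0.2 else 0.5
  }
  for (nm in c("n_females", "n_males", "n_replicates", "n_markers",
               "markers_per_contig", "start_cohort_size", "pool_sample_size")) {
    if (!is_count(get(nm)) || get(nm) < 1) {
      stopf("`%s` must be a positive integer", nm, class = "larvascan_config_error")
    }
  }
  if (n_markers %% markers_per_contig != 0) {
    stopf("`n_markers` must be a multiple of `markers_per_contig`",
          class = "larvascan_config_error")
  }
  if (length(survival_schedule) != 3 || any(survival_schedule <= 0) ||
      any(survival_schedule > 1)) {
    stopf("`survival_schedule` must be 3 per-stage fractions in (0, 1]",
          class = "larvascan_config_error")
  }
  if (sieve_quantile <= 0 || sieve_quantile >= 1) {
    stopf("`sieve_quantile` must lie in (0, 1)", class = "larvascan_config_error")
  }
  if (n_viability_loci + n_size_loci > n_markers) {
    stopf("planted loci exceed `n_markers`", class = "larvascan_config_error")
  }
  if (mean_depth <= 0) {
    stopf("`mean_depth` must be positive", class = "larvascan_config_error")
  }
  if (depth_dispersion < 0) {
    stopf("`depth_dispersion` must be >= 0", class = "larvascan_config_error")
  }
  if (viability_start_freq <= 0 || viability_start_freq >= 1) {
    stopf("`viability_start_freq` must lie in (0, 1)",
          class = "larvascan_config_error")
  }
  if (!length(viability_s) %in% c(1L, 3L) || !is.numeric(viability_s)) {
    stopf("`viability_s` must be a scalar or length-3 per-stage vector",
          class = "larvascan_config_error")
  }
  viability_s <- rep(viability_s, length.out = 3)
  names(survival_schedule) <- c("d11", "d16", "d23")
  cfg <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    n_replicates = as.integer(n_replicates), n_markers = as.integer(n_markers),
    markers_per_contig = as.integer(markers_per_contig),
    n_contigs = as.integer(n_markers / markers_per_contig),
    start_cohort_size = as.integer(start_cohort_size),
    survival_schedule = survival_schedule,
    n_viability_loci = as.integer(n_viability_loci),
    n_size_loci = as.integer(n_size_loci),
    viability_s = viability_s, viability_regime = viability_regime,
    viability_start_freq = viability_start_freq,
    size_effect_scale = size_effect_scale, sieve_quantile = sieve_quantile,
    pool_sample_size = as.integer(pool_sample_size),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    parental_mean_depth = parental_mean_depth,
    survival_jitter_sd = survival_jitter_sd, size_tradeoff = size_tradeoff,
    size_mean_um = size_mean_um, size_sd_um = size_sd_um,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cross: %d females x %d males, %d replicates/family\n",
              x$n_females, x$n_males, x$n_replicates))
  cat(sprintf("  panel: %d markers in %d contigs (%d viability, %d size loci)\n",
              x$n_markers, x$n_contigs, x$n_viability_loci, x$n_size_loci))
  cat(sprintf("  cohort: %d embryos/replicate, survival %s (overall %.1f%%)\n",
              x$start_cohort_size,
              paste(signif(x$survival_schedule, 2), collapse = " x "),
              100 * prod(x$survival_schedule)))
  cat(sprintf("  pooling: %d individuals, depth %g (dispersion %g), seed %s\n",
              x$pool_sample_size, x$mean_depth, x$depth_dispersion,
              x$seed %||% "none"))
  invisible(x)
}

# Marker panel layout: ids, contig membership, planted-locus labels, per-stage
# fitness of the three genotypes (w0/w1/w2 = dosage 0/1/2 of the alternative
# allele), start frequencies and liability effects. Planted loci occupy whole
# contigs at the head of the panel so contig-level tests see coherent signal.
marker_layout <- function(config) {
  n <- config$n_markers
  mpc <- config$markers_per_contig
  contig <- sprintf("C%04d", rep(seq_len(config$n_contigs), each = mpc))
  layout <- tibble::tibble(
    marker_id = sprintf("M%05d", seq_len(n)),
    contig = contig,
    position = rep(seq_len(mpc), config$n_contigs) * 500L,
    label = "neutral",
    segregating = FALSE,
    start_freq = 0.5,
    size_effect = 0,
    regime = NA_character_
  )
  s <- config$viability_s
  nv <- config$n_viability_loci
  if (nv > 0) {
    idx <- seq_len(nv)
    layout$label[idx] <- "viability"
    layout$segregating[idx] <- TRUE
    layout$start_freq[idx] <- config$viability_start_freq
    layout$regime[idx] <- config$viability_regime
  }
  if (config$n_size_loci > 0) {
    first <- (ceiling(nv / mpc)) * mpc # next free whole contig
    idx <- first + seq_len(config$n_size_loci)
    if (max(idx) > n) stopf("not enough contigs for planted size loci",
                            class = "larvascan_config_error")
    layout$label[idx] <- "size"
    layout$segregating[idx] <- TRUE
    layout$size_effect[idx] <- config$size_effect_scale
  }
  # Per-stage genotype fitness for planted viability loci.
  stages <- c("d11", "d16", "d23")
  fitness <- vector("list", n)
  for (i in seq_len(n)) {
    if (layout$label[i] != "viability") next
    # direction alternates per contig so that contig-level aggregation sees
    # a coherent signal while both directions occur across the panel
    phase <- if (ceiling(i / mpc) %% 2 == 1) 1 else -1
    w <- matrix(1, nrow = 3, ncol = 3, dimnames = list(NULL, stages))
    for (k in seq_along(stages)) {
      if (config$viability_regime == "balancing") {
        w[, k] <- c(1, 1 + s[k], 1) # heterozygote advantage
      } else {
        # per-copy multiplicative; a negative phase selects against the
        # focal allele with per-copy fitness 1/(1+s), keeping w positive
        # for any s > 0
        ph <- if (config$viability_regime == "fluctuating") {
          phase * (-1)^(k - 1)
        } else {
          phase
        }
        w[, k] <- (1 + s[k])^(ph * (0:2))
      }
    }
    fitness[[i]] <- w
  }
  layout$fitness <- fitness
  layout
}
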