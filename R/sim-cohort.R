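# Larval cohort objects and the per-stage simulation operations.
#
# A cohort tracks individual identity only where it matters: at segregating
# (planted) loci each individual carries an alternative-allele dosage in
# {0, 1, 2}; at every other informative marker all F1 individuals are
# heterozygous (opposite-homozygote parents), so the within-cohort frequency
# is exactly 1/2 for any subset and needs no per-individual storage.

new_cohort <- function(female, male, replicate, ids, seg_markers,
                       doses = NULL) {
  if (is.null(doses)) {
    doses <- matrix(integer(), nrow = length(ids), ncol = length(seg_markers))
  }
  structure(
    list(female = as.integer(female), male = as.integer(male),
         replicate = if (is.null(replicate)) NA_integer_ else as.integer(replicate),
         ids = as.integer(ids), n = length(ids),
         seg_markers = seg_markers, doses = doses),
    class = "larval_cohort"
  )
}

#' @export
print.larval_cohort <- function(x, ...) {
  cat(sprintf("<larval_cohort> F%d.M%d%s: %d individuals, %d segregating loci\n",
              x$female, x$male,
              if (is.na(x$replicate)) "" else sprintf(".R%d", x$replicate),
              x$n, length(x$seg_markers)))
  invisible(x)
}

subset_cohort <- function(cohort, keep) {
  cohort$ids <- cohort$ids[keep]
  cohort$doses <- cohort$doses[keep, , drop = FALSE]
  cohort$n <- length(cohort$ids)
  cohort
}

# True alternative-allele frequency of every marker in `marker_ids` within the
# cohort (1/2 at non-segregating informative markers).
cohort_freq <- function(cohort, marker_ids) {
  f <- rep(0.5, length(marker_ids))
  names(f) <- marker_ids
  if (length(cohort$seg_markers) && cohort$n > 0) {
    seg <- intersect(marker_ids, cohort$seg_markers)
    f[seg] <- colMeans(cohort$doses[, match(seg, cohort$seg_markers),
                                    drop = FALSE]) / 2
  }
  f
}

#' Apply one stage of viability selection to a larval cohort
#'
#' Survival is multiplicative across loci and per-allele-copy within a locus:
#' an individual with dosage `x` at a locus whose stage fitness triple is
#' `(w0, w1, w2)` contributes `w[x + 1]` to its fitness product. For the
#' directional regime the triple is `(1, 1+s, (1+s)^2)`, which makes the
#' expected one-locus allele-frequency recursion exactly the genic
#' `p' = p(1+s) / (1+ps)`. Survival probabilities are rescaled so the expected
#' number of survivors equals `survival_fraction * n`.
#'
#' @param cohort A `larval_cohort`.
#' @param stage_fitness Named list of genotype fitness triples `c(w0, w1, w2)`
#'   keyed by marker id (markers absent from the list are neutral), or a named
#'   numeric vector of selection coefficients `s` shorthand for
#'   `(1, 1+s, (1+s)^2)`.
#' @param survival_fraction Expected surviving fraction, in (0, 1].
#' @return The surviving cohort (a subset of the input individuals).
#' @export
apply_stage_selection <- function(cohort, stage_fitness, survival_fraction) {
  stopifnot(inherits(cohort, "larval_cohort"))
  if (cohort$n == 0) {
    stopf("cohort is empty", class = "larvascan_parameter_error")
  }
  if (survival_fraction <= 0 || survival_fraction > 1) {
    stopf("`survival_fraction` must lie in (0, 1]",
          class = "larvascan_parameter_error")
  }
  if (is.numeric(stage_fitness)) {
    stage_fitness <- lapply(stage_fitness, function(s) c(1, 1 + s, (1 + s)^2))
  }
  w <- rep(1, cohort$n)
  sel <- intersect(names(stage_fitness), cohort$seg_markers)
  for (m in sel) {
    triple <- stage_fitness[[m]]
    if (any(triple <= 0)) {
      stopf("fitness for marker %s is nonpositive", m,
            class = "larvascan_parameter_error")
    }
    w <- w * triple[cohort$doses[, match(m, cohort$seg_markers)] + 1]
  }
  if (all(w == w[1])) {
    # No fitness variance: survivors are a uniform random subsample.
    n_surv <- rbinom(1, cohort$n, survival_fraction)
    keep <- sort(sample.int(cohort$n, n_surv))
  } else {
    p <- pmin(1, survival_fraction * cohort$n * w / sum(w))
    keep <- which(runif(cohort$n) < p)
  }
  subset_cohort(cohort, keep)
}

#' Split day-23 survivors into Big and Small sieve fractions
#'
#' Each survivor gets a polygenic size liability: the sum of per-locus
#' liability effects times allele dosage, plus standard Gaussian noise. The
#' top `1 - sieve_quantile` of the cohort by liability is labelled Big
#' (retained on the sieve), the rest Small.
#'
#' @param cohort A `larval_cohort` of day-23 survivors.
#' @param size_effects Named numeric vector of per-allele liability effects
#'   (markers absent contribute nothing).
#' @param sieve_quantile Liability quantile of the sieve cut, in (0, 1).
#' @return A list with `larval_cohort` elements `big` and `small`.
#' @export
assign_size_groups <- function(cohort, size_effects, sieve_quantile = 0.5) {
  stopifnot(inherits(cohort, "larval_cohort"))
  if (sieve_quantile <= 0 || sieve_quantile >= 1) {
    stopf("`sieve_quantile` must lie in (0, 1)",
          class = "larvascan_parameter_error")
  }
  if (cohort$n == 0) {
    warn("empty cohort: no size groups assigned")
    return(list(big = cohort, small = cohort))
  }
  liability <- rnorm(cohort$n)
  eff <- size_effects[names(size_effects) %in% cohort$seg_markers]
  if (length(eff)) {
    cols <- match(names(eff), cohort$seg_markers)
    liability <- liability +
      as.vector(cohort$doses[, cols, drop = FALSE] %*% unname(eff))
  }
  n_big <- round(cohort$n * (1 - sieve_quantile))
  ord <- order(liability, decreasing = TRUE)
  big_idx <- sort(ord[seq_len(n_big)])
  small_idx <- sort(ord[setdiff(seq_len(cohort$n), seq_len(n_big))])
  list(big = subset_cohort(cohort, big_idx),
       small = subset_cohort(cohort, small_idx),
       liability = liability)
}

#' Draw pooled sequencing read counts from a cohort
#'
#' Pooled sequencing noise has two stages: first `pool_sample_size`
#' individuals are sampled without replacement into the DNA pool (the study's
#' pools were far smaller than the cohorts), then per-marker depth is drawn
#' from a negative binomial around `mean_depth` (Poisson when
#' `depth_dispersion = 0`) and the alternative-allele read count is binomial
#' with success probability equal to the alternative-allele frequency among
#' the pooled individuals. Reference and alternative counts sum to the depth.
#'
#' @param cohort A `larval_cohort`.
#' @param marker_ids Markers to report (defaults to segregating loci only).
#' @param pool_sample_size Individuals sampled into the pool (capped at the
#'   cohort size).
#' @param mean_depth Mean reads per marker; must be positive.
#' @param depth_dispersion Negative-binomial overdispersion
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson depth.
#' @return A tibble with `marker_id`, `ref_count`, `alt_count` and the latent
#'   `pool_alt_freq` among pooled individuals.
#' @export
sample_pool_reads <- function(cohort, marker_ids = NULL,
                              pool_sample_size = 5000,
                              mean_depth = 100, depth_dispersion = 0) {
  stopifnot(inherits(cohort, "larval_cohort"))
  if (mean_depth <= 0) {
    stopf("`mean_depth` must be positive", class = "larvascan_parameter_error")
  }
  marker_ids <- marker_ids %||% cohort$seg_markers
  n_pool <- min(pool_sample_size, cohort$n)
  pooled <- if (n_pool < cohort$n) {
    subset_cohort(cohort, sort(sample.int(cohort$n, n_pool)))
  } else {
    cohort
  }
  freq <- cohort_freq(pooled, marker_ids)
  m <- length(marker_ids)
  depth <- if (depth_dispersion == 0) {
    rpois(m, mean_depth)
  } else {
    rnbinom(m, mu = mean_depth, size = 1 / depth_dispersion)
  }
  alt <- rbinom(m, depth, freq)
  tibble::tibble(marker_id = marker_ids,
                 ref_count = as.integer(depth - alt),
                 alt_count = as.integer(alt),
                 pool_alt_freq = unname(freq))
}
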