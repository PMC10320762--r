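# End-to-end synthetic pooled larval study.

stage_fitness_list <- function(layout, stage) {
  idx <- which(!vapply(layout$fitness, is.null, logical(1)))
  out <- lapply(idx, function(i) layout$fitness[[i]][, stage])
  names(out) <- layout$marker_id[idx]
  out
}

simulate_cross_impl <- function(config) {
  layout <- marker_layout(config)
  fams <- tidyr::expand_grid(female = seq_len(config$n_females),
                             male = seq_len(config$n_males))
  n_mark <- config$n_markers
  parents <- fams |>
    dplyr::reframe(
      marker_id = layout$marker_id,
      contig = layout$contig,
      position = layout$position,
      female_gt = "0/0",
      male_gt = "1/1",
      female_depth = rpois(n_mark, config$parental_mean_depth),
      male_depth = rpois(n_mark, config$parental_mean_depth),
      .by = c("female", "male")
    )
  seg <- layout$marker_id[layout$segregating]
  p0 <- layout$start_freq[layout$segregating]
  family_pools <- vector("list", nrow(fams))
  cohorts <- list()
  for (i in seq_len(nrow(fams))) {
    n_total <- config$n_replicates * config$start_cohort_size
    doses <- if (length(seg)) {
      matrix(rbinom(n_total * length(seg), 2, rep(p0, each = n_total)),
             nrow = n_total, ncol = length(seg))
    } else NULL
    pool <- new_cohort(fams$female[i], fams$male[i], NULL,
                       seq_len(n_total), seg, doses)
    family_pools[[i]] <- pool
    split_ids <- sample.int(n_total)
    for (r in seq_len(config$n_replicates)) {
      idx <- sort(split_ids[((r - 1) * config$start_cohort_size + 1):
                              (r * config$start_cohort_size)])
      rc <- subset_cohort(pool, idx)
      rc$replicate <- r
      cohorts[[length(cohorts) + 1]] <- rc
    }
  }
  list(parents = parents, family_pools = family_pools, cohorts = cohorts,
       layout = layout)
}

#' Simulate an NC-II factorial cross and its day-0 larval cohorts
#'
#' Every emitted marker has opposite-homozygote parents within each family
#' (the female carries the reference allele, the male the alternative), so
#' all F1 individuals are heterozygous at every informative marker. Planted
#' selected loci additionally carry segregating dosages drawn from
#' Binomial(2, start frequency). The fertilized family population is created
#' before the replicate split (as day-0 pools are), then divided at random
#' into `n_replicates` cohorts of `start_cohort_size` individuals.
#'
#' @param config A [sim_config()].
#' @return A list: `parents` (per-family parental genotype/depth tibble),
#'   `family_pools` (pre-split fertilized populations, one per family),
#'   `cohorts` (per-replicate day-0 `larval_cohort`s) and `layout` (the marker
#'   panel with ground-truth labels).
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cross_impl(config))
}

#' Simulate a complete pooled larval study with known ground truth
#'
#' Runs the full generative model: NC-II cross, staged type-III mortality with
#' per-locus viability selection across days 0/11/16/23, a sieve split of
#' day-23 survivors into Big and Small on a polygenic size liability, and
#' two-stage pooled sequencing (individual subsample, then binomial reads) on
#' every phenotyping day. Day-0 pools are drawn from each family's fertilized
#' population before the replicate split. Replicate-level survival jitter and
#' an optional negative survival-size coupling generate the phenotype table.
#'
#' @param config A [sim_config()].
#' @return A `pool_study` list: `counts` (pooled count table, one row per
#'   marker x sample), `parents`, `phenotypes` (per replicate x day survival
#'   and mean size), `truth` (marker labels and true cohort allele frequencies
#'   at segregating loci) and `config`.
#' @export
#' @examples
#' study <- simulate_pool_study(sim_config(
#'   n_females = 1, n_males = 1, n_replicates = 2, n_markers = 20,
#'   markers_per_contig = 5, start_cohort_size = 500, pool_sample_size = 200,
#'   seed = 42))
#' study$counts
simulate_pool_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cross <- simulate_cross_impl(config)
    layout <- cross$layout
    ids <- layout$marker_id
    seg <- ids[layout$segregating]
    size_eff <- setNames(layout$size_effect[layout$segregating], seg)
    size_eff <- size_eff[size_eff != 0]
    stages <- list(d11 = 11L, d16 = 16L, d23 = 23L)
    fit <- lapply(names(stages), function(st) stage_fitness_list(layout, st))
    names(fit) <- names(stages)

    rows <- list()
    truth_rows <- list()
    pheno <- list()
    add_counts <- function(reads, female, male, replicate, day, size_group) {
      rows[[length(rows) + 1]] <<- reads |>
        dplyr::transmute(
          marker_id = .data$marker_id,
          female = as.integer(female), male = as.integer(male),
          replicate = if (is.null(replicate)) NA_integer_ else as.integer(replicate),
          day = as.integer(day), size_group = size_group %||% NA_character_,
          ref_count = .data$ref_count, alt_count = .data$alt_count,
          missing = (.data$ref_count + .data$alt_count) == 0L
        )
    }
    add_truth <- function(cohort, day, size_group = NA_character_) {
      if (!length(seg)) return(invisible())
      truth_rows[[length(truth_rows) + 1]] <<- tibble::tibble(
        marker_id = seg,
        female = cohort$female, male = cohort$male,
        replicate = cohort$replicate, day = as.integer(day),
        size_group = size_group,
        true_freq = unname(cohort_freq(cohort, seg))
      )
    }
    draw <- function(cohort) {
      sample_pool_reads(cohort, ids, config$pool_sample_size,
                        config$mean_depth, config$depth_dispersion)
    }

    fams <- unique(cross$parents[c("female", "male")])
    for (i in seq_len(nrow(fams))) {
      fp <- cross$family_pools[[i]]
      add_counts(draw(fp), fp$female, fp$male, NULL, 0L, NULL)
      add_truth(fp, 0L)
    }
    for (cohort in cross$cohorts) {
      u <- rnorm(1)
      sched <- config$survival_schedule *
        exp(config$survival_jitter_sd * u - config$survival_jitter_sd^2 / 2)
      sched <- pmin(sched, 1)
      surv <- c(d0 = cohort$n)
      ch <- cohort
      for (st in names(stages)) {
        ch <- apply_stage_selection(ch, fit[[st]], sched[[st]])
        surv[st] <- ch$n
        if (st != "d23") {
          add_counts(draw(ch), ch$female, ch$male, ch$replicate, stages[[st]], NULL)
          add_truth(ch, stages[[st]])
        }
      }
      groups <- assign_size_groups(ch, size_eff, config$sieve_quantile)
      add_counts(draw(groups$big), ch$female, ch$male, ch$replicate, 23L, "Big")
      add_truth(groups$big, 23L, "Big")
      add_counts(draw(groups$small), ch$female, ch$male, ch$replicate, 23L, "Small")
      add_truth(groups$small, 23L, "Small")
      size23 <- config$size_mean_um -
        config$size_tradeoff * config$size_sd_um * u +
        rnorm(1, 0, 0.3 * config$size_sd_um)
      pheno[[length(pheno) + 1]] <- tibble::tibble(
        female = cohort$female, male = cohort$male,
        replicate = cohort$replicate,
        day = c(0L, 11L, 16L, 23L),
        survival_count = as.integer(surv),
        mean_size_um = size23 * c(0.05, 0.45, 0.70, 1.00)
      )
    }
    counts <- dplyr::bind_rows(rows) |>
      dplyr::left_join(layout[c("marker_id", "contig", "position")],
                       by = "marker_id") |>
      dplyr::select("marker_id", "contig", "position", "female", "male",
                    "replicate", "day", "size_group", "ref_count",
                    "alt_count", "missing")
    counts$ref_count[counts$missing] <- NA_integer_
    counts$alt_count[counts$missing] <- NA_integer_
    truth <- list(
      layout = layout[setdiff(names(layout), "fitness")],
      frequencies = if (length(truth_rows)) dplyr::bind_rows(truth_rows)
                    else tibble::tibble()
    )
    structure(list(counts = counts, parents = cross$parents,
                   phenotypes = dplyr::bind_rows(pheno),
                   truth = truth, config = config),
              class = "pool_study")
  })
}

#' @export
print.pool_study <- function(x, ...) {
  cat(sprintf(
    "<pool_study> %d markers, %d samples, %d planted loci (seed %s)\n",
    length(unique(x$counts$marker_id)),
    nrow(unique(x$counts[c("female", "male", "replicate", "day", "size_group")])),
    sum(x$truth$layout$label != "neutral"), x$config$seed %||% "none"))
  invisible(x)
}

#' Write simulator ground truth as JSON
#'
#' @param truth The `truth` element of a [simulate_pool_study()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(
    list(layout = truth$layout, frequencies = truth$frequencies),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write or read a simulator configuration as YAML
#'
#' Keys are exactly the [sim_config()] fields.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$survival_schedule <- as.list(x$survival_schedule)
  x$n_contigs <- NULL # derived
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$survival_schedule <- unlist(x$survival_schedule)
  do.call(sim_config, x)
}
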