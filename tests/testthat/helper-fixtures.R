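# Fixture builders shared across tests. Everything is constructed in code;
# counts are chosen so that "significant" cells are unambiguous at the
# thresholds under test and "null" cells are exactly independent.

# One marker's replicate series as count-table rows. `ref`/`alt` are vectors
# aligned with `days`/`sizes`; day-0 rows carry no replicate id.
series_counts <- function(marker_id, ref, alt,
                          days = c(0, 11, 16, 23, 23),
                          sizes = c(NA, NA, NA, "Big", "Small"),
                          female = 1, male = 1, replicate = 1,
                          contig = "C0001", position = 1L) {
  tibble::tibble(
    marker_id = marker_id, contig = contig, position = as.integer(position),
    female = as.integer(female), male = as.integer(male),
    replicate = ifelse(days == 0, NA_integer_, as.integer(replicate)),
    day = as.integer(days), size_group = as.character(sizes),
    ref_count = as.integer(ref), alt_count = as.integer(alt),
    missing = is.na(ref) | is.na(alt)
  )
}

# A scan-ready marker list (the heterozygous set) for constructed counts.
markers_of <- function(counts) {
  reps <- unique(counts[!is.na(counts$replicate),
                        c("female", "male", "replicate")])
  out <- dplyr::cross_join(reps,
                           tibble::tibble(marker_id = unique(counts$marker_id)))
  out[c("female", "male", "replicate", "marker_id")]
}

# Parental table declaring every marker informative (female hom-ref).
parents_of <- function(counts, female_gt = "0/0", male_gt = "1/1",
                       depth = 100) {
  mk <- unique(counts[c("marker_id", "contig", "position")])
  fams <- unique(counts[c("female", "male")])
  dplyr::cross_join(fams, mk) |>
    dplyr::mutate(female_gt = female_gt, male_gt = male_gt,
                  female_depth = depth, male_depth = depth)
}

# Replicate engineered to the worked-example marker tallies: nHet markers of
# which `big_only + dual` pass the D0-vs-D23Big test, `small_only + dual`
# pass D0-vs-D23Small, and `dual` pass both. Null cells repeat the day-0
# counts exactly (statistic 0); significant cells shift far beyond the
# 0.05/nHet critical value at depth 400.
table1_fixture <- function(n_het = 5516, big_only = 1077, small_only = 212,
                           dual = 192) {
  id <- sprintf("T%05d", seq_len(n_het))
  kind <- rep("null", n_het)
  kind[seq_len(dual)] <- "dual"
  kind[dual + seq_len(big_only)] <- "big"
  kind[dual + big_only + seq_len(small_only)] <- "small"
  null_c <- c(200L, 200L)
  sig_c <- c(360L, 40L) # both alleles >= 20x, far past the 0.05/nHet critical value
  big_ref <- ifelse(kind %in% c("dual", "big"), sig_c[1], null_c[1])
  big_alt <- ifelse(kind %in% c("dual", "big"), sig_c[2], null_c[2])
  small_ref <- ifelse(kind %in% c("dual", "small"), sig_c[1], null_c[1])
  small_alt <- ifelse(kind %in% c("dual", "small"), sig_c[2], null_c[2])
  counts <- dplyr::bind_rows(
    tibble::tibble(marker_id = id, day = 0L, size_group = NA_character_,
                   replicate = NA_integer_, ref_count = 200L, alt_count = 200L),
    tibble::tibble(marker_id = id, day = 23L, size_group = "Big",
                   replicate = 1L, ref_count = as.integer(big_ref),
                   alt_count = as.integer(big_alt)),
    tibble::tibble(marker_id = id, day = 23L, size_group = "Small",
                   replicate = 1L, ref_count = as.integer(small_ref),
                   alt_count = as.integer(small_alt))
  ) |>
    dplyr::mutate(contig = "C0001", position = 1L, female = 1L, male = 1L,
                  missing = FALSE) |>
    dplyr::select("marker_id", "contig", "position", "female", "male",
                  "replicate", "day", "size_group", "ref_count", "alt_count",
                  "missing")
  list(counts = counts, kind = kind,
       markers = tibble::tibble(female = 1L, male = 1L, replicate = 1L,
                                marker_id = id))
}

# Small simulated study used by several tests.
smoke_study <- function(seed = 11, ...) {
  simulate_pool_study(sim_config(
    n_females = 1, n_males = 1, n_replicates = 2, n_markers = 40,
    markers_per_contig = 5, start_cohort_size = 2000, pool_sample_size = 500,
    mean_depth = 200, n_viability_loci = 5, n_size_loci = 5, seed = seed, ...))
}
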