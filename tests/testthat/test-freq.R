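test_that("pooled allele frequencies are read-count ratios", {
  counts <- dplyr::bind_rows(
    series_counts("m1", ref = c(0, 35, 30, 30, 30), alt = c(50, 35, 70, 30, 30)))
  f <- compute_allele_freq(counts)
  expect_equal(f$alt_af[1], 1.0) # (ref 0, alt 50)
  expect_equal(f$ref_af[2], 0.5) # symmetric counts
  expect_equal(f$alt_af[3], 0.70) # 70 / (30 + 70)
  expect_equal(f$ref_af + f$alt_af, rep(1, 5))
  zero <- series_counts("z", ref = 0, alt = 0, days = 0, sizes = NA)
  expect_error(compute_allele_freq(zero),
               class = "larvascan_computation_error")
})

test_that("day-0 normalization gives the expected deltas", {
  depth <- 1000L
  traj <- c(0.5, 0.6, 0.4, 0.5, 0.5)
  counts <- series_counts("m1", ref = as.integer((1 - traj) * depth),
                          alt = as.integer(traj * depth))
  d <- compute_allele_freq(counts) |> normalize_to_day0()
  expect_equal(d$delta_af[order(d$day, d$size_group)], c(0.1, -0.1, 0, 0))

  flat <- series_counts("m2", ref = rep(300L, 5), alt = rep(300L, 5))
  d2 <- compute_allele_freq(flat) |> normalize_to_day0()
  expect_equal(d2$delta_af, rep(0, 4))
})

test_that("normalization is translation-consistent and needs day 0", {
  base <- c(0.30, 0.35, 0.40, 0.45, 0.42)
  mk <- function(id, traj) {
    series_counts(id, ref = as.integer(round((1 - traj) * 2000)),
                  alt = as.integer(round(traj * 2000)))
  }
  d1 <- compute_allele_freq(mk("a", base)) |> normalize_to_day0()
  d2 <- compute_allele_freq(mk("b", base + 0.2)) |> normalize_to_day0()
  expect_equal(d1$delta_af, d2$delta_af, tolerance = 1e-12)

  no_d0 <- mk("c", base)[-1, ]
  f <- compute_allele_freq(no_d0)
  expect_message(out <- normalize_to_day0(f), "lack a day-0")
  expect_equal(nrow(out), 0)
})

test_that("mean trajectories average over nonmissing markers", {
  counts <- dplyr::bind_rows(
    series_counts("m1", ref = c(60, 50, 50, 50, 50), alt = c(40, 50, 50, 50, 50)),
    series_counts("m2", ref = c(40, NA, 50, 50, 50), alt = c(60, NA, 50, 50, 50)))
  tr <- compute_allele_freq(counts) |> mean_trajectory()
  expect_equal(tr$mean_alt_af[tr$day == 0], 0.5) # (0.4 + 0.6) / 2
  expect_equal(tr$n_markers[tr$day == 11], 1L) # m2 missing at day 11
  expect_equal(tr$mean_alt_af[tr$day == 11], 0.5)
})

test_that("haplotype frequencies follow the parental orientation", {
  counts <- series_counts("m1", ref = c(70, 70, 70, 70, 70),
                          alt = c(30, 30, 30, 30, 30))
  f <- compute_allele_freq(counts)
  pg_ref <- parents_of(counts) # female hom-ref
  h <- haplotype_frequencies(f, pg_ref)
  expect_equal(h$female_af, rep(0.7, 5))
  expect_equal(h$male_af, rep(0.3, 5))
  pg_alt <- parents_of(counts, female_gt = "1/1", male_gt = "0/0")
  h2 <- haplotype_frequencies(f, pg_alt)
  expect_equal(h2$female_af, rep(0.3, 5)) # orientation flip
  expect_equal(h$female_af + h$male_af, rep(1, 5)) # conservation
  pg_bad <- parents_of(counts, female_gt = "0/1")
  expect_error(haplotype_frequencies(f, pg_bad),
               class = "larvascan_validation_error")
})

test_that("heterozygosity is ref_af * alt_af with the right extremes", {
  counts <- series_counts("m1",
                          ref = c(50L, 100L, 80L, 50L, 99L),
                          alt = c(50L, 0L, 20L, 50L, 1L))
  h <- compute_allele_freq(counts) |> heterozygosity()
  expect_equal(h$heterozygosity[1], 0.25) # maximum at 0.5/0.5
  expect_equal(h$heterozygosity[2], 0) # fixation
  expect_equal(h$heterozygosity[3], 0.16) # 0.8 * 0.2
  expect_true(all(h$heterozygosity <= 0.25))
})

test_that("divergence direction reproduces an engineered 97/95 split", {
  n <- 192
  up <- 97
  alt_end <- c(rep(210L, up), rep(190L, n - up))
  counts <- dplyr::bind_rows(
    tibble::tibble(marker_id = sprintf("d%03d", 1:n), day = 0L,
                   replicate = NA_integer_, size_group = NA_character_,
                   ref_count = 200L, alt_count = 200L),
    tibble::tibble(marker_id = sprintf("d%03d", 1:n), day = 23L,
                   replicate = 1L, size_group = "Big",
                   ref_count = 400L - alt_end, alt_count = alt_end)) |>
    dplyr::mutate(contig = "c", position = 1L, female = 1L, male = 1L,
                  missing = FALSE)
  f <- compute_allele_freq(counts)
  dv <- divergence_direction(f, sprintf("d%03d", 1:n))
  expect_equal(dv$n_increase, 97L)
  expect_equal(dv$n_decrease, 95L)
  expect_equal(dv$n_tie, 0L)
  expect_equal(percent(dv$n_increase, n, 2), 50.52)
  expect_equal(percent(dv$n_decrease, n, 2), 49.48)

  # ties are reported, never forced into either class
  tie <- counts
  tie$alt_count[tie$day == 23] <- 200L
  tie$ref_count[tie$day == 23] <- 200L
  dvt <- divergence_direction(compute_allele_freq(tie), sprintf("d%03d", 1:n))
  expect_equal(dvt$n_increase + dvt$n_decrease, 0L)
  expect_equal(dvt$n_tie, 192L)
})
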