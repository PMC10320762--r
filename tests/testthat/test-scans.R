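test_that("the viability scan reproduces an engineered replicate's tallies", {
  fx <- table1_fixture() # 5516 markers: 1269 Big-significant, 404 Small, 192 dual
  vs <- viability_scan(fx$counts, fx$markers)
  expect_equal(vs$n_het[1], 5516L)
  expect_equal(vs$alpha[1], 0.05 / 5516)
  expect_equal(sum(vs$p_big < vs$alpha, na.rm = TRUE), 1269L)
  expect_equal(sum(vs$p_small < vs$alpha, na.rm = TRUE), 404L)
  expect_equal(sum(vs$significant), 192L)
  expect_setequal(vs$marker_id[vs$significant], fx$markers$marker_id[fx$kind == "dual"])
  # identical day-0 and day-23 counts can never be significant
  expect_false(any(vs$significant[fx$kind == "null"]))
  g <- glance(vs)
  expect_equal(g$n_significant, 192L)
})

test_that("a replicate without a Small group is decided by the Big test alone", {
  fx <- table1_fixture(n_het = 50, big_only = 7, small_only = 0, dual = 0)
  counts <- fx$counts[is.na(fx$counts$size_group) |
                        fx$counts$size_group != "Small", ]
  vs <- viability_scan(counts, fx$markers)
  expect_true(all(is.na(vs$p_small)))
  expect_equal(sum(vs$significant), 7L)
  # but with no day-23 sample at all the scan refuses to run
  no23 <- counts[counts$day != 23, ]
  expect_error(viability_scan(no23, fx$markers),
               class = "larvascan_scan_error")
})

test_that("the haplotype scan controls q-values and ignores orientation", {
  withr::local_seed(41)
  n <- 1000
  shift <- 50
  d0_alt <- rbinom(n, 400, 0.5)
  p23 <- c(rep(0.68, shift), rep(0.5, n - shift))
  b_alt <- rbinom(n, 400, p23)
  s_alt <- rbinom(n, 400, p23)
  id <- sprintf("h%04d", 1:n)
  counts <- dplyr::bind_rows(
    tibble::tibble(marker_id = id, day = 0L, replicate = NA_integer_,
                   size_group = NA_character_, ref_count = 400L - d0_alt,
                   alt_count = d0_alt),
    tibble::tibble(marker_id = id, day = 23L, replicate = 1L,
                   size_group = "Big", ref_count = 400L - b_alt,
                   alt_count = b_alt),
    tibble::tibble(marker_id = id, day = 23L, replicate = 1L,
                   size_group = "Small", ref_count = 400L - s_alt,
                   alt_count = s_alt)) |>
    dplyr::mutate(contig = "c", position = 1L, female = 1L, male = 1L,
                  missing = FALSE)
  pg <- parents_of(counts)
  mk <- markers_of(counts)
  hs <- haplotype_scan(counts, pg, mk, fdr = "storey")
  flagged <- hs$marker_id[hs$significant]
  truth <- id[1:shift]
  expect_gte(length(intersect(flagged, truth)) / shift, 0.8)
  fdp <- length(setdiff(flagged, truth)) / max(1, length(flagged))
  expect_lte(fdp, 0.10)
  # flipping every parental orientation leaves the p-values unchanged
  pg_flip <- parents_of(counts, female_gt = "1/1", male_gt = "0/0")
  hs_flip <- haplotype_scan(counts, pg_flip, mk, fdr = "storey")
  expect_equal(hs$p_big, hs_flip$p_big, tolerance = 1e-12)
  # a perfectly balanced table is never significant
  even <- hs[hs$marker_id == id[n], ]
  expect_false(even$significant)
})

test_that("contig totals aggregate marker counts and match the summed table", {
  counts <- dplyr::bind_rows(
    series_counts("m1", ref = c(10, 50, 50, 50, 50), alt = c(20, 50, 50, 50, 50),
                  contig = "cA"),
    series_counts("m2", ref = c(30, 50, 50, 50, 50), alt = c(40, 50, 50, 50, 50),
                  contig = "cA"))
  pg <- parents_of(counts)
  mk <- markers_of(counts)
  cs <- contig_scan(counts, pg, mk)
  # day-0 female total 10 + 30 = 40, male total 20 + 40 = 60
  expect_equal(cs$f_d0, 40)
  expect_equal(cs$m_d0, 60)
  manual <- chisq_2x2(40, 60, 100, 100)
  expect_equal(cs$p_d0_big, manual$p_value, tolerance = 1e-12)
  # equal counts across days are never significant
  flat <- dplyr::bind_rows(
    series_counts("m1", ref = rep(50L, 5), alt = rep(50L, 5), contig = "cA"),
    series_counts("m2", ref = rep(60L, 5), alt = rep(60L, 5), contig = "cA"))
  cs2 <- contig_scan(flat, parents_of(flat), markers_of(flat))
  expect_false(any(cs2$selected))
})

test_that("the size scan flags engineered Big-Small differences", {
  fx <- table1_fixture(n_het = 1101, big_only = 0, small_only = 0, dual = 0)
  counts <- fx$counts
  # plant 46 size-associated markers: Big and Small pools differ strongly
  planted <- fx$markers$marker_id[1:46]
  sel <- counts$size_group %in% "Big" & counts$marker_id %in% planted
  counts$ref_count[sel] <- 310L
  counts$alt_count[sel] <- 90L
  ss <- size_scan(counts, fx$markers)
  expect_equal(ss$n_het[1], 1101L)
  expect_equal(sum(ss$significant), 46L)
  expect_setequal(ss$marker_id[ss$significant], planted)
  expect_equal(percent(sum(ss$significant), 1101, 2), 4.18)
  # identical Big/Small counts give p = 1
  expect_equal(ss$p_value[!ss$marker_id %in% planted],
               rep(1, 1101 - 46))
  # a replicate without both size groups refuses the scan
  expect_error(size_scan(counts[counts$size_group %in% c(NA, "Big"), ],
                         fx$markers),
               class = "larvascan_scan_error")
})

test_that("overlap sets intersect exactly", {
  ov <- overlap_sets(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"), r3 = "c")
  expect_equal(ov$intersection, "c")
  expect_equal(unname(ov$sizes), c(3L, 3L, 1L))
  expect_equal(ov$pairwise$overlap[1], 2L) # r1 vs r2
  expect_equal(overlap_sets(c("a"), c("b"))$intersection, character(0))
  expect_error(overlap_sets(c("a")), class = "larvascan_validation_error")

  # three replicate scans sharing an engineered set of 149 markers
  common <- sprintf("shared%03d", 1:149)
  r1 <- c(common, sprintf("r1_%03d", 1:43))
  r2 <- c(common, sprintf("r2_%04d", 1:4193))
  r3 <- c(common, sprintf("r3_%04d", 1:3906))
  ov2 <- overlap_sets(r1 = r1, r2 = r2, r3 = r3)
  expect_length(ov2$intersection, 149)
})
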