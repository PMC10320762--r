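test_that("parental depth filter is inclusive at the 40x boundary", {
  pg <- tibble::tibble(
    female = 1L, male = 1L, marker_id = c("a", "b", "c", "d"),
    contig = "c1", position = 1:4,
    female_gt = "0/0", male_gt = "1/1",
    female_depth = c(39, 40, 100, NA), male_depth = c(100, 40, 39, 80))
  out <- filter_parental_depth(pg)
  expect_equal(out$marker_id, "b") # (40, 40) retained; 39 and NA removed
  expect_warning(expect_warning(filter_parental_depth(pg[pg$marker_id == "a", ]),
                                "dropped entirely"),
                 "no markers pass")
})

test_that("zero-then-recovered counts are masked, terminal zeros kept", {
  # alt series (D0=10, D11=0, D16=8, D23=9): the D11 zero is impossible
  x <- series_counts("m1", ref = c(30, 30, 30, 30), alt = c(10, 0, 8, 9),
                     days = c(0, 11, 16, 23), sizes = c(NA, NA, NA, "Big"))
  out <- apply_zero_recovery_rule(x)
  expect_true(out$missing[out$day == 11])
  expect_true(is.na(out$ref_count[out$day == 11])) # both alleles masked
  expect_equal(out$missing[out$day != 11], rep(FALSE, 3))

  # monotone loss to zero: nothing to mask
  y <- series_counts("m2", ref = c(30, 30, 30, 30), alt = c(10, 8, 6, 0),
                     days = c(0, 11, 16, 23), sizes = c(NA, NA, NA, "Big"))
  expect_equal(apply_zero_recovery_rule(y), y)

  # an allele never observed: nothing to mask
  z <- series_counts("m3", ref = c(30, 30, 30, 30), alt = c(0, 0, 0, 0),
                     days = c(0, 11, 16, 23), sizes = c(NA, NA, NA, "Big"))
  expect_equal(apply_zero_recovery_rule(z), z)
})

test_that("zero-recovery respects lineages and the shared day-0 pool", {
  # replicate 1 loses the allele for good; replicate 2 still carries it:
  # the R1 zero is terminal within its own tank and must stay
  x <- dplyr::bind_rows(
    series_counts("m1", ref = c(30, 30, 30), alt = c(10, 0, 0),
                  days = c(0, 11, 23), sizes = c(NA, NA, "Big"), replicate = 1),
    series_counts("m1", ref = c(30, 30), alt = c(9, 8),
                  days = c(11, 23), sizes = c(NA, "Big"), replicate = 2))
  out <- apply_zero_recovery_rule(x)
  expect_false(any(out$missing))

  # a day-0 zero with the allele present later in any replicate is impossible
  y <- dplyr::bind_rows(
    series_counts("m2", ref = c(40, 30, 30), alt = c(0, 5, 7),
                  days = c(0, 11, 23), sizes = c(NA, NA, "Big"), replicate = 1))
  out2 <- apply_zero_recovery_rule(y)
  expect_true(out2$missing[out2$day == 0])
})

test_that("filters are idempotent", {
  x <- dplyr::bind_rows(
    series_counts("m1", ref = c(30, 30, 30, 30), alt = c(10, 0, 8, 9),
                  days = c(0, 11, 16, 23), sizes = c(NA, NA, NA, "Big")),
    series_counts("m2", ref = c(25, 0, 30, 30), alt = c(25, 40, 30, 31),
                  days = c(0, 11, 16, 23), sizes = c(NA, NA, NA, "Big")))
  once <- apply_zero_recovery_rule(x)
  expect_equal(apply_zero_recovery_rule(once), once)
  pg <- parents_of(x)
  expect_equal(filter_parental_depth(filter_parental_depth(pg)),
               filter_parental_depth(pg))
})

test_that("the 20x both-allele rule defines the heterozygous set", {
  counts <- dplyr::bind_rows(
    series_counts("ok", ref = c(20, 22, 21, 20, 25), alt = c(20, 24, 23, 20, 22)),
    series_counts("shallow", ref = c(30, 30, 19, 30, 30), alt = c(30, 30, 40, 30, 30)),
    series_counts("gap", ref = c(30, NA, 30, 30, 30), alt = c(30, NA, 30, 30, 30)))
  pg <- parents_of(counts)
  het <- select_heterozygous_markers(counts, pg)
  # boundary 20x retained; 19x excluded; masked/absent time points exempt
  expect_setequal(het$marker_id, c("ok", "gap"))
  nh <- n_het(het)
  expect_equal(nh$n_het, 2L)
})

test_that("non-informative or unknown parents exclude a marker", {
  counts <- dplyr::bind_rows(
    series_counts("m1", ref = c(30, 30, 30, 30, 30), alt = c(30, 30, 30, 30, 30)),
    series_counts("m2", ref = c(30, 30, 30, 30, 30), alt = c(30, 30, 30, 30, 30)),
    series_counts("orphan", ref = c(30, 30, 30, 30, 30), alt = c(30, 30, 30, 30, 30)))
  pg <- parents_of(counts[counts$marker_id != "orphan", ])
  pg$female_gt[pg$marker_id == "m2"] <- "0/1"
  expect_message(het <- select_heterozygous_markers(counts, pg),
                 "absent from the parental table")
  expect_equal(het$marker_id, "m1")
})

test_that("masking before the depth rule retains a superset of markers", {
  # a marker whose only sub-20x cell is a biologically impossible zero:
  # masking first exempts the cell; depth-filtering first would discard it
  counts <- series_counts("m1", ref = c(30, 0, 30, 30, 30),
                          alt = c(30, 35, 30, 30, 30))
  pg <- parents_of(counts)
  in_order <- select_heterozygous_markers(apply_zero_recovery_rule(counts), pg)
  reversed <- select_heterozygous_markers(counts, pg)
  expect_equal(in_order$marker_id, "m1")
  expect_length(reversed$marker_id, 0)
  expect_true(all(reversed$marker_id %in% in_order$marker_id))
})

test_that("a generator-built replicate reports the engineered nHet", {
  fx <- table1_fixture(n_het = 80, big_only = 10, small_only = 5, dual = 8)
  pg <- parents_of(fx$counts)
  het <- select_heterozygous_markers(fx$counts, pg)
  expect_equal(n_het(het)$n_het, 80L)
})

test_that("filter reports tally marker attrition", {
  counts <- series_counts("m1", ref = c(30, 30, 30, 30, 30),
                          alt = c(30, 30, 30, 30, 30))
  rep <- filter_report(counts, counts[0, ], reasons = list(depth = 1))
  expect_equal(rep$markers_in, 1)
  expect_equal(rep$markers_out, 0)
})
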