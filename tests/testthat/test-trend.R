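mk_traj <- function(id, traj, contig = "C0001", depth = 10000L) {
  series_counts(id, ref = as.integer((1 - traj) * depth),
                alt = as.integer(traj * depth), contig = contig)
}

test_that("consistency requires one strict sign across the deltas", {
  counts <- dplyr::bind_rows(
    mk_traj("up", c(0.50, 0.52, 0.55, 0.58, 0.57)),
    mk_traj("mixed", c(0.50, 0.55, 0.48, 0.58, 0.60)),
    mk_traj("tied", c(0.50, 0.50, 0.55, 0.58, 0.57)),
    mk_traj("down", c(0.50, 0.46, 0.43, 0.40, 0.41)))
  deltas <- compute_allele_freq(counts) |> normalize_to_day0()
  tr <- consistent_trend_markers(deltas, contigs = NULL)
  res <- setNames(tr$consistent, tr$marker_id)
  expect_true(res[["up"]])
  expect_false(res[["mixed"]]) # day-16 delta is negative
  expect_false(res[["tied"]]) # a zero delta breaks consistency
  expect_true(res[["down"]])
  expect_equal(tr$direction[tr$marker_id == "down"], "decreasing")
  expect_equal(tr$n_comparisons, rep(4L, 4))
})

test_that("the chain rule instead demands a monotone trajectory", {
  counts <- dplyr::bind_rows(
    mk_traj("chain_up", c(0.50, 0.52, 0.55, 0.58, 0.57)),
    mk_traj("rises_then_dips", c(0.50, 0.55, 0.52, 0.58, 0.60)))
  deltas <- compute_allele_freq(counts) |> normalize_to_day0()
  tr <- consistent_trend_markers(deltas, contigs = NULL, method = "chain")
  res <- setNames(tr$consistent, tr$marker_id)
  expect_true(res[["chain_up"]]) # all four successive steps positive
  # every delta is positive but the D11 -> D16 step is negative
  expect_false(res[["rises_then_dips"]])
  under_delta <- consistent_trend_markers(deltas, contigs = NULL)
  expect_true(under_delta$consistent[under_delta$marker_id == "rises_then_dips"])
})

test_that("trend selection is restricted to significant contigs", {
  counts <- dplyr::bind_rows(
    mk_traj("in", c(0.50, 0.55, 0.60, 0.65, 0.64), contig = "cSel"),
    mk_traj("out", c(0.50, 0.55, 0.60, 0.65, 0.64), contig = "cNeu"))
  deltas <- compute_allele_freq(counts) |> normalize_to_day0()
  tr <- consistent_trend_markers(deltas, contigs = "cSel")
  expect_equal(tr$marker_id, "in")
})

test_that("a missing Small group leaves three comparisons", {
  counts <- mk_traj("m", c(0.50, 0.53, 0.56, 0.60, NA))
  counts <- counts[1:4, ]
  deltas <- compute_allele_freq(counts) |> normalize_to_day0()
  tr <- consistent_trend_markers(deltas, contigs = NULL)
  expect_equal(tr$n_comparisons, 3L)
  expect_true(tr$consistent)
})

test_that("chance of drift converges to the exchangeable-signs limit", {
  cd <- chance_of_drift(0.5, depths = 1e6, n_sims = 4e4, seed = 1)
  expect_lt(abs(cd$chance_of_drift - 0.125), 0.01) # 2 * (1/2)^4
  cd3 <- chance_of_drift(0.5, depths = rep(1e6, 3), n_sims = 4e4, seed = 1)
  expect_lt(abs(cd3$chance_of_drift - 0.25), 0.012) # 2 * (1/2)^3
})

test_that("finite depth only lowers the chance of drift (ties)", {
  shallow <- chance_of_drift(0.5, depths = 30, n_sims = 4e4, seed = 2)
  expect_lt(shallow$chance_of_drift, 0.125)
})

test_that("chance of drift is deterministic and scales as 1/sqrt(n_sims)", {
  a <- chance_of_drift(0.4, depths = 100, n_sims = 5000, seed = 3)
  b <- chance_of_drift(0.4, depths = 100, n_sims = 5000, seed = 3)
  expect_identical(a, b)
  small <- replicate(40, chance_of_drift(0.5, 1e5, n_sims = 1000)$chance_of_drift)
  big <- replicate(40, chance_of_drift(0.5, 1e5, n_sims = 16000)$chance_of_drift)
  # 16x the simulations should shrink the spread about 4-fold
  expect_lt(sd(big), sd(small) / 2)
})

test_that("degenerate frequencies and bad inputs are handled", {
  expect_warning(cd <- chance_of_drift(0, depths = 100, n_sims = 1000),
                 "fixed")
  expect_equal(cd$chance_of_drift, 0)
  expect_error(chance_of_drift(0.5, depths = 100, n_sims = 10),
               class = "larvascan_parameter_error")
  expect_error(chance_of_drift(1.5, depths = 100),
               class = "larvascan_parameter_error")
  expect_error(chance_of_drift(0.5, depths = c(10, 10)),
               class = "larvascan_parameter_error")
})

test_that("neutral consistent-marker fraction matches the drift null", {
  # deep-coverage neutral markers: the observed fraction of consistent
  # trajectories should sit near the sampling-noise-only prediction
  withr::local_seed(51)
  n <- 4000
  depth <- 5000L
  depth0 <- 2000000L # the null treats day 0 as a fixed reference, so the
                     # comparison needs a day-0 estimate with negligible noise
  id <- sprintf("n%04d", 1:n)
  mkrows <- function(day, size, alt, d) {
    tibble::tibble(marker_id = id, contig = "c", position = 1L,
                   female = 1L, male = 1L,
                   replicate = if (day == 0) NA_integer_ else 1L,
                   day = as.integer(day), size_group = size,
                   ref_count = d - alt, alt_count = alt, missing = FALSE)
  }
  counts <- dplyr::bind_rows(
    mkrows(0, NA_character_, as.integer(rbinom(n, depth0, 0.5)), depth0),
    mkrows(11, NA_character_, as.integer(rbinom(n, depth, 0.5)), depth),
    mkrows(16, NA_character_, as.integer(rbinom(n, depth, 0.5)), depth),
    mkrows(23, "Big", as.integer(rbinom(n, depth, 0.5)), depth),
    mkrows(23, "Small", as.integer(rbinom(n, depth, 0.5)), depth))
  deltas <- compute_allele_freq(counts) |> normalize_to_day0()
  tr <- consistent_trend_markers(deltas, contigs = NULL)
  observed <- mean(tr$consistent)
  cd <- chance_of_drift(0.5, depths = depth, n_sims = 5e4, seed = 52)
  se <- sqrt(0.125 * 0.875 / n)
  expect_lt(abs(observed - cd$chance_of_drift), 4 * se)
})

test_that("drift probabilities multiply across replicates", {
  expect_equal(joint_drift_probability(rep(0.125, 8)), 0.125^8)
  expect_lt(abs(joint_drift_probability(rep(0.125, 8)) - 5.96e-8), 1e-9)
  expect_equal(joint_drift_probability(c(0.5, 0)), 0)
  expect_equal(joint_drift_probability(0.37), 0.37)
  expect_error(joint_drift_probability(c(0.5, 1.2)),
               class = "larvascan_parameter_error")
})

test_that("drift_report averages per-marker chances over a marker set", {
  counts <- dplyr::bind_rows(
    mk_traj("a", c(0.50, 0.52, 0.55, 0.58, 0.57), depth = 400L),
    mk_traj("b", c(0.30, 0.32, 0.29, 0.31, 0.33), depth = 400L))
  f <- compute_allele_freq(counts)
  dr <- drift_report(f, c("a", "b"), n_sims = 5000, seed = 9)
  expect_equal(nrow(dr), 2)
  expect_true(all(dr$chance_of_drift > 0 & dr$chance_of_drift < 0.125))
  expect_equal(attr(dr, "mean_chance"), mean(dr$chance_of_drift))
  expect_identical(drift_report(f, c("a", "b"), n_sims = 5000, seed = 9), dr)
})
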