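# 2x2 contingency testing and q-value FDR control.

#' Pearson chi-square test of a 2x2 contingency table
#'
#' Tests independence of a table `rbind(c(a, b), c(c, d))` (rows: reference /
#' alternative allele reads; columns: the two samples being compared) with
#' one degree of freedom. The continuity correction is off by default and can
#' be enabled with `yates = TRUE`. Tables with a zero row or column margin
#' are undefined and raise an error. Expected cells below 5 trigger a
#' warning-level log message but do not suppress the test, which is applied
#' uniformly across markers.
#'
#' @param a,b,c,d Nonnegative cell counts, row-wise.
#' @param yates Apply the Yates continuity correction?
#' @return A one-row tibble with `statistic` and `p_value`.
#' @export
#' @examples
#' chisq_2x2(30, 10, 10, 30) # statistic 20
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stopf("cells must be nonnegative counts", class = "larvascan_test_error")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("2x2 table has a zero margin; test undefined",
          class = "larvascan_test_error")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    inform("expected cell count below 5; chi-square approximation is rough")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value))
}

# Vectorized Pearson 2x2 statistic/p-value used inside the scans
# (identical to chisq_2x2 cell-for-cell; margins must be positive).
chisq_2x2_vec <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- !is.na(n) & r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - n / 2)
  stat <- ifelse(ok, n * num^2 / (r1 * r2 * c1 * c2), NA_real_)
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Convert p-values to q-values
#'
#' Benjamini-Hochberg q-values are the step-up adjusted values
#' `q_i = min over {j : p_j >= p_i} of p_j * m / rank_j`, clipped to 1.
#' Storey q-values scale these by an estimate of the null proportion pi0,
#' obtained from the standard lambda grid 0.05-0.95 (step 0.05) with a cubic
#' smoothing spline evaluated at the largest lambda; with fewer than 100
#' p-values the estimate is unstable and the method falls back to BH
#' (pi0 = 1). q-values are monotone nondecreasing in p within a family.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"bh"` or `"storey"`.
#' @return Numeric vector of q-values (empty input gives empty output).
#' @export
qvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]", class = "larvascan_test_error")
  }
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- storey_pi0(p)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Storey estimate of the null proportion pi0
#'
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` evaluated on the lambda
#' grid 0.05, 0.10, ..., 0.95 and smoothed with a df = 3 cubic spline; the
#' smoother's value at the largest lambda, clipped to (0, 1], is returned.
#' Fewer than 100 p-values return 1 (BH fallback).
#'
#' @param p Numeric vector of p-values.
#' @param lambda Grid of tuning values in (0, 1).
#' @return A scalar pi0 estimate in (0, 1].
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}
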