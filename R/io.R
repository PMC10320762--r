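# Reading, writing and validating pooled count tables and parental genotypes.

#' Parse pooled-sample keys of the form `Fx.Mx.Rx.Dx[Big|Small]`
#'
#' Sample names encode the female and male parent, the replicate tank, the
#' sampling day and (on day 23 only) the sieve size group, e.g.
#' `"F1.M1.R2.D23Big"`. Day-0 samples carry no replicate, because the day-0
#' pool is taken from the fertilized population before the replicate split
#' (`"F1.M1.D0"`).
#'
#' @param x Character vector of sample keys.
#' @return A tibble with columns `female`, `male`, `replicate` (NA on day 0),
#'   `day` and `size_group` (NA unless day 23).
#' @export
#' @examples
#' parse_sample_key(c("F1.M1.R2.D23Big", "F2.M1.D0"))
parse_sample_key <- function(x) {
  pat <- "^F([0-9]+)\\.M([0-9]+)(?:\\.R([0-9]+))?\\.D([0-9]+)(Big|Small)?$"
  m <- regmatches(x, regexec(pat, x))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stopf("malformed sample key(s): %s",
          paste(unique(x[bad]), collapse = ", "),
          class = "larvascan_parse_error")
  }
  out <- tibble::tibble(
    female = as.integer(vapply(m, `[`, "", 2)),
    male = as.integer(vapply(m, `[`, "", 3)),
    replicate = suppressWarnings(as.integer(vapply(m, `[`, "", 4))),
    day = as.integer(vapply(m, `[`, "", 5)),
    size_group = dplyr::na_if(vapply(m, `[`, "", 6), "")
  )
  validate_sample_keys(out)
  out
}

validate_sample_keys <- function(keys) {
  bad_size <- !is.na(keys$size_group) & keys$day != 23
  if (any(bad_size)) {
    stopf("size_group is only defined on day 23 (%d offending row(s))",
          sum(bad_size), class = "larvascan_validation_error")
  }
  bad_rep <- is.na(keys$replicate) & keys$day != 0
  if (any(bad_rep)) {
    stopf("replicate may be missing only on day 0 (%d offending row(s))",
          sum(bad_rep), class = "larvascan_validation_error")
  }
  bad_d0 <- !is.na(keys$replicate) & keys$day == 0
  if (any(bad_d0)) {
    stopf("day-0 pools precede the replicate split and carry no replicate id",
          class = "larvascan_validation_error")
  }
  invisible(keys)
}

#' Compose sample keys from their components
#'
#' The inverse of [parse_sample_key()].
#'
#' @param female,male,replicate,day,size_group Key components (vectors are
#'   recycled by `sprintf`).
#' @return Character vector of `Fx.Mx.Rx.Dx[Big|Small]` keys.
#' @export
sample_key <- function(female, male, replicate, day, size_group = NA) {
  paste0("F", female, ".M", male,
         ifelse(is.na(replicate), "", paste0(".R", replicate)),
         ".D", day,
         ifelse(is.na(size_group), "", size_group))
}

validate_pool_counts <- function(counts) {
  needed <- c("marker_id", "contig", "position", "female", "male",
              "replicate", "day", "size_group", "ref_count", "alt_count")
  miss <- setdiff(needed, names(counts))
  if (length(miss)) {
    stopf("count table lacks column(s): %s", paste(miss, collapse = ", "),
          class = "larvascan_validation_error")
  }
  if (!"missing" %in% names(counts)) {
    counts$missing <- is.na(counts$ref_count) | is.na(counts$alt_count)
  }
  validate_sample_keys(counts)
  live <- !counts$missing
  if (any(counts$ref_count[live] < 0 | counts$alt_count[live] < 0,
          na.rm = TRUE)) {
    stopf("negative read counts", class = "larvascan_validation_error")
  }
  key <- paste(counts$marker_id, counts$female, counts$male,
               counts$replicate, counts$day, counts$size_group)
  if (anyDuplicated(key)) {
    stopf("duplicated (marker, sample) pairs", class = "larvascan_validation_error")
  }
  counts
}

#' Read or write a pooled allele-count table (TSV)
#'
#' The on-disk schema is a tab-separated table with a header and columns
#' `marker_id`, `contig`, `position`, `sample` (an `Fx.Mx.Rx.Dx[Big|Small]`
#' key) or the explicit `female`/`male`/`replicate`/`day`/`size_group`
#' columns, plus `ref_count` and `alt_count`. Missing cells carry empty
#' counts. `write_pool_counts()` followed by `read_pool_counts()` is the
#' identity.
#'
#' @param path File path.
#' @return `read_pool_counts()`: a validated count tibble;
#'   `write_pool_counts()`: `path`, invisibly.
#' @export
read_pool_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(counts)
  if (nrow(probs)) {
    stopf("parse failure at line(s) %s of %s",
          paste(head(probs$row, 5), collapse = ", "), path,
          class = "larvascan_parse_error")
  }
  if ("sample" %in% names(counts) && !"female" %in% names(counts)) {
    counts <- dplyr::bind_cols(
      counts[setdiff(names(counts), "sample")],
      parse_sample_key(counts$sample)
    )
  }
  counts <- counts |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("position", "female", "male", "replicate",
                                    "day", "ref_count", "alt_count")),
                    as.integer),
      missing = is.na(.data$ref_count) | is.na(.data$alt_count)
    ) |>
    dplyr::select("marker_id", "contig", "position", "female", "male",
                  "replicate", "day", "size_group", "ref_count", "alt_count",
                  "missing")
  validate_pool_counts(counts)
}

#' @rdname read_pool_counts
#' @param counts A pooled count tibble.
#' @export
write_pool_counts <- function(counts, path) {
  counts <- validate_pool_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read parental genotypes and depths from a VCF
#'
#' Extracts per-parent genotype calls (GT) and depths (DP) for biallelic SNPs
#' from a VCF with one sample per parent. Indel and multiallelic records are
#' skipped and counted. A marker is *informative* when the two parents are
#' homozygous for opposite alleles, which makes every F1 heterozygous and
#' lets reads be assigned to the maternal or paternal haplotype.
#'
#' @param path VCF file (VCFv4.x; plain text or bgzipped).
#' @param female_sample,male_sample Sample names of the two parents; default
#'   to the first and second genotype columns.
#' @param female,male Integer ids recorded for the family.
#' @return A tibble with `female`, `male`, `marker_id`, `contig`, `position`,
#'   `female_gt`, `male_gt` (slash-normalized, `NA` when missing),
#'   `female_depth`, `male_depth` (NA when DP is absent, which fails the depth
#'   filter) and `informative`. The number of skipped records is attached as
#'   attribute `skipped`.
#' @export
read_parental_vcf <- function(path, female_sample = NULL, male_sample = NULL,
                              female = 1L, male = 1L) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  skipped <- sum(!snp)
  if (skipped) {
    inform(sprintf("skipped %d non-SNP/multiallelic record(s)", skipped))
  }
  samples <- colnames(vcf@gt)[-1]
  female_sample <- female_sample %||% samples[1]
  male_sample <- male_sample %||% samples[2]
  if (!all(c(female_sample, male_sample) %in% samples)) {
    stopf("parent sample(s) not found in VCF", class = "larvascan_parse_error")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  norm_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(g %in% c(".", "./."), NA_character_, g)
  }
  f_gt <- norm_gt(gt[snp, female_sample])
  m_gt <- norm_gt(gt[snp, male_sample])
  out <- tibble::tibble(
    female = as.integer(female), male = as.integer(male),
    marker_id = ifelse(is.na(fix[snp, "ID"]) | fix[snp, "ID"] == ".",
                       paste0(fix[snp, "CHROM"], "_", fix[snp, "POS"]),
                       fix[snp, "ID"]),
    contig = fix[snp, "CHROM"],
    position = as.integer(fix[snp, "POS"]),
    female_gt = f_gt, male_gt = m_gt,
    female_depth = if (is.null(dim(dp))) rep(NA_real_, sum(snp))
                   else dp[snp, female_sample],
    male_depth = if (is.null(dim(dp))) rep(NA_real_, sum(snp))
                 else dp[snp, male_sample]
  )
  out$informative <- is_informative(out$female_gt, out$male_gt)
  attr(out, "skipped") <- skipped
  out
}

# Opposite-homozygote parents: marker heterozygous in every F1.
is_informative <- function(female_gt, male_gt) {
  hom0 <- function(g) !is.na(g) & g == "0/0"
  hom1 <- function(g) !is.na(g) & g == "1/1"
  (hom0(female_gt) & hom1(male_gt)) | (hom1(female_gt) & hom0(male_gt))
}
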