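#' Filter bi-allelic SNP records on depth and reference support
#'
#' Applies the per-replicate record filters used before replicate
#' intersection: a record is kept iff its total depth lies in
#' `[min_total, max_total]` and its reference read count is at least
#' `min_ref`.  The filter is deliberately asymmetric — only the reference
#' allele carries a minimum — matching the variant-calling convention it
#' mirrors; pass `min_alt` to add a mirrored alternate-allele minimum.
#'
#' @param records Data frame of SNP records with columns `ref_count` and
#'   `alt_count` (as produced by [simulate_read_ratio_dataset()] or
#'   [read_vcf_subset()]).
#' @param min_total Minimum total reads per record (default 10).
#' @param max_total Maximum total reads per record (default 300).
#' @param min_ref Minimum reference-allele reads (default 5).
#' @param min_alt Optional minimum alternate-allele reads (default 0, i.e.
#'   disabled).
#'
#' @return The subset of `records`, order preserved.
#' @export
filter_biallelic <- function(records, min_total = 10, max_total = 300,
                             min_ref = 5, min_alt = 0) {
  stopifnot(is.data.frame(records),
            all(c("ref_count", "alt_count") %in% names(records)),
            min_total > 0, max_total > 0, min_ref > 0)
  total <- records$ref_count + records$alt_count
  keep <- total >= min_total & total <= max_total &
    records$ref_count >= min_ref & records$alt_count >= min_alt
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

snp_key <- function(records) {
  paste(records$contig, records$position,
        records$ref_allele, records$alt_allele, sep = ":")
}

#' Intersect replicate libraries and combine read counts
#'
#' A SNP is considered real only when called in both replicate libraries of
#' an individual; for shared SNPs the reference and alternate read counts
#' of the two replicates are summed.  Records are matched on the full key
#' (contig, position, ref allele, alt allele), so discordant calls at the
#' same coordinate are not merged.
#'
#' @param rep1,rep2 Filtered SNP record data frames (one replicate each).
#'
#' @return A data frame with one combined record per shared key, in the
#'   order of `rep1`.
#' @export
intersect_replicates <- function(rep1, rep2) {
  cols <- c("contig", "position", "ref_allele", "alt_allele",
            "ref_count", "alt_count")
  stopifnot(all(cols %in% names(rep1)), all(cols %in% names(rep2)))
  k1 <- snp_key(rep1)
  k2 <- snp_key(rep2)
  for (nm in c("rep1", "rep2")) {
    k <- if (nm == "rep1") k1 else k2
    if (anyDuplicated(k)) {
      stop(sprintf("duplicate SNP key in %s: %s", nm, k[duplicated(k)][1L]),
           call. = FALSE)
    }
  }
  shared <- k1 %in% k2
  out <- rep1[shared, cols, drop = FALSE]
  m <- match(k1[shared], k2)
  out$ref_count <- out$ref_count + rep2$ref_count[m]
  out$alt_count <- out$alt_count + rep2$alt_count[m]
  rownames(out) <- NULL
  out
}

#' Compute reference read ratios
#'
#' The per-SNP statistic whose histogram carries the ploidy signal:
#' `ref_count / (ref_count + alt_count)`.  In a diploid, heterozygous sites
#' concentrate around 0.5; in a tetraploid, the three dosage classes put
#' peaks at 0.25, 0.5 and 0.75; a triploid peaks at 1/3 and 2/3.
#'
#' @param records Combined SNP record data frame.
#' @param sample_id Optional sample label stored on the result.
#'
#' @return A data frame of class `ratio_set` with columns `contig`,
#'   `position`, `ratio`, `depth`.
#' @export
compute_ratios <- function(records, sample_id = NULL) {
  stopifnot(is.data.frame(records),
            all(c("ref_count", "alt_count") %in% names(records)))
  depth <- records$ref_count + records$alt_count
  if (any(depth == 0)) {
    stop("record with zero total depth; filter before computing ratios",
         call. = FALSE)
  }
  out <- data.frame(
    contig = records$contig %||% NA_character_,
    position = records$position %||% NA_integer_,
    ratio = records$ref_count / depth,
    depth = depth,
    stringsAsFactors = FALSE
  )
  attr(out, "sample_id") <- sample_id
  class(out) <- c("ratio_set", "data.frame")
  out
}
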