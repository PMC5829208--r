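# File formats.  Coordinates are 1-based inclusive everywhere (VCF/SAM
# convention).  TSV dialects: tab-separated, mandatory header row, UTF-8,
# '.' for missing.

#' Write replicate SNP records as a minimal VCF v4.2
#'
#' One sample column per replicate library; per-sample allele depths go in
#' the `AD` FORMAT field as `ref,alt`.  Sites absent from a replicate get
#' a missing genotype column.
#'
#' @param records SNP record data frame with a `replicate` column (as from
#'   [simulate_read_ratio_dataset()]).
#' @param path Output file path.
#' @param sample_prefix Sample-column name prefix (default `"rep"`).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(records, path, sample_prefix = "rep") {
  stopifnot(is.data.frame(records), "replicate" %in% names(records))
  reps <- sort(unique(records$replicate))
  key <- paste(records$contig, records$position,
               records$ref_allele, records$alt_allele, sep = ":")
  sites <- records[!duplicated(key), c("contig", "position", "ref_allele",
                                       "alt_allele"), drop = FALSE]
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  site_key <- paste(sites$contig, sites$position,
                    sites$ref_allele, sites$alt_allele, sep = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ploidyshift",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0(sample_prefix, reps)), collapse = "\t")
  )
  geno <- matrix(".", nrow = nrow(sites), ncol = length(reps))
  for (j in seq_along(reps)) {
    rr <- records[records$replicate == reps[j], , drop = FALSE]
    m <- match(paste(rr$contig, rr$position, rr$ref_allele, rr$alt_allele,
                     sep = ":"), site_key)
    geno[m, j] <- paste0(rr$ref_count, ",", rr$alt_count)
  }
  body <- paste(sites$contig, sites$position, ".", sites$ref_allele,
                sites$alt_allele, ".", "PASS", ".", "AD",
                apply(geno, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNP allele-depth records from a VCF
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) whose per-sample `AD` field
#' carries `ref,alt` read depths, returning one SNP record per bi-allelic
#' row per sample.  Multi-allelic rows are skipped (with a count in the
#' `skipped_multiallelic` attribute) or rejected.
#'
#' @param path VCF file path.
#' @param skip_multiallelic Skip rows with more than one ALT allele
#'   (default) instead of erroring.
#' @return A data frame of SNP records with a `replicate` column numbering
#'   the VCF sample columns in order; attribute `samples` maps replicate
#'   numbers to sample names.
#' @export
read_vcf_subset <- function(path, skip_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(replicate = integer(), contig = character(),
                      position = integer(), ref_allele = character(),
                      alt_allele = character(), ref_count = integer(),
                      alt_count = integer(), stringsAsFactors = FALSE)
    attr(out, "skipped_multiallelic") <- 0L
    return(out)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && !skip_multiallelic) {
    stop(sprintf("multi-allelic record at %s:%s", fix$CHROM[multi][1L],
                 fix$POS[multi][1L]), call. = FALSE)
  }
  if (is.null(v@gt) || !any(grepl("AD", v@gt[, 1L]))) {
    stop("VCF lacks the per-sample AD (allele depth) FORMAT field",
         call. = FALSE)
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  keep <- which(!multi)
  out <- do.call(rbind, lapply(seq_along(samples), function(j) {
    cell <- ad[keep, j]
    has <- !is.na(cell) & cell != "."
    if (!any(has)) return(NULL)
    parts <- strsplit(cell[has], ",", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop(sprintf("malformed AD field at %s:%s (sample %s)",
                   fix$CHROM[keep][has][bad][1L],
                   fix$POS[keep][has][bad][1L], samples[j]),
           call. = FALSE)
    }
    data.frame(
      replicate = j,
      contig = fix$CHROM[keep][has],
      position = as.integer(fix$POS[keep][has]),
      ref_allele = fix$REF[keep][has],
      alt_allele = fix$ALT[keep][has],
      ref_count = as.integer(vapply(parts, `[`, "", 1L)),
      alt_count = as.integer(vapply(parts, `[`, "", 2L)),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    out <- data.frame(replicate = integer(), contig = character(),
                      position = integer(), ref_allele = character(),
                      alt_allele = character(), ref_count = integer(),
                      alt_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped_multiallelic") <- sum(multi)
  attr(out, "samples") <- samples
  out
}

#' Write or read SNP records as TSV
#'
#' @param records SNP record data frame.
#' @param path File path.
#' @return `write_snp_tsv`: `path`, invisibly. `read_snp_tsv`: the
#'   records.
#' @export
write_snp_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_snp_tsv
#' @export
read_snp_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Write contig alignments in the alignment TSV dialect
#'
#' One row per read: `read_id`, `contig`, `start`, `end`, `calls`, where
#' `calls` packs the variant-column base calls as
#' `pos:base;pos:base` (or `.` when the read covers no column).
#'
#' @param alignments A list of `contig_alignment` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alignments, path) {
  if (inherits(alignments, "contig_alignment")) {
    alignments <- list(alignments)
  }
  rows <- lapply(alignments, function(aln) {
    calls <- split(aln$calls, aln$calls$read_id)
    packed <- vapply(aln$reads$read_id, function(id) {
      cc <- calls[[id]]
      if (is.null(cc) || !nrow(cc)) return(".")
      paste(sprintf("%d:%s", cc$pos, cc$base), collapse = ";")
    }, "")
    data.frame(read_id = aln$reads$read_id, contig = aln$contig,
               contig_length = aln$contig_length,
               start = aln$reads$start, end = aln$reads$end,
               calls = packed, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read contig alignments from the alignment TSV dialect
#'
#' @param path File path written by [write_alignment_tsv()].
#' @return A list of `contig_alignment` objects, one per contig.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(calls = "character"))
  lapply(split(df, df$contig), function(d) {
    calls <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
      s <- d$calls[i]
      if (is.na(s) || s == ".") return(NULL)
      kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      data.frame(read_id = d$read_id[i],
                 pos = as.integer(vapply(kv, `[`, "", 1L)),
                 base = vapply(kv, `[`, "", 2L), stringsAsFactors = FALSE)
    }))
    if (is.null(calls)) {
      calls <- data.frame(read_id = character(), pos = integer(),
                          base = character(), stringsAsFactors = FALSE)
    }
    contig_alignment(
      contig = d$contig[1L], contig_length = d$contig_length[1L],
      reads = data.frame(read_id = d$read_id, start = d$start, end = d$end,
                         stringsAsFactors = FALSE),
      calls = calls
    )
  })
}

#' Write or read tip traits as two-column TSV
#'
#' Columns `tip_label` and `value`.
#'
#' @param traits Named numeric vector.
#' @param path File path.
#' @return `write_traits_tsv`: `path`, invisibly. `read_traits_tsv`: a
#'   named numeric vector.
#' @export
write_traits_tsv <- function(traits, path) {
  utils::write.table(
    data.frame(tip_label = names(traits), value = as.numeric(traits)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$value, df$tip_label)
}
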