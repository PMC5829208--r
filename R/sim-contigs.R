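#' Simulate read alignments on contigs with known haplotype structure
#'
#' Each contig carries `k` true haplotypes (drawn from `haplotype_probs`)
#' defined over a set of variant columns; with probability
#' `haplotype_divergence` a column is divergent, in which case every
#' haplotype draws its own base there (redrawn until at least two
#' haplotypes differ).  Reads are error-free copies of one haplotype over a
#' contiguous span of `read_span` bases at a uniform random start, and the
#' true haplotype label is retained for scoring.
#'
#' @param config A [contig_sim_config()].
#'
#' @return A list of `contig_alignment` objects (see
#'   [count_haplotypes()]), each with attribute `true_k`, the number of
#'   distinct haplotype sequences actually realised over the variant
#'   columns.
#' @export
simulate_contig_alignments <- function(config) {
  stopifnot(inherits(config, "contig_sim_config"))
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed, {
    lapply(seq_len(config$n_contigs), function(ci) {
      k <- sample.int(4L, 1L, prob = config$haplotype_probs)
      ncol_v <- if (length(config$n_variant_columns) == 1L) {
        config$n_variant_columns
      } else {
        sample(config$n_variant_columns, 1L)
      }
      # variant columns inside the window every read start can reach often
      # enough; uniform over the contig keeps partial overlap realistic
      cols <- sort(sample.int(config$contig_length, ncol_v))
      hap <- matrix("", nrow = k, ncol = ncol_v)
      for (j in seq_len(ncol_v)) {
        if (k > 1L && stats::runif(1) < config$haplotype_divergence) {
          repeat {
            draw <- sample(bases, k, replace = TRUE)
            if (length(unique(draw)) > 1L) break
          }
          hap[, j] <- draw
        } else {
          hap[, j] <- bases[1L]
        }
      }
      true_k <- nrow(unique(hap))

      n_reads <- k * config$reads_per_haplotype
      hap_of_read <- rep(seq_len(k), each = config$reads_per_haplotype)
      start <- sample.int(config$contig_length - config$read_span + 1L,
                          n_reads, replace = TRUE)
      end <- start + config$read_span - 1L
      read_id <- sprintf("r%04d", seq_len(n_reads))

      calls <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
        j <- which(cols >= start[i] & cols <= end[i])
        if (!length(j)) return(NULL)
        data.frame(read_id = read_id[i], pos = cols[j],
                   base = hap[hap_of_read[i], j], stringsAsFactors = FALSE)
      }))
      if (is.null(calls)) {
        calls <- data.frame(read_id = character(), pos = integer(),
                            base = character(), stringsAsFactors = FALSE)
      }
      aln <- contig_alignment(
        contig = sprintf("contig%04d", ci),
        contig_length = config$contig_length,
        reads = data.frame(read_id = read_id, start = start, end = end,
                           stringsAsFactors = FALSE),
        calls = calls
      )
      attr(aln, "true_k") <- true_k
      attr(aln, "true_hap") <- hap_of_read
      aln
    })
  })
}

#' Construct a contig alignment
#'
#' The substrate for haplotype counting: reads placed on one contig with
#' their base calls at (candidate) variant columns.
#'
#' @param contig Contig identifier.
#' @param contig_length Contig length in bases.
#' @param reads Data frame with columns `read_id`, `start`, `end`
#'   (1-based, inclusive).
#' @param calls Data frame with columns `read_id`, `pos`, `base`: the base
#'   each read reports at each covered candidate column.
#'
#' @return An object of class `contig_alignment`.
#' @export
contig_alignment <- function(contig, contig_length, reads, calls) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "start", "end") %in% names(reads)),
            is.data.frame(calls),
            all(c("read_id", "pos", "base") %in% names(calls)))
  if (nrow(reads) && any(reads$start > reads$end)) {
    stop("read start must be <= end", call. = FALSE)
  }
  if (nrow(reads) && any(reads$end > contig_length)) {
    stop("read end must be <= contig length", call. = FALSE)
  }
  structure(
    list(contig = contig, contig_length = as.integer(contig_length),
         reads = reads, calls = calls),
    class = "contig_alignment"
  )
}

#' @export
print.contig_alignment <- function(x, ...) {
  cat(sprintf("<contig_alignment> %s (%d bp): %d reads, %d call columns\n",
              x$contig, x$contig_length, nrow(x$reads),
              length(unique(x$calls$pos))))
  invisible(x)
}
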