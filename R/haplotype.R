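#' Call variant columns in a contig alignment
#'
#' A column is a variant column when at least two distinct bases each have
#' at least `min_allele_reads` supporting reads.  Singleton disagreements
#' (typically sequencing error) therefore never create a column at the
#' default threshold.
#'
#' @param aln A `contig_alignment`.
#' @param min_allele_reads Minimum reads supporting each of >= 2 alleles.
#' @return Sorted integer vector of variant column positions.
#' @export
call_variant_columns <- function(aln, min_allele_reads = 2) {
  stopifnot(inherits(aln, "contig_alignment"))
  if (!nrow(aln$calls)) return(integer())
  tab <- table(aln$calls$pos, aln$calls$base)
  keep <- apply(tab, 1L, function(row) sum(row >= min_allele_reads) >= 2L)
  sort(as.integer(rownames(tab)[keep]))
}

#' Remove over-long read alignments
#'
#' Drops reads whose aligned span (`end - start + 1`) exceeds `max_span`
#' bases; a read spanning exactly `max_span` is retained.  Long alignments
#' chain partially overlapping reads into spurious haplotype joins, which
#' is why the haplotype analysis caps them.
#'
#' @param aln A `contig_alignment`.
#' @param max_span Maximum allowed span in bases (default 200).
#' @return The filtered `contig_alignment`.
#' @export
filter_reads <- function(aln, max_span = 200) {
  stopifnot(inherits(aln, "contig_alignment"))
  if (!nrow(aln$reads)) return(aln)
  keep <- (aln$reads$end - aln$reads$start + 1L) <= max_span
  kept_ids <- aln$reads$read_id[keep]
  out <- aln
  out$reads <- aln$reads[keep, , drop = FALSE]
  out$calls <- aln$calls[aln$calls$read_id %in% kept_ids, , drop = FALSE]
  rownames(out$reads) <- rownames(out$calls) <- NULL
  out
}

# Read-by-column base matrix restricted to the given columns; NA where a
# read does not cover the column.  Rows ordered like aln$reads.
call_matrix <- function(aln, columns) {
  m <- matrix(NA_character_, nrow = nrow(aln$reads), ncol = length(columns),
              dimnames = list(aln$reads$read_id, columns))
  cc <- aln$calls[aln$calls$pos %in% columns, , drop = FALSE]
  if (nrow(cc)) {
    m[cbind(match(cc$read_id, aln$reads$read_id),
            match(cc$pos, columns))] <- cc$base
  }
  m
}

# Adjacency of the read conflict graph: TRUE iff two reads share >= 1
# variant column and disagree there.
conflict_graph <- function(base_mat) {
  n <- nrow(base_mat)
  adj <- matrix(FALSE, n, n)
  if (n < 2L || ncol(base_mat) == 0L) return(adj)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !is.na(base_mat[i, ]) & !is.na(base_mat[j, ])
      if (any(shared) && any(base_mat[i, shared] != base_mat[j, shared])) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

# Saturation-first greedy coloring (DSATUR): repeatedly color the read
# whose neighbours already use the most colors (ties: higher conflict
# degree, then the caller's order, i.e. start position then read id) with
# the smallest color absent among its neighbours.  Deterministic, and
# exact on the small structured conflict graphs that error-free haplotype
# reads produce.
greedy_coloring <- function(adj, order_idx) {
  n <- nrow(adj)
  color <- integer(n)
  rank <- integer(n)
  rank[order_idx] <- seq_len(n)
  deg <- rowSums(adj)
  for (step in seq_len(n)) {
    unc <- which(color == 0L)
    sat <- vapply(unc, function(v) {
      length(unique(color[adj[v, ] & color > 0L]))
    }, integer(1))
    v <- unc[order(-sat, -deg[unc], rank[unc])][1L]
    used <- color[adj[v, ] & color > 0L]
    cc <- 1L
    while (cc %in% used) cc <- cc + 1L
    color[v] <- cc
  }
  color
}

#' Count distinct haplotypes on a contig
#'
#' Conservative (minimum-consistent) haplotype counting: reads that
#' disagree at a shared variant column cannot descend from the same
#' haplotype, so the reads form a conflict graph whose minimal coloring
#' lower-bounds the haplotype number.  The graph is colored by a
#' deterministic saturation-first greedy (ties broken by start position
#' then read id); color classes whose
#' consensus sequences agree over all shared variant columns are then
#' merged (partial-overlap chains can split one haplotype into several
#' compatible classes); finally classes supported by fewer than
#' `min_reads_per_hap` reads are discarded and the survivors are counted.
#'
#' A contig with no variant columns but at least `min_reads_per_hap` reads
#' counts one haplotype; an empty alignment counts zero.
#'
#' @param aln A `contig_alignment`, already span-filtered (see
#'   [filter_reads()]).
#' @param min_reads_per_hap Minimum reads supporting a reported haplotype
#'   (default 20).
#' @param min_allele_reads Variant-column support threshold, passed to
#'   [call_variant_columns()].
#' @param per_contig If `TRUE`, apply `min_reads_per_hap` to the whole
#'   contig rather than to each haplotype class.
#' @return Non-negative integer haplotype count.
#' @export
count_haplotypes <- function(aln, min_reads_per_hap = 20,
                             min_allele_reads = 2, per_contig = FALSE) {
  stopifnot(inherits(aln, "contig_alignment"))
  n_reads <- nrow(aln$reads)
  if (n_reads == 0L) return(0L)
  if (per_contig && n_reads < min_reads_per_hap) return(0L)
  columns <- call_variant_columns(aln, min_allele_reads)
  if (!length(columns)) {
    if (per_contig) return(1L)
    return(if (n_reads >= min_reads_per_hap) 1L else 0L)
  }
  bm <- call_matrix(aln, columns)
  adj <- conflict_graph(bm)
  ord <- order(aln$reads$start, aln$reads$read_id)
  color <- greedy_coloring(adj, ord)
  classes <- split(seq_len(n_reads), color)

  consensus <- function(idx) {
    apply(bm[idx, , drop = FALSE], 2L, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return(NA_character_)
      names(sort(table(col), decreasing = TRUE))[1L]
    })
  }
  # merge classes whose consensi never disagree on a jointly covered
  # column; agglomerative with consensus recomputed after each merge, so a
  # class compatible with two mutually conflicting classes (e.g. one that
  # covers no shared column) cannot chain them together
  merged <- classes
  cons <- lapply(merged, consensus)
  repeat {
    k <- length(merged)
    if (k < 2L) break
    pair <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        shared <- !is.na(cons[[i]]) & !is.na(cons[[j]])
        if (!any(shared) || all(cons[[i]][shared] == cons[[j]][shared])) {
          pair <- c(i, j)
          break
        }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    merged[[pair[1L]]] <- c(merged[[pair[1L]]], merged[[pair[2L]]])
    merged[[pair[2L]]] <- NULL
    cons <- lapply(merged, consensus)
  }
  sizes <- lengths(merged)
  if (per_contig) return(length(merged))
  sum(sizes >= min_reads_per_hap)
}

#' Frequency distribution of haplotype counts over contigs
#'
#' Groups contigs by estimated haplotype number and reports the frequency
#' of contigs with one, two, and three-or-more haplotypes.  Contigs that
#' scored zero (failed the support filters) are excluded from the
#' denominator.
#'
#' @param counts Integer vector of per-contig haplotype counts.
#' @param sample_id Optional sample label.
#' @return An object of class `haplotype_summary`: list with `counts`,
#'   `frequencies` (named `1`, `2`, `3+`), `n_contigs`
#'   (denominator), `n_zero` and `sample_id`.
#' @export
haplotype_frequency_distribution <- function(counts, sample_id = NULL) {
  counts <- as.integer(counts)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("haplotype counts must be non-negative", call. = FALSE)
  }
  nz <- counts[counts >= 1L]
  if (!length(nz)) {
    stop("all contigs scored zero haplotypes; nothing to summarise",
         call. = FALSE)
  }
  freq <- c(
    `1` = mean(nz == 1L),
    `2` = mean(nz == 2L),
    `3+` = mean(nz >= 3L)
  )
  structure(
    list(counts = counts, frequencies = freq, n_contigs = length(nz),
         n_zero = sum(counts == 0L), sample_id = sample_id),
    class = "haplotype_summary"
  )
}

#' @export
print.haplotype_summary <- function(x, ...) {
  cat("Haplotype-number frequencies over contigs\n")
  if (!is.null(x$sample_id)) cat("  sample:", x$sample_id, "\n")
  cat(sprintf("  %d contigs scored (%d excluded at zero)\n",
              x$n_contigs, x$n_zero))
  print(round(x$frequencies, 4))
  invisible(x)
}
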