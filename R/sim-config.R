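#' Configuration for the SNP read-ratio simulator
#'
#' Parameterises a RAD-like experiment on one individual: `n_snps`
#' heterozygous bi-allelic sites are sequenced in `n_replicates` duplicate
#' libraries, and at each site each read reports the reference or alternate
#' allele.  For a site where the alternate allele occupies `d` of `ploidy`
#' chromosome copies, a read is reference with probability
#' `(ploidy - d) / ploidy`, perturbed by a symmetric per-read error.  In
#' diploids a fraction of sites may be collapsed paralog pairs, which
#' sequence like dosage-1-of-4 sites (reference read probability 0.25 or
#' 0.75 with equal chance) and put spurious mass at the outer peaks of the
#' ratio histogram.
#'
#' @param ploidy Integer, one of 2, 3, 4.
#' @param n_snps Number of bi-allelic sites to simulate.
#' @param depth_law Either `"poisson"` (default) or `"fixed"`; reads per
#'   site per replicate follow this law with mean `depth_mean`.  Poisson
#'   draws are truncated at 1 so every record carries at least one read.
#' @param depth_mean Mean sequencing depth per site per replicate library.
#' @param error_rate Per-read probability of reporting the other allele;
#'   must lie in `[0, 0.5)`.
#' @param paralog_fraction Probability that a diploid site is a collapsed
#'   paralog pair; ignored for ploidy 3 and 4.
#' @param dosage_weights Probability vector over alternate-allele dosages
#'   `1 .. ploidy - 1`; must sum to 1.  Defaults: `1` (diploid),
#'   `c(0.5, 0.5)` (triploid), `c(0.25, 0.5, 0.25)` (tetraploid).
#' @param n_replicates Number of duplicate libraries (the replicate design
#'   uses 2).
#' @param seed Integer seed; the same config yields byte-identical output.
#'
#' @return An object of class `snp_sim_config`.
#' @seealso [simulate_read_ratio_dataset()]
#' @export
snp_sim_config <- function(ploidy = 2,
                           n_snps = 10000,
                           depth_law = c("poisson", "fixed"),
                           depth_mean = 30,
                           error_rate = 0.005,
                           paralog_fraction = 0.05,
                           dosage_weights = NULL,
                           n_replicates = 2,
                           seed = 1) {
  depth_law <- match.arg(depth_law)
  if (!ploidy %in% c(2, 3, 4)) {
    stop("`ploidy` must be 2, 3 or 4", call. = FALSE)
  }
  stop_if_not_count(n_snps, "n_snps")
  stop_if_not_count(n_replicates, "n_replicates")
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    stop("mean depth must be > 0", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must lie in [0, 0.5)", call. = FALSE)
  }
  if (paralog_fraction < 0 || paralog_fraction > 1) {
    stop("`paralog_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(dosage_weights)) {
    dosage_weights <- switch(as.character(ploidy),
      "2" = 1,
      "3" = c(0.5, 0.5),
      "4" = c(0.25, 0.5, 0.25)
    )
  }
  if (length(dosage_weights) != ploidy - 1) {
    stop(sprintf(
      "`dosage_weights` must have length ploidy - 1 = %d (dosages 1..%d)",
      ploidy - 1, ploidy - 1
    ), call. = FALSE)
  }
  if (any(dosage_weights < 0) || abs(sum(dosage_weights) - 1) > 1e-12) {
    stop("`dosage_weights` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(
      ploidy = as.integer(ploidy), n_snps = as.integer(n_snps),
      depth_law = depth_law, depth_mean = depth_mean,
      error_rate = error_rate, paralog_fraction = paralog_fraction,
      dosage_weights = as.numeric(dosage_weights),
      n_replicates = as.integer(n_replicates), seed = as.integer(seed)
    ),
    class = "snp_sim_config"
  )
}

#' Configuration for the contig-alignment simulator
#'
#' Emulates the situation where duplicated loci (homeologues) are collapsed
#' into a single assembled contig, so that reads from one sample carry 1-4
#' distinct haplotypes per contig.  Each contig draws its true haplotype
#' number, haplotypes differ at a set of variant columns, and reads are
#' error-free copies of one haplotype over a contiguous span.
#'
#' @param n_contigs Number of contigs.
#' @param haplotype_probs Probability vector over true haplotype numbers
#'   1..4 per contig.
#' @param n_variant_columns Variant columns per contig; a single value or a
#'   vector to sample from uniformly (e.g. `2:4`).
#' @param reads_per_haplotype Reads drawn from each true haplotype.
#' @param read_span Aligned length of every read, in bases.
#' @param contig_length Contig length in bases; must be >= `read_span`.
#' @param haplotype_divergence Per-column probability that the haplotypes
#'   differ at that column (each haplotype then draws its own base).
#' @param seed Integer seed.
#'
#' @return An object of class `contig_sim_config`.
#' @seealso [simulate_contig_alignments()]
#' @export
contig_sim_config <- function(n_contigs = 100,
                              haplotype_probs = c(0, 1, 0, 0),
                              n_variant_columns = 2:4,
                              reads_per_haplotype = 25,
                              read_span = 150,
                              contig_length = 300,
                              haplotype_divergence = 1,
                              seed = 1) {
  stop_if_not_count(n_contigs, "n_contigs")
  stop_if_not_count(reads_per_haplotype, "reads_per_haplotype")
  stop_if_not_count(read_span, "read_span")
  stop_if_not_count(contig_length, "contig_length")
  if (length(haplotype_probs) != 4 || any(haplotype_probs < 0) ||
      abs(sum(haplotype_probs) - 1) > 1e-12) {
    stop("`haplotype_probs` must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (any(n_variant_columns < 1)) {
    stop("`n_variant_columns` must be >= 1", call. = FALSE)
  }
  if (contig_length < read_span) {
    stop("`contig_length` must be >= `read_span`", call. = FALSE)
  }
  if (haplotype_divergence < 0 || haplotype_divergence > 1) {
    stop("`haplotype_divergence` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_contigs = as.integer(n_contigs),
      haplotype_probs = as.numeric(haplotype_probs),
      n_variant_columns = as.integer(n_variant_columns),
      reads_per_haplotype = as.integer(reads_per_haplotype),
      read_span = as.integer(read_span),
      contig_length = as.integer(contig_length),
      haplotype_divergence = haplotype_divergence,
      seed = as.integer(seed)
    ),
    class = "contig_sim_config"
  )
}

#' Configuration for the Ornstein-Uhlenbeck trait simulator
#'
#' Traits evolve on an ultrametric tree toward a lineage-specific optimum:
#' selection strength `alpha` (per unit tree height), diffusion variance
#' `sigma2`, root held at the base optimum `theta0`, and persistent optimum
#' shifts (`offsets`, in trait units) on chosen branches that apply to all
#' descendant lineages.
#'
#' @param tree An ultrametric `phylo` tree (checked to relative tolerance
#'   1e-9 of its height).
#' @param shift_edges Integer indices into `tree$edge` rows carrying
#'   optimum shifts; may be empty.
#' @param offsets Numeric optimum offsets, one per shift edge.
#' @param theta0 Base (root) optimum.
#' @param alpha Selection strength, >= 0 (0 is the Brownian-motion limit,
#'   under which optima have no effect).
#' @param sigma2 Diffusion variance, > 0.
#' @param seed Integer seed.
#'
#' @return An object of class `ou_sim_config`.
#' @seealso [simulate_ou_traits()], [detect_shifts()]
#' @export
ou_sim_config <- function(tree, shift_edges = integer(), offsets = numeric(),
                          theta0 = 0, alpha = 2, sigma2 = 1, seed = 1) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  assert_ultrametric(tree, rel_tol = 1e-9)
  if (length(shift_edges) != length(offsets)) {
    stop("`shift_edges` and `offsets` must have the same length",
         call. = FALSE)
  }
  if (length(shift_edges) &&
      (any(shift_edges < 1) || any(shift_edges > nrow(tree$edge)))) {
    stop("`shift_edges` must index rows of tree$edge", call. = FALSE)
  }
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (sigma2 <= 0) stop("`sigma2` must be > 0", call. = FALSE)
  structure(
    list(
      tree = tree, shift_edges = as.integer(shift_edges),
      offsets = as.numeric(offsets), theta0 = theta0,
      alpha = alpha, sigma2 = sigma2, seed = as.integer(seed)
    ),
    class = "ou_sim_config"
  )
}
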