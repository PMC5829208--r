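#' Simulate replicate SNP allele-depth records
#'
#' Generates per-replicate bi-allelic SNP records for one individual under a
#' known ploidy.  For each of `n_snps` sites an alternate-allele dosage `d`
#' is drawn from `dosage_weights`; in each replicate library a read depth is
#' drawn from `depth_law`, and the reference read count is binomial with
#' success probability `(ploidy - d) / ploidy`, perturbed by the symmetric
#' per-read error rate.  Diploid sites flagged as collapsed paralogs
#' (probability `paralog_fraction`) instead use reference probability 0.25
#' or 0.75 with equal chance, mimicking two co-assembled loci.  Sites,
#' alleles and dosages are shared across replicates (the replicates
#' resequence the same individual); depths and read counts are drawn
#' independently per replicate.
#'
#' @param config A [snp_sim_config()].
#'
#' @return A data frame of SNP records with columns `replicate`, `contig`,
#'   `position`, `ref_allele`, `alt_allele`, `ref_count`, `alt_count`, and
#'   attributes `dosage` (true per-site dosage, 0 marking paralog sites)
#'   and `config`.
#'
#' @examples
#' recs <- simulate_read_ratio_dataset(
#'   snp_sim_config(ploidy = 2, n_snps = 500, error_rate = 0,
#'                  paralog_fraction = 0, seed = 7))
#' head(recs)
#' @export
simulate_read_ratio_dataset <- function(config) {
  stopifnot(inherits(config, "snp_sim_config"))
  with_seed(config$seed, {
    n <- config$n_snps
    ploidy <- config$ploidy

    # site map: ~50 sites per contig, unique positions within a contig
    n_contigs <- max(1L, ceiling(n / 50))
    contig <- sprintf("ctg%05d", sample.int(n_contigs, n, replace = TRUE))
    position <- integer(n)
    for (ct in unique(contig)) {
      idx <- which(contig == ct)
      position[idx] <- sort(sample.int(10000L, length(idx)))
    }
    bases <- c("A", "C", "G", "T")
    ri <- sample.int(4L, n, replace = TRUE)
    ref_allele <- bases[ri]
    alt_allele <- bases[((ri - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]

    dosage <- sample.int(ploidy - 1L, n, replace = TRUE,
                         prob = config$dosage_weights)
    p_ref <- (ploidy - dosage) / ploidy
    if (ploidy == 2L && config$paralog_fraction > 0) {
      is_par <- stats::runif(n) < config$paralog_fraction
      p_ref[is_par] <- sample(c(0.25, 0.75), sum(is_par), replace = TRUE)
      dosage[is_par] <- 0L # 0 marks a paralog site in the truth attribute
    }
    e <- config$error_rate
    p_obs <- p_ref * (1 - e) + (1 - p_ref) * e

    out <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      depth <- switch(config$depth_law,
        fixed = rep.int(as.integer(round(config$depth_mean)), n),
        poisson = pmax(1L, stats::rpois(n, config$depth_mean))
      )
      ref_count <- stats::rbinom(n, depth, p_obs)
      out[[r]] <- data.frame(
        replicate = r, contig = contig, position = position,
        ref_allele = ref_allele, alt_allele = alt_allele,
        ref_count = ref_count, alt_count = depth - ref_count,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "dosage") <- dosage
    attr(res, "config") <- config
    res
  })
}
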