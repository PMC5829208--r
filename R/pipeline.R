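#' Configuration for a full pipeline run
#'
#' Collects stage selection and all stage parameters for
#' [run_pipeline()].  Unknown parameter names are rejected so a typo
#' cannot silently fall back to a default.
#'
#' @param stages Character vector drawn from `"simulate"`, `"snp"`,
#'   `"mixture"`, `"haplotypes"`, `"shifts"`; may be empty.
#' @param out_dir Output directory for intermediate TSVs and the
#'   manifest.
#' @param seed Integer master seed, recorded in the manifest.
#' @param sim Parameters forwarded to [snp_sim_config()] (the `simulate`
#'   stage).
#' @param snp List with `min_total`, `max_total`, `min_ref` for
#'   [filter_biallelic()], and optionally `rep1`/`rep2` TSV paths when
#'   the `simulate` stage is not run.
#' @param mixture Parameters forwarded to [fit_ratio_mixture()] plus
#'   optional `t_low`/`t_high` for [classify_ploidy()].
#' @param haplotypes List with `sim` (a [contig_sim_config()] parameter
#'   list or `NULL`), `alignments` (TSV path), `min_reads_per_hap`,
#'   `max_span`.
#' @param shifts List with `tree` (Newick path or `phylo`), `traits`
#'   (TSV path or named vector), `criterion`, `n_boot`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "snp", "mixture"),
                       out_dir = tempfile("ploidyshift_run_"),
                       seed = 1,
                       sim = list(),
                       snp = list(),
                       mixture = list(),
                       haplotypes = list(),
                       shifts = list(),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  known <- c("simulate", "snp", "mixture", "haplotypes", "shifts")
  if (length(stages) && !all(stages %in% known)) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "), call. = FALSE)
  }
  check_keys <- function(lst, allowed, where) {
    extra <- setdiff(names(lst), allowed)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in `%s`: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(sim, names(formals(snp_sim_config)), "sim")
  check_keys(snp, c("min_total", "max_total", "min_ref", "min_alt",
                    "rep1", "rep2"), "snp")
  check_keys(mixture, c(setdiff(names(formals(fit_ratio_mixture)),
                                "ratios"), "t_low", "t_high"), "mixture")
  check_keys(haplotypes, c("sim", "alignments", "min_reads_per_hap",
                           "max_span", "min_allele_reads"), "haplotypes")
  check_keys(shifts, c("tree", "traits", "criterion", "n_boot",
                       "alpha_grid", "nlambda", "max_shifts"), "shifts")
  structure(
    list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
         sim = sim, snp = snp, mixture = mixture,
         haplotypes = haplotypes, shifts = shifts, log_level = log_level),
    class = "run_config"
  )
}

run_log <- function(config, fmt, ...) {
  if (config$log_level == "info") message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the WGD-signal pipeline
#'
#' Chains the selected stages in order — simulate replicate SNP data,
#' filter and intersect replicates, fit the read-ratio mixture and
#' classify ploidy, count haplotypes per contig, and detect OU optimum
#' shifts — writing every intermediate table to `config$out_dir` and
#' returning a manifest of record counts.  Rerunning with the same config
#' (including seeds) reproduces the outputs byte for byte.
#'
#' @param config A [run_config()].
#' @return An object of class `run_manifest`: the config echo, per-stage
#'   record counts, key results (`peak_ratio`, `category`,
#'   `haplotype_frequencies`, `shift_edges`), package version and wall
#'   time.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  results <- list()

  records <- NULL
  if ("simulate" %in% config$stages) {
    sim_cfg <- do.call(snp_sim_config,
                       utils::modifyList(list(seed = config$seed),
                                         config$sim))
    records <- simulate_read_ratio_dataset(sim_cfg)
    write_snp_tsv(records, file.path(config$out_dir, "snp_records.tsv"))
    counts$simulated <- nrow(records)
    run_log(config, "simulate: %d records (%d replicates)",
            nrow(records), sim_cfg$n_replicates)
  }

  combined <- NULL
  if ("snp" %in% config$stages) {
    if (is.null(records)) {
      if (is.null(config$snp$rep1) || is.null(config$snp$rep2)) {
        stop("snp stage: no simulated records and no rep1/rep2 inputs",
             call. = FALSE)
      }
      r1 <- read_snp_tsv(config$snp$rep1)
      r2 <- read_snp_tsv(config$snp$rep2)
    } else {
      r1 <- records[records$replicate == 1L, , drop = FALSE]
      r2 <- records[records$replicate == 2L, , drop = FALSE]
    }
    counts$snp_input <- nrow(r1) + nrow(r2)
    args <- config$snp[names(config$snp) %in%
                         c("min_total", "max_total", "min_ref", "min_alt")]
    f1 <- do.call(filter_biallelic, c(list(r1), args))
    f2 <- do.call(filter_biallelic, c(list(r2), args))
    counts$snp_filtered <- nrow(f1) + nrow(f2)
    run_log(config,
            "snp filter (total %s-%s, ref >= %s): %d of %d records kept",
            args$min_total %||% 10, args$max_total %||% 300,
            args$min_ref %||% 5, counts$snp_filtered, counts$snp_input)
    combined <- intersect_replicates(f1, f2)
    counts$snp_combined <- nrow(combined)
    run_log(config, "replicate intersection: %d shared SNPs",
            nrow(combined))
    write_snp_tsv(combined, file.path(config$out_dir, "snp_combined.tsv"))
  }

  if ("mixture" %in% config$stages) {
    if (is.null(combined)) {
      stop("mixture stage requires the snp stage", call. = FALSE)
    }
    ratios <- compute_ratios(combined)
    counts$ratios <- nrow(ratios)
    cls_args <- config$mixture[names(config$mixture) %in%
                                 c("t_low", "t_high")]
    fit_args <- config$mixture[!names(config$mixture) %in%
                                 c("t_low", "t_high")]
    fit <- do.call(fit_ratio_mixture, c(list(ratios), fit_args))
    pr <- peak_ratio(fit)
    results$peak_ratio <- pr
    results$category <- do.call(classify_ploidy, c(list(pr), cls_args))
    results$mixture <- data.frame(
      component = c("low", "mid", "high"),
      mu = fit$mu, sigma = fit$sigma, lambda = fit$lambda
    )
    utils::write.table(
      cbind(results$mixture,
            loglik = fit$loglik, peak_ratio = pr,
            category = results$category),
      file.path(config$out_dir, "mixture_fit.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    run_log(config, "mixture: peak ratio %.4f -> %s", pr, results$category)
  }

  if ("haplotypes" %in% config$stages) {
    h <- config$haplotypes
    if (!is.null(h$sim)) {
      hap_cfg <- do.call(contig_sim_config,
                         utils::modifyList(list(seed = config$seed), h$sim))
      alns <- simulate_contig_alignments(hap_cfg)
      write_alignment_tsv(alns,
                          file.path(config$out_dir, "alignments.tsv"))
    } else if (!is.null(h$alignments)) {
      alns <- read_alignment_tsv(h$alignments)
    } else {
      stop("haplotypes stage: provide `sim` parameters or `alignments`",
           call. = FALSE)
    }
    counts$contigs <- length(alns)
    hap_counts <- vapply(alns, function(a) {
      count_haplotypes(filter_reads(a, h$max_span %||% 200),
                       min_reads_per_hap = h$min_reads_per_hap %||% 20,
                       min_allele_reads = h$min_allele_reads %||% 2)
    }, integer(1))
    hs <- haplotype_frequency_distribution(hap_counts)
    results$haplotype_frequencies <- hs$frequencies
    utils::write.table(
      data.frame(contig = vapply(alns, `[[`, "", "contig"),
                 haplotypes = hap_counts),
      file.path(config$out_dir, "haplotype_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    run_log(config, "haplotypes: %d contigs, frequencies %s",
            length(alns),
            paste(sprintf("%s=%.3f", names(hs$frequencies),
                          hs$frequencies), collapse = " "))
  }

  if ("shifts" %in% config$stages) {
    s <- config$shifts
    if (is.null(s$tree) || is.null(s$traits)) {
      stop("shifts stage: provide `tree` and `traits`", call. = FALSE)
    }
    tree <- if (inherits(s$tree, "phylo")) s$tree else
      ape::read.tree(s$tree)
    traits <- if (is.character(s$traits)) read_traits_tsv(s$traits) else
      s$traits
    fit <- detect_shifts(tree, traits,
                         criterion = s$criterion %||% "ebic",
                         alpha_grid = s$alpha_grid,
                         nlambda = s$nlambda %||% 50,
                         max_shifts = s$max_shifts)
    if (!is.null(s$n_boot) && s$n_boot >= 2 && length(fit$shift_edges)) {
      fit <- bootstrap_support(fit, n_boot = s$n_boot, seed = config$seed)
    }
    sm <- summary(fit)$shifts
    utils::write.table(sm, file.path(config$out_dir, "shifts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$shift_edges <- fit$shift_edges
    results$shift_fit <- fit
    run_log(config, "shifts: %d selected (alpha %.3g)",
            length(fit$shift_edges), fit$alpha)
  }

  manifest <- structure(
    list(config = config, counts = counts, results = results,
         version = as.character(utils::packageVersion("ploidyshift")),
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "run_manifest"
  )
  manifest_df <- data.frame(stage = names(counts),
                            records = unlist(counts, use.names = FALSE))
  utils::write.table(manifest_df,
                     file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("ploidyshift run manifest (v", x$version, ")\n", sep = "")
  cat("  stages:", paste(x$config$stages, collapse = " -> "), "\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-14s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.null(x$results$peak_ratio)) {
    cat(sprintf("  peak ratio %.4f -> %s\n", x$results$peak_ratio,
                x$results$category))
  }
  if (!is.null(x$results$haplotype_frequencies)) {
    cat("  haplotype frequencies:",
        paste(sprintf("%s=%.3f", names(x$results$haplotype_frequencies),
                      x$results$haplotype_frequencies), collapse = " "),
        "\n")
  }
  if (!is.null(x$results$shift_edges)) {
    cat("  shift edges:",
        if (length(x$results$shift_edges))
          paste(x$results$shift_edges, collapse = ", ") else "none", "\n")
  }
  cat(sprintf("  wall time %.2f s\n", x$wall_time))
  invisible(x)
}
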