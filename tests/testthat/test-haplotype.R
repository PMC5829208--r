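test_that("variant columns require two supported alleles", {
  # all reads identical: no variant columns
  aln <- phased_alignment(list(list(n = 30, bases = c(`50` = "A"))))
  expect_identical(call_variant_columns(aln), integer())
  # a clean 25/25 split at one column
  aln2 <- phased_alignment(list(list(n = 25, bases = c(`50` = "A")),
                                list(n = 25, bases = c(`50` = "G"))))
  expect_identical(call_variant_columns(aln2), 50L)
  # a single-read minor allele does not reach the default support of 2
  aln3 <- phased_alignment(list(list(n = 30, bases = c(`50` = "A")),
                                list(n = 1, bases = c(`50` = "G"))))
  expect_identical(call_variant_columns(aln3), integer())
  expect_identical(call_variant_columns(aln3, min_allele_reads = 1), 50L)
})

test_that("reads stretching beyond the span cap are excluded", {
  aln <- contig_alignment(
    contig = "c1", contig_length = 400,
    reads = data.frame(read_id = c("a", "b", "c"),
                       start = c(1, 1, 10), end = c(250, 200, 150)),
    calls = data.frame(read_id = c("a", "b", "c"), pos = c(50, 50, 50),
                       base = c("A", "A", "G"))
  )
  out <- filter_reads(aln, max_span = 200)
  expect_identical(out$reads$read_id, c("b", "c")) # 250-base span removed
  expect_identical(sort(unique(out$calls$read_id)), c("b", "c"))
  empty <- contig_alignment("c2", 100,
                            data.frame(read_id = character(),
                                       start = integer(), end = integer()),
                            data.frame(read_id = character(),
                                       pos = integer(), base = character()))
  expect_identical(nrow(filter_reads(empty)$reads), 0L)
})

test_that("haplotype counting matches the phased structure of the reads", {
  # 50 identical reads, no variants -> one haplotype
  expect_identical(
    count_haplotypes(phased_alignment(list(list(n = 50, bases = c())))), 1L)
  # two phased groups disagreeing at two columns -> two
  two <- phased_alignment(list(
    list(n = 25, bases = c(`40` = "A", `60` = "C")),
    list(n = 25, bases = c(`40` = "G", `60` = "T"))))
  expect_identical(count_haplotypes(two), 2L)
  # four mutually conflicting groups of 25 -> four
  four <- phased_alignment(list(
    list(n = 25, bases = c(`40` = "A", `60` = "A")),
    list(n = 25, bases = c(`40` = "C", `60` = "C")),
    list(n = 25, bases = c(`40` = "G", `60` = "G")),
    list(n = 25, bases = c(`40` = "T", `60` = "T"))))
  expect_identical(count_haplotypes(four), 4L)
  # the same with one group at 10 reads: that haplotype fails the 20-read
  # support filter
  three <- phased_alignment(list(
    list(n = 25, bases = c(`40` = "A", `60` = "A")),
    list(n = 25, bases = c(`40` = "C", `60` = "C")),
    list(n = 25, bases = c(`40` = "G", `60` = "G")),
    list(n = 10, bases = c(`40` = "T", `60` = "T"))))
  expect_identical(count_haplotypes(three), 3L)
  # both groups below 20 reads -> nothing survives the support filter
  weak <- phased_alignment(list(
    list(n = 15, bases = c(`40` = "A")),
    list(n = 15, bases = c(`40` = "G"))))
  expect_identical(count_haplotypes(weak), 0L)
  # empty alignment -> zero
  empty <- contig_alignment("c", 100,
                            data.frame(read_id = character(),
                                       start = integer(), end = integer()),
                            data.frame(read_id = character(),
                                       pos = integer(), base = character()))
  expect_identical(count_haplotypes(empty), 0L)
})

test_that("partial-overlap chains are merged within, not across, haplotypes", {
  # two haplotypes, each sequenced as three staggered read groups that
  # agree where they overlap; conservative counting must chain each
  # haplotype's groups together and keep the haplotypes apart
  hap_bases <- list(
    list(c(`50` = "A", `90` = "C"), c(`90` = "C", `170` = "G"),
         c(`170` = "G", `250` = "T")),
    list(c(`50` = "T", `90` = "G"), c(`90` = "G", `170` = "A"),
         c(`170` = "A", `250` = "C"))
  )
  reads <- list()
  calls <- list()
  idx <- 0L
  for (h in 1:2) {
    for (g in 1:3) {
      st <- c(1, 80, 160)[g]
      for (i in 1:10) {
        idx <- idx + 1L
        id <- sprintf("r%02d", idx)
        reads[[idx]] <- data.frame(read_id = id, start = st, end = st + 99)
        b <- hap_bases[[h]][[g]]
        calls[[idx]] <- data.frame(read_id = id,
                                   pos = as.integer(names(b)),
                                   base = unname(b))
      }
    }
  }
  aln <- contig_alignment("c1", 300, do.call(rbind, reads),
                          do.call(rbind, calls))
  expect_identical(count_haplotypes(aln), 2L)
})

test_that("greedy conflict coloring equals the exact chromatic number", {
  n_agree <- 0L
  for (seed in 1:100) {
    cfg <- contig_sim_config(
      n_contigs = 1,
      haplotype_probs = c(0.2, 0.35, 0.3, 0.15),
      n_variant_columns = 2:3, reads_per_haplotype = 3,
      read_span = 60, contig_length = 120,
      haplotype_divergence = 0.9, seed = seed
    )
    aln <- simulate_contig_alignments(cfg)[[1]]
    cols <- call_variant_columns(aln, min_allele_reads = 1)
    bm <- ploidyshift:::call_matrix(aln, cols)
    adj <- ploidyshift:::conflict_graph(bm)
    ord <- order(aln$reads$start, aln$reads$read_id)
    greedy <- max(ploidyshift:::greedy_coloring(adj, ord), 1L)
    if (greedy == chromatic_number(adj)) n_agree <- n_agree + 1L
  }
  expect_identical(n_agree, 100L)
})

test_that("counts are bounded by reads and surviving column alleles", {
  for (seed in 1:20) {
    cfg <- contig_sim_config(n_contigs = 1,
                             haplotype_probs = c(0.25, 0.25, 0.25, 0.25),
                             n_variant_columns = 3,
                             reads_per_haplotype = 6, read_span = 100,
                             contig_length = 150, seed = 400 + seed)
    aln <- simulate_contig_alignments(cfg)[[1]]
    cnt <- count_haplotypes(aln, min_reads_per_hap = 1)
    expect_lte(cnt, nrow(aln$reads))
    cols <- call_variant_columns(aln)
    if (length(cols)) {
      bm <- ploidyshift:::call_matrix(aln, cols)
      max_alleles <- max(apply(bm, 2, function(col) {
        tab <- table(col[!is.na(col)])
        sum(tab >= 2)
      }))
      expect_gte(cnt, max_alleles)
    }
  }
})

test_that("simulated diploid contigs score at most two haplotypes", {
  cfg <- contig_sim_config(n_contigs = 50, haplotype_probs = c(0, 1, 0, 0),
                           reads_per_haplotype = 25, seed = 6)
  alns <- simulate_contig_alignments(cfg)
  counts <- vapply(alns, function(a) count_haplotypes(filter_reads(a)),
                   integer(1))
  expect_gte(mean(counts <= 2), 0.95)
  expect_true(all(counts >= 1))
})

test_that("under-supported simulated contigs score zero haplotypes", {
  cfg <- contig_sim_config(n_contigs = 10, haplotype_probs = c(0, 1, 0, 0),
                           reads_per_haplotype = 8, read_span = 150,
                           contig_length = 160,
                           n_variant_columns = 3, seed = 13)
  alns <- simulate_contig_alignments(cfg)
  counts <- vapply(alns, function(a) count_haplotypes(filter_reads(a)),
                   integer(1))
  expect_true(all(counts == 0L))
})

test_that("haplotype frequencies group contigs as 1, 2 and 3+", {
  hs <- haplotype_frequency_distribution(
    c(rep(1, 95), rep(2, 4), 3))
  expect_equal(unname(hs$frequencies), c(0.95, 0.04, 0.01))
  expect_equal(sum(hs$frequencies), 1, tolerance = 1e-9)
  hs2 <- haplotype_frequency_distribution(rep(1, 10))
  expect_equal(unname(hs2$frequencies), c(1, 0, 0))
  hs3 <- haplotype_frequency_distribution(c(rep(1, 50), rep(2, 30),
                                            rep(4, 20)))
  expect_equal(unname(hs3$frequencies), c(0.5, 0.3, 0.2))
  # zeros are excluded from the denominator
  hs4 <- haplotype_frequency_distribution(c(0, 0, 1, 2))
  expect_equal(hs4$n_contigs, 2L)
  expect_equal(hs4$n_zero, 2L)
  expect_error(haplotype_frequency_distribution(c(0, 0)), "zero")
  expect_error(haplotype_frequency_distribution(c(-1, 2)), "non-negative")
})
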