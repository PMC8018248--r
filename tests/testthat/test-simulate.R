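test_that("generation is byte-identical under a fixed seed", {
  g1 <- sim_genomes(2, seed = 601)
  g2 <- sim_genomes(2, seed = 601)
  expect_identical(g1, g2)
  expect_false(identical(g1$sequence, sim_genomes(2, seed = 602)$sequence))
  lr1 <- sim_long_reads(g1, 50, chimera_rate = 0.1, seed = 603)
  lr2 <- sim_long_reads(g1, 50, chimera_rate = 0.1, seed = 603)
  expect_identical(lr1, lr2)
  tf1 <- withr::local_tempfile(fileext = ".fastq")
  tf2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lr1$reads, tf1)
  write_fastq(lr2$reads, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("genome GC and exact lengths obey the configuration", {
  g <- sim_genomes(1, lengths = 100000L, gc_range = c(0.5, 0.5), seed = 611)
  gc_obs <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc_obs - 0.5), 0.02)   # well inside the binomial interval
  g3 <- sim_genomes(3, lengths = c(38200L, 65000L, 129400L), seed = 612)
  expect_equal(g3$length, c(38200L, 65000L, 129400L))
  expect_equal(nchar(g3$sequence), g3$length)
})

test_that("strain variants differ at exactly the planted sites", {
  g <- sim_genomes(1, lengths = 20000L, seed = 621)
  st0 <- sim_strain(g, n_sites = 0L, seed = 622)
  expect_identical(st0$sequence, g$sequence)
  st <- sim_strain(g, minor_freq = 0.2, n_sites = 40L, seed = 623)
  a <- strsplit(g$sequence, "")[[1]]
  b <- strsplit(st$sequence, "")[[1]]
  diffs <- which(a != b) - 1L
  expect_equal(diffs, st$snps$pos)
  expect_equal(a[diffs + 1L], st$snps$ref)
  expect_equal(b[diffs + 1L], st$snps$alt)
})

test_that("error-free long reads are exact (wrapped) genome substrings", {
  g <- sim_genomes(1, lengths = 30000L, seed = 631)
  lr <- sim_long_reads(g, 40, sub_rate = 0, ins_rate = 0, del_rate = 0,
                       seed = 632)
  doubled <- paste0(g$sequence, g$sequence)
  for (i in seq_len(nrow(lr$reads))) {
    s <- lr$reads$sequence[i]
    hit <- grepl(s, doubled, fixed = TRUE) ||
      grepl(viromer:::revcomp(s), doubled, fixed = TRUE)
    expect_true(hit, info = lr$reads$read_id[i])
  }
  # truth coordinates reproduce each read exactly
  tr <- lr$truth
  for (i in seq_len(nrow(tr))) {
    frag <- substr(doubled, tr$genome_start[i] + 1, tr$genome_end[i])
    if (tr$strand[i] == "-") frag <- viromer:::revcomp(frag)
    expect_equal(substr(lr$reads$sequence[match(tr$read_id[i], lr$reads$read_id)],
                        tr$read_start[i] + 1, tr$read_end[i]),
                 frag)
  }
})

test_that("chimera counts fall inside the binomial interval", {
  g <- sim_genomes(2, lengths = c(30000L, 40000L), seed = 641)
  lr <- sim_long_reads(g, 10000, read_median_bp = 2000, sub_rate = 0,
                       ins_rate = 0, del_rate = 0, chimera_rate = 0.05,
                       seed = 642)
  n_chim <- sum(dplyr::distinct(lr$truth, .data$read_id,
                                .data$is_chimera)$is_chimera)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(n_chim, ci[1])
  expect_lte(n_chim, ci[2])
  # chimera truth records carry two origins and a junction
  chim <- lr$truth[lr$truth$is_chimera, ]
  expect_true(all(table(chim$read_id) == 2L))
  expect_true(all(!is.na(chim$junction)))
})

test_that("long-read lengths hit the configured median", {
  g <- sim_genomes(1, lengths = 100000L, seed = 651)
  lr <- sim_long_reads(g, 10000, read_median_bp = 7000, sub_rate = 0,
                       ins_rate = 0, del_rate = 0, seed = 652)
  expect_lt(abs(median(lr$reads$length) - 7000) / 7000, 0.05)
})

test_that("short-read pairs tile the genome at the target depth", {
  g <- sim_genomes(1, lengths = 100000L, seed = 661)
  sr <- sim_short_reads(g, depth = 50, seed = 662)
  expect_equal(sr$n_pairs, 20000L)
  expect_equal(nrow(sr$reads), 40000L)
  # error-free mates are exact substrings at their truth coordinates
  idx <- sample.int(nrow(sr$alignments), 200)
  for (i in idx) {
    a <- sr$alignments[i, ]
    frag <- substr(g$sequence, a$target_start + 1, a$target_end)
    got <- sr$reads$sequence[match(a$query_id, sr$reads$read_id)]
    if (a$strand == "-") frag <- viromer:::revcomp(frag)
    expect_equal(got, frag, info = a$query_id)
  }
  # insert-size convention: mate gap = insert - 2 * read_len on average
  starts <- matrix(sr$alignments$target_start, ncol = 2)
  gap <- starts[, 2] - starts[, 1] - 125
  expect_lt(abs(mean(gap) - (400 - 250)), 5)
})

test_that("strain mixtures express the minor frequency in sampled reads", {
  f <- 0.2
  g <- sim_genomes(1, lengths = 5000L, seed = 671)
  st <- sim_strain(g, minor_freq = f, n_sites = 20L, seed = 672)
  sr <- sim_short_reads(g, depth = 500, strain = st, minor_freq = f,
                        seed = 673)
  # count alternate alleles directly from read sequences via truth coords
  ctg <- tibble::tibble(contig_id = g$genome_id, sequence = g$sequence,
                        length = g$length)
  pu <- build_pileup(sr$alignments, sr$reads, ctg, min_base_quality = 0)
  for (k in seq_len(nrow(st$snps))) {
    col <- pu[pu$pos == st$snps$pos[k], ]
    freq <- col[[st$snps$alt[k]]] / col$depth
    ci <- qbinom(c(0.005, 0.995), col$depth, f) / col$depth
    expect_gte(freq, ci[1])
    expect_lte(freq, ci[2])
  }
})

test_that("QC library truth labels agree with the filter rule arithmetic", {
  ql <- sim_qc_library(400, seed = 681)
  res <- qc_filter(ql$reads)
  expect_setequal(res$kept$read_id, ql$truth$read_id[ql$truth$keep])
  got <- res$removed[order(res$removed$read_id), ]
  want <- ql$truth[!ql$truth$keep, ][order(ql$truth$read_id[!ql$truth$keep]), ]
  expect_equal(got$reason, want$reason)
})

test_that("contig sets and their alignments stay internally consistent", {
  cs <- sim_contig_set(20, seed = 691)
  a <- cs$alignments
  lens <- setNames(cs$contigs$length, cs$contigs$contig_id)
  expect_true(all(a$query_end <= lens[a$query_id]))
  expect_true(all(a$target_end <= lens[a$target_id]))
  expect_true(all(a$query_end - a$query_start ==
                  a$target_end - a$target_start))
  expect_true(all(a$matches <= a$block_len))
})
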