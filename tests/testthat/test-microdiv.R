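mk_aln <- function(id, identity, rcov, qlen = 1000L) {
  alen <- as.integer(round(rcov * qlen))
  alignment_tbl(id, "t", qlen, 50000L, 0L, alen, 0L, alen, "+",
                matches = as.integer(round(identity * alen)),
                block_len = alen)
}

test_that("read mapping thresholds are inclusive at the boundary", {
  aln <- dplyr::bind_rows(
    mk_aln("keep_both", 0.96, 0.80),
    mk_aln("drop_ident", 0.94, 0.99),
    mk_aln("exact_boundary", 0.95, 0.70),
    mk_aln("drop_cov", 0.99, 0.60)
  )
  kept <- filter_read_alignments(aln)
  expect_setequal(kept$query_id, c("keep_both", "exact_boundary"))
  aln$query_len <- NA_integer_
  expect_error(filter_read_alignments(aln), "query_len")
})

test_that("population selection uses strict breadth and depth thresholds", {
  ctg <- tibble::tibble(contig_id = "c", length = 10000L)
  cover <- function(total_span, depth) {
    # `depth` stacked alignments over the first total_span bases
    purrr::map(seq_len(depth), function(i) {
      alignment_tbl(paste0("r", i), "c", total_span, 10000L, 0L, total_span,
                    0L, total_span, "+", total_span, total_span)
    }) |> purrr::list_rbind()
  }
  sel <- select_populations(ctg, cover(7100L, 17))   # breadth .71, depth 12.07
  expect_true(sel$selected)
  expect_equal(sel$breadth, 0.71)
  sel2 <- select_populations(ctg, cover(6900L, 80))  # breadth .69, depth high
  expect_false(sel2$selected)
  # depth exactly 10.0 fails the strict > rule
  aln3 <- purrr::map(1:10, function(i) {
    alignment_tbl(paste0("r", i), "c", 10000L, 10000L, 0L, 10000L, 0L,
                  10000L, "+", 10000L, 10000L)
  }) |> purrr::list_rbind()
  sel3 <- select_populations(ctg, aln3)
  expect_equal(sel3$mean_depth, 10)
  expect_false(sel3$selected)
  expect_equal(select_populations(ctg, empty_aln())$breadth, 0)
})

test_that("the SNP truth rule needs >= 4 reads and > 1% frequency", {
  ref <- make_contig("c", strrep("A", 10))
  pu <- tibble::tibble(
    contig_id = "c", pos = c(0L, 1L, 2L),
    A = c(27L, 95L, 496L), C = c(3L, 5L, 4L), G = 0L, T = 0L,
    depth = c(30L, 100L, 500L)
  )
  snps <- call_snps(pu, ref)
  expect_equal(snps$alt, rep("C", 3))
  expect_equal(snps$is_true, c(FALSE, TRUE, FALSE))
  expect_equal(snps$alt_freq, c(0.1, 0.05, 0.008))
})

test_that("multi-allelic sites yield one call per alternate base", {
  ref <- make_contig("c", "AN")
  pu <- tibble::tibble(contig_id = "c", pos = c(0L, 1L),
                       A = c(80L, 50L), C = c(12L, 10L), G = c(8L, 0L),
                       T = 0L, depth = c(100L, 60L))
  snps <- call_snps(pu, ref)
  # position 1 skipped (reference N); position 0 has two alt calls
  expect_equal(nrow(snps), 2L)
  expect_setequal(snps$alt, c("C", "G"))
  expect_equal(snps$is_true, c(TRUE, TRUE))
})

test_that("per-site pi matches its closed form and bounds", {
  expect_equal(site_pi(c(A = 100, C = 0, G = 0, T = 0)), 0)
  expect_equal(site_pi(c(A = 90, C = 0, G = 10, T = 0)),
               (1 - (0.81 + 0.01)) * 100 / 99)
  expect_equal(site_pi(c(A = 25, C = 25, G = 25, T = 25)), 0.75 * 100 / 99)
  expect_true(is.na(site_pi(c(A = 1, C = 0, G = 0, T = 0))))
  # monotone in minor-allele frequency up to 0.5, bounded by the maximum
  C <- 200
  pis <- vapply(1:100, function(k) {
    site_pi(c(A = C - k, C = k, G = 0, T = 0))
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
  expect_true(all(pis <= 0.75 * C / (C - 1) + 1e-12))
})

test_that("contig microdiversity is the median over true-SNP sites", {
  ctg <- make_contig("c", strrep("A", 100))
  pu <- tibble::tibble(contig_id = "c", pos = c(10L, 20L, 30L),
                       A = c(90L, 50L, 99L), C = c(10L, 50L, 1L), G = 0L,
                       T = 0L, depth = 100L)
  snps <- call_snps(pu, ctg)
  md <- contig_microdiversity(ctg, pu, snps)
  expect_equal(md$n_true_snps, 2L)   # the 1% site fails the rule
  expect_equal(md$pi,
               stats::median(c(site_pi(c(90, 10, 0, 0)),
                               site_pi(c(50, 50, 0, 0)))))
  # no true SNPs reports zero, not missing
  mono <- tibble::tibble(contig_id = "c", pos = 0:99, A = 100L, C = 0L,
                         G = 0L, T = 0L, depth = 100L)
  md0 <- contig_microdiversity(ctg, mono, call_snps(mono, ctg))
  expect_equal(md0$pi, 0)
  expect_equal(md0$n_true_snps, 0L)
})

test_that("a two-strain mixture recovers the analytic heterozygosity", {
  f <- 0.2; depth <- 200
  g <- sim_genomes(1, lengths = 5000L, seed = 301)
  g$contig_id <- g$genome_id
  st <- sim_strain(g, minor_freq = f, n_sites = 40L, seed = 302)
  sr <- sim_short_reads(g, depth = depth, strain = st, minor_freq = f,
                        seed = 303)
  ctg <- tibble::tibble(contig_id = g$genome_id, sequence = g$sequence,
                        length = g$length)
  pu <- build_pileup(sr$alignments, sr$reads, ctg)
  md <- contig_microdiversity(ctg, pu, call_snps(pu, ctg))
  expected <- 2 * f * (1 - f) * depth / (depth - 1)
  expect_lt(abs(md$pi - expected) / expected, 0.1)
  expect_gte(md$n_true_snps, 35L)
})

test_that("sequencing error alone rarely produces true SNPs", {
  g <- sim_genomes(1, lengths = 10000L, seed = 311)
  g$contig_id <- g$genome_id
  sr <- sim_short_reads(g, depth = 100, sub_rate = 0.001, seed = 312)
  ctg <- tibble::tibble(contig_id = g$genome_id, sequence = g$sequence,
                        length = g$length)
  pu <- build_pileup(sr$alignments, sr$reads, ctg)
  snps <- call_snps(pu, ctg)
  frac_true <- length(unique(snps$pos[snps$is_true])) / g$length
  expect_lte(frac_true, 1e-3)
})

test_that("microdiversity group comparisons match enumeration and detect shifts", {
  same <- compare_microdiversity(list(a = c(0.1, 0.2, 0.3, 0.15),
                                      b = c(0.1, 0.2, 0.3, 0.15)))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  expect_equal(same$direction, "tie")
  withr::local_seed(37)
  x <- runif(4); names(x) <- NULL
  y <- runif(4)
  res <- compare_microdiversity(list(a = x, b = y))
  expect_equal(res$u, oracle_mwu_u(x, y))
  shift <- compare_microdiversity(list(a = x, b = x + 1))
  expect_equal(shift$direction, "b>a")
  expect_equal(shift$u, 0)
  expect_warning(compare_microdiversity(list(a = 1, b = c(1, 2))), "size")
})
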