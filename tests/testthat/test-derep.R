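viral_fixture <- function() {
  withr::local_seed(19, .local_envir = parent.frame())
  contigs <- tibble::tibble(
    contig_id = c("c6000_cat2", "c6000_cat3", "c4999_cat1", "c2000_cat1",
                  "c8000_nocall"),
    length = c(6000L, 6000L, 4999L, 2000L, 8000L)
  )
  calls <- tibble::tibble(
    contig_id = c("c6000_cat2", "c6000_cat3", "c4999_cat1", "c2000_cat1"),
    category = c(2L, 3L, 1L, 1L)
  )
  list(contigs = contigs, calls = calls)
}

test_that("viral-contig filter applies category and length rules", {
  fx <- viral_fixture()
  kept <- filter_viral_contigs(fx$contigs, fx$calls)
  expect_equal(kept$contig_id, "c6000_cat2")
  # call referencing an unknown contig errors
  bad <- dplyr::bind_rows(fx$calls,
                          tibble::tibble(contig_id = "ghost", category = 1L))
  expect_error(filter_viral_contigs(fx$contigs, bad), "unknown contig")
})

test_that("pairwise similarity merges intervals on the shorter sequence", {
  a <- tibble::tibble(contig_id = "a", length = 10000L)
  b <- tibble::tibble(contig_id = "b", length = 12000L)
  full <- alignment_tbl("a", "b", 10000L, 12000L, 0L, 10000L, 0L, 10000L,
                        "+", 10000L, 10000L)
  expect_equal(pairwise_similarity(a, b, full),
               tibble::tibble(identity = 1, coverage = 1))
  part <- alignment_tbl("a", "b", 10000L, 12000L, 1000L, 9000L, 0L, 8000L,
                        "+", 7680L, 8000L)
  ps <- pairwise_similarity(a, b, part)
  expect_equal(ps$identity, 0.96)
  expect_equal(ps$coverage, 0.8)
  # two disjoint 4 kb blocks cover 0.8 of the shorter sequence, not 0.4
  two <- dplyr::bind_rows(
    alignment_tbl("a", "b", 10000L, 12000L, 0L, 4000L, 0L, 4000L, "+",
                  4000L, 4000L),
    alignment_tbl("a", "b", 10000L, 12000L, 5000L, 9000L, 6000L, 10000L,
                  "+", 4000L, 4000L)
  )
  expect_equal(pairwise_similarity(a, b, two)$coverage, 0.8)
  # overlapping intervals collapse, matching the boolean-vector oracle
  ovl <- dplyr::bind_rows(
    alignment_tbl("a", "b", 10000L, 12000L, 0L, 6000L, 0L, 6000L, "+",
                  6000L, 6000L),
    alignment_tbl("a", "b", 10000L, 12000L, 4000L, 9000L, 4000L, 9000L,
                  "+", 5000L, 5000L)
  )
  expect_equal(pairwise_similarity(a, b, ovl)$coverage,
               oracle_covered_bp(c(0, 4000), c(6000, 9000), 10000) / 10000)
  expect_equal(pairwise_similarity(a, b, empty_aln()),
               tibble::tibble(identity = 0, coverage = 0))
})

test_that("dereplication follows the greedy longest-first rule", {
  contigs <- tibble::tibble(contig_id = c("long", "short"),
                            length = c(9000L, 9000L))
  aln <- alignment_tbl("short", "long", 9000L, 9000L, 0L, 9000L, 0L, 9000L,
                       "+", 8900L, 9000L)
  m <- dereplicate(contigs, aln)
  expect_equal(unique(m$rep_id), "long")   # lexicographic tie-break at equal length
  # a contig at 90% identity to everything stays a singleton
  c2 <- tibble::tibble(contig_id = c("a", "b"), length = c(9000L, 8000L))
  lowid <- alignment_tbl("b", "a", 8000L, 9000L, 0L, 8000L, 0L, 8000L, "+",
                         7200L, 8000L)
  m2 <- dereplicate(c2, lowid)
  expect_equal(dplyr::n_distinct(m2$rep_id), 2L)
})

test_that("greedy clusters match the exhaustive oracle on simulated sets", {
  for (s in 1:8) {
    cs <- sim_contig_set(sample(6:30, 1), seed = 400 + s)
    m <- dereplicate(cs$contigs, cs$alignments)
    orc <- oracle_greedy_derep(cs$contigs, cs$alignments)
    expect_equal(m$rep_id, unname(orc[m$member_id]),
                 info = paste("set", s))
    # partition property
    expect_setequal(m$member_id, cs$contigs$contig_id)
    expect_true(all(m$rep_id %in% m$member_id))
  }
})

test_that("raising thresholds never decreases the cluster count", {
  cs <- sim_contig_set(25, seed = 501)
  n_clusters <- function(id, cov) {
    dplyr::n_distinct(dereplicate(cs$contigs, cs$alignments, id, cov)$rep_id)
  }
  base <- n_clusters(0.90, 0.50)
  expect_gte(n_clusters(0.95, 0.50), base)
  expect_gte(n_clusters(0.90, 0.70), base)
  expect_gte(n_clusters(0.99, 0.90), n_clusters(0.95, 0.70))
})

test_that("dereplicating a duplicated input yields the same cluster count", {
  cs <- sim_contig_set(12, seed = 502)
  m1 <- dereplicate(cs$contigs, cs$alignments)
  dup <- cs$contigs |> dplyr::mutate(contig_id = paste0(contig_id, "_dup"))
  both <- dplyr::bind_rows(cs$contigs, dup)
  # alignments: original pairs, mirrored pairs, and perfect self-pairs
  a <- cs$alignments
  mir <- purrr::map(list(c("_dup", ""), c("", "_dup"), c("_dup", "_dup")),
                    function(sfx) {
                      a |> dplyr::mutate(
                        query_id = paste0(query_id, sfx[1]),
                        target_id = paste0(target_id, sfx[2]))
                    }) |> purrr::list_rbind()
  selfp <- purrr::map(seq_len(nrow(cs$contigs)), function(i) {
    L <- cs$contigs$length[i]
    alignment_tbl(cs$contigs$contig_id[i],
                  paste0(cs$contigs$contig_id[i], "_dup"),
                  L, L, 0L, L, 0L, L, "+", L, L)
  }) |> purrr::list_rbind()
  m2 <- dereplicate(both, dplyr::bind_rows(a, mir, selfp))
  expect_equal(dplyr::n_distinct(m2$rep_id), dplyr::n_distinct(m1$rep_id))
})

test_that("enhanced virome attribution matches the designed overlap", {
  va <- sim_virome_assemblies(seed = 77)
  ev <- build_enhanced_virome(va$assemblies, va$alignments)
  expect_equal(ev$attribution$n_populations, 10L)
  expect_equal(ev$attribution$n_in_all, 6L)
  expect_equal(ev$attribution$unique_hybrid, 2L)
  expect_equal(ev$attribution$unique_olc, 1L)
  expect_equal(ev$attribution$unique_short, 1L)
  expect_equal(ev$attribution$n_shared_some, 0L)
  # per-population source bookkeeping
  pops <- ev$populations
  expect_setequal(pops$unique_to[!is.na(pops$unique_to)],
                  c("hybrid", "hybrid", "olc", "short"))
})

test_that("colliding contig ids across assemblies are namespaced", {
  withr::local_seed(23)
  ctg <- make_contig("shared_name", rand_dna(6000))
  calls <- tibble::tibble(contig_id = "shared_name", category = 1L)
  assemblies <- list(x = list(contigs = ctg, calls = calls),
                     y = list(contigs = ctg, calls = calls))
  ev <- build_enhanced_virome(assemblies, empty_aln())
  expect_setequal(ev$members$member_id,
                  c("x:shared_name", "y:shared_name"))
})

test_that("rank abundance orders by depth per million reads with id ties", {
  members <- tibble::tibble(
    member_id = sprintf("p%03d", 1:100),
    rep_id = sprintf("p%03d", 1:100),
    member_length = rep(10000L, 100)
  )
  # equal depth on every population
  aln <- alignment_tbl(
    query_id = sprintf("sr%03d", 1:100),
    target_id = sprintf("p%03d", 1:100),
    query_len = 125L, target_len = 10000L,
    query_start = 0L, query_end = 125L,
    target_start = 0L, target_end = 125L,
    strand = "+", matches = 125L, block_len = 125L
  )
  ab <- rank_abundance(members, aln)
  expect_equal(ab$rank, 1:100)
  expect_equal(ab$rep_id, sort(members$rep_id))  # ties broken by id
  expect_equal(nrow(top_decile(ab)), 10L)
  # power-law abundances match an independent full sort
  withr::local_seed(29)
  aln2 <- aln[rep(1:100, times = round(1000 * (1:100)^-1.2)), ]
  ab2 <- rank_abundance(members, aln2)
  counts <- table(aln2$target_id)
  expected_order <- names(sort(-counts))
  expect_equal(ab2$rep_id[1:50], expected_order[1:50])
  # unmapped populations appear with zero abundance
  ab3 <- rank_abundance(members, aln[1:50, ])
  expect_true(all(ab3$abundance[ab3$rank > 50] == 0))
})

test_that("the top decile is floor(N/10) records", {
  ab <- tibble::tibble(rep_id = sprintf("p%04d", 1:5161),
                       abundance = runif(5161), rank = 1:5161)
  expect_equal(nrow(top_decile(ab)), 516L)
  expect_equal(nrow(top_decile(ab[1:9, ])), 0L)
})
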