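#' Filter read alignments by population mapping thresholds
#'
#' Retains alignments with identity `>= min_identity` and aligned query
#' fraction `>= min_read_coverage` - the standard read-recruitment rule used
#' to define viral populations (70% read coverage at 95% identity). Both are
#' inclusive (`>=`) boundaries.
#'
#' @param alignments Alignment tibble; needs `matches`, `block_len`,
#'   `query_start`, `query_end` and `query_len`.
#' @param min_identity Minimum `matches / block_len` (default 0.95).
#' @param min_read_coverage Minimum aligned fraction of the read
#'   (default 0.70).
#' @return The retained alignment rows.
#' @export
filter_read_alignments <- function(alignments, min_identity = 0.95,
                                   min_read_coverage = 0.70) {
  if (is.null(alignments[["query_len"]]) || anyNA(alignments$query_len)) {
    abort("alignments must carry query_len (read length)")
  }
  ident <- alignments$matches / alignments$block_len
  rcov <- (alignments$query_end - alignments$query_start) /
    alignments$query_len
  alignments[ident >= min_identity & rcov >= min_read_coverage, , drop = FALSE]
}

#' Select contigs qualifying as sampled viral populations
#'
#' A contig qualifies for microdiversity estimation when reads cover more
#' than `min_breadth` of its length and mean depth exceeds `min_depth` (both
#' strict `>`, matching the ">70% of length covered, >10x coverage" rule).
#' Breadth counts positions with at least one aligned base; mean depth is
#' total aligned bases over the whole contig length.
#'
#' @param contigs Contig tibble.
#' @param alignments Retained read alignments (see
#'   [filter_read_alignments()]) with CIGARs or plain intervals; aligned
#'   bases are approximated by target intervals when no CIGAR is present.
#' @param min_breadth Strict breadth threshold (default 0.70).
#' @param min_depth Strict mean-depth threshold (default 10).
#' @return One row per contig: `contig_id`, `length`, `breadth`,
#'   `mean_depth`, `selected`.
#' @export
select_populations <- function(contigs, alignments, min_breadth = 0.70,
                               min_depth = 10) {
  if (is.null(contigs[["length"]])) contigs$length <- nchar(contigs$sequence)
  purrr::map2(contigs$contig_id, contigs$length, function(cid, clen) {
    rows <- alignments[alignments$target_id == cid, , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(tibble(contig_id = cid, length = clen, breadth = 0,
                    mean_depth = 0, selected = FALSE))
    }
    ir <- IRanges::IRanges(start = rows$target_start + 1L,
                           end = pmin(rows$target_end, clen))
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    total_bases <- sum(rows$target_end - rows$target_start)
    breadth <- covered / clen
    mean_depth <- total_bases / clen
    tibble(contig_id = cid, length = clen, breadth = breadth,
           mean_depth = mean_depth,
           selected = breadth > min_breadth & mean_depth > min_depth)
  }) |> purrr::list_rbind()
}

#' Call SNPs from a pileup under the explicit truth rule
#'
#' Emits one call per (position, non-reference base with at least one count).
#' A call is a *true* SNP when the alternate base is supported by at least
#' `min_alt_count` reads **and** exceeds `min_alt_freq` of the position's
#' counted coverage. Base-quality filtering is assumed to have happened in
#' [build_pileup()]. Positions whose reference base is `N` are skipped;
#' multi-allelic positions yield one call per alternate base.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param reference One-row contig tibble with `sequence`.
#' @param min_alt_count Minimum supporting reads (default 4).
#' @param min_alt_freq Strict minimum alternate frequency (default 0.01).
#' @return A tibble: `contig_id`, `pos`, `ref`, `alt`, `alt_count`, `depth`,
#'   `alt_freq`, `is_true`.
#' @export
call_snps <- function(pileup, reference, min_alt_count = 4L,
                      min_alt_freq = 0.01) {
  refseq <- strsplit(reference$sequence[[1]], "", fixed = TRUE)[[1]]
  ref <- refseq[pileup$pos + 1L]
  keep <- ref %in% DNA_BASES
  pu <- pileup[keep, , drop = FALSE]
  ref <- ref[keep]
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(pu, ref = ref),
    cols = dplyr::all_of(DNA_BASES),
    names_to = "alt", values_to = "alt_count"
  ) |>
    filter(.data$alt != .data$ref, .data$alt_count > 0L) |>
    mutate(
      alt_freq = .data$alt_count / .data$depth,
      is_true = .data$alt_count >= min_alt_count &
        .data$alt_freq > min_alt_freq
    ) |>
    select("contig_id", "pos", "ref", "alt", "alt_count", "depth",
           "alt_freq", "is_true")
  long
}

#' Per-site nucleotide diversity from base counts
#'
#' Unbiased per-site heterozygosity: with coverage `C` and base frequencies
#' `f_b`, `pi_s = C/(C-1) * (1 - sum(f_b^2))`. Sites with coverage below 2
#' are undefined (`NA`).
#'
#' @param counts Numeric matrix or data frame with columns `A`, `C`, `G`,
#'   `T` (one row per site), or a vector of four counts.
#' @return Numeric vector of per-site pi values.
#' @export
site_pi <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  m <- as.matrix(as.data.frame(counts)[, DNA_BASES[DNA_BASES %in% colnames(counts)],
                                       drop = FALSE])
  if (ncol(m) != 4L) m <- as.matrix(as.data.frame(counts))
  C <- rowSums(m)
  pi <- ifelse(C >= 2, C / (C - 1) * (1 - rowSums((m / C)^2)), NA_real_)
  as.numeric(pi)
}

#' Per-contig microdiversity summary
#'
#' Computes per-site pi at every position carrying at least one true SNP and
#' summarises per contig with the median (default) or mean. Contigs with no
#' true SNPs report `pi = 0` rather than missing.
#'
#' @param contig One-row contig tibble.
#' @param pileup Pileup tibble for that contig.
#' @param snps SNP tibble from [call_snps()].
#' @param summary `"median"` (default) or `"mean"` over true-SNP sites.
#' @return A one-row tibble: `contig_id`, `n_true_snps`, `pi` (the summary),
#'   `pi_per_site` (list-column of per-site values), `breadth`, `mean_depth`.
#' @export
contig_microdiversity <- function(contig, pileup, snps,
                                  summary = c("median", "mean")) {
  summary <- match.arg(summary)
  cid <- contig$contig_id[[1]]
  clen <- contig_len1(contig)
  true_pos <- sort(unique(snps$pos[snps$is_true & snps$contig_id == cid]))
  pu <- pileup[pileup$contig_id == cid, , drop = FALSE]
  if (length(true_pos) > 0L) {
    cols <- pu[match(true_pos, pu$pos), , drop = FALSE]
    pis <- site_pi(cols[DNA_BASES])
    pis <- pis[!is.na(pis)]
  } else {
    pis <- numeric(0)
  }
  stat <- if (length(pis) == 0L) 0 else if (summary == "median") {
    stats::median(pis)
  } else {
    mean(pis)
  }
  tibble(
    contig_id = cid,
    n_true_snps = length(true_pos),
    pi = stat,
    pi_per_site = list(pis),
    breadth = sum(pu$depth > 0L) / clen,
    mean_depth = sum(pu$depth) / clen
  )
}

#' Compare microdiversity between groups of contigs
#'
#' Pairwise two-sided Mann-Whitney U tests on per-contig pi values, with the
#' effect direction (sign of the median difference).
#'
#' @param groups Named list of numeric vectors (per-contig pi per group).
#' @return A tibble with one row per unordered pair: `group_a`, `group_b`,
#'   `u`, `p_value`, `median_a`, `median_b`, `direction` (`"a>b"`, `"b>a"`,
#'   `"tie"`).
#' @export
compare_microdiversity <- function(groups) {
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty")
  if (any(lengths(groups) < 2L)) {
    warn("group of size < 2: p-values unreliable")
  }
  nm <- names(groups)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    res <- compare_lengths(groups[[p[1]]], groups[[p[2]]])
    ma <- res$median_a; mb <- res$median_b
    tibble(group_a = p[1], group_b = p[2], u = res$u, p_value = res$p_value,
           median_a = ma, median_b = mb,
           direction = dplyr::case_when(ma > mb ~ "a>b", mb > ma ~ "b>a",
                                        TRUE ~ "tie"))
  }) |> purrr::list_rbind()
}
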