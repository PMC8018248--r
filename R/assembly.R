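#' Contiguity statistics for an assembly
#'
#' N50 is the largest length `L` such that contigs of length `>= L` together
#' hold at least half of the assembly's bases.
#'
#' @param contigs Contig tibble (or numeric vector of lengths).
#' @return A one-row tibble: `n_contigs`, `total_bp`, `n50`, `max_len`.
#' @export
contig_stats <- function(contigs) {
  lens <- if (is.numeric(contigs)) contigs else {
    if (is.null(contigs[["length"]])) nchar(contigs$sequence) else contigs$length
  }
  if (length(lens) == 0L) abort("no contigs")
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  csum <- cumsum(lens)
  n50 <- lens[which(csum >= sum(lens) / 2)[1]]
  tibble(n_contigs = length(lens), total_bp = sum(lens), n50 = n50,
         max_len = lens[1])
}

#' Residual error profile of an assembly against a trusted reference
#'
#' Accumulates mismatches and indels over the supplied alignments (one
#' primary alignment per assembled region is assumed) and reports them per
#' 100 kbp of aligned sequence, plus a percent accuracy. Indels are counted
#' both as events and as bases: the per-100-kbp figure uses *events*
#' (matching the usual assembly-assessment convention), accuracy uses
#' *bases*. The denominator is aligned bases (matched columns), so unaligned
#' contig tails do not dilute the rates.
#'
#' @param alignments Alignment tibble of assembly contigs onto the reference.
#'   Counts are taken from `=\\X`-style CIGARs when present, else from the
#'   `mismatches`/`ins_*`/`del_*` columns.
#' @return A one-row tibble: `aligned_bases`, `mismatches`, `indel_events`,
#'   `indel_bases`, `mismatches_per_100kbp`, `indels_per_100kbp`,
#'   `accuracy_pct`.
#' @export
error_profile <- function(alignments) {
  if (nrow(alignments) == 0L) abort("no alignments")
  need <- c("mismatches", "ins_events", "ins_bases", "del_events", "del_bases")
  if (!all(need %in% names(alignments)) || anyNA(alignments$mismatches)) {
    counts <- cigar_counts(alignments$cigar)
    if (anyNA(counts$mismatches)) {
      abort("error_profile needs =/X CIGARs or explicit mismatch counts")
    }
    alignments[names(counts)] <- counts
  }
  aligned <- sum(alignments$matches + alignments$mismatches)
  mm <- sum(alignments$mismatches)
  iev <- sum(alignments$ins_events + alignments$del_events)
  ib <- sum(alignments$ins_bases + alignments$del_bases)
  tibble(
    aligned_bases = aligned,
    mismatches = mm,
    indel_events = iev,
    indel_bases = ib,
    mismatches_per_100kbp = 1e5 * mm / aligned,
    indels_per_100kbp = 1e5 * iev / aligned,
    accuracy_pct = 100 * (1 - (mm + ib) / aligned)
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' Simple six-frame ORF caller: within every stop-to-stop stretch of a frame,
#' the ORF runs from the first ATG to the in-frame stop (the stop codon is
#' required and excluded from the length). Reverse-strand ORFs are reported
#' in forward-strand coordinates (0-based half-open, stop codon excluded).
#' This is a deliberate simplification of a full gene caller: absolute length
#' medians are not comparable to model-based predictors, relative contrasts
#' are.
#'
#' @param contig One-row contig tibble (or a plain sequence string).
#' @param min_aa Minimum protein length in amino acids (default 30).
#' @return A tibble: `contig_id`, `start`, `end`, `strand`, `frame` (0-2 on
#'   each strand), `aa_len`.
#' @export
find_orfs <- function(contig, min_aa = 30L) {
  if (is.character(contig)) {
    contig <- tibble(contig_id = "contig", sequence = contig)
  }
  seqf <- toupper(contig$sequence[[1]])
  cid <- contig$contig_id[[1]]
  L <- nchar(seqf)
  seqr <- revcomp(seqf)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqf else seqr
    for (frame in 0:2) {
      orfs <- frame_orfs(s, frame)
      if (nrow(orfs) == 0L) next
      # orfs: codon-resolution start of ATG and start of stop (0-based on s)
      if (strand == "+") {
        start <- orfs$atg; end <- orfs$stop
      } else {
        start <- L - orfs$stop; end <- L - orfs$atg
      }
      res[[length(res) + 1L]] <- tibble(
        contig_id = cid, start = start, end = end, strand = strand,
        frame = frame, aa_len = (orfs$stop - orfs$atg) %/% 3L
      )
    }
  }
  out <- if (length(res)) purrr::list_rbind(res) else {
    tibble(contig_id = character(), start = integer(), end = integer(),
           strand = character(), frame = integer(), aa_len = integer())
  }
  out |> filter(.data$aa_len >= min_aa) |>
    arrange(.data$start, .data$end, .data$strand)
}

# ORFs in a single frame of a single strand; returns 0-based offsets of the
# ATG and of the stop codon's first base
frame_orfs <- function(s, frame) {
  L <- nchar(s)
  n_codons <- (L - frame) %/% 3L
  if (n_codons < 2L) return(tibble(atg = integer(), stop = integer()))
  starts <- frame + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts + 1L, starts + 3L)
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  stop_idx <- which(is_stop)
  if (length(stop_idx) == 0L) return(tibble(atg = integer(), stop = integer()))
  seg_start <- c(1L, utils::head(stop_idx, -1) + 1L)  # segment before each stop
  atg <- integer(0); stp <- integer(0)
  for (k in seq_along(stop_idx)) {
    if (stop_idx[k] == seg_start[k]) next              # empty segment
    rng <- seg_start[k]:(stop_idx[k] - 1L)
    hit <- rng[is_atg[rng]][1]
    if (!is.na(hit)) {
      atg <- c(atg, starts[hit])
      stp <- c(stp, starts[stop_idx[k]])
    }
  }
  tibble(atg = atg, stop = stp)
}

#' Summarise predicted protein lengths
#'
#' @param orfs ORF tibble from [find_orfs()] (possibly over many contigs).
#' @param min_aa Minimum length included in the summary.
#' @return A one-row tibble: `n_orfs`, `median_protein_aa`.
#' @export
orf_summary <- function(orfs, min_aa = 30L) {
  keep <- orfs$aa_len >= min_aa
  tibble(n_orfs = sum(keep),
         median_protein_aa = if (any(keep)) stats::median(orfs$aa_len[keep])
         else NA_real_)
}
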