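#' Parse a CIGAR string into operations
#'
#' @param cigar A single CIGAR string (`M`, `=`, `X`, `I`, `D`, `N`, `S`, `H`
#'   operations).
#' @return A tibble with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(tibble(op = character(), len = integer()))
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    abort(sprintf("malformed CIGAR: %s", cigar))
  }
  tibble(
    op = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1, nchar(toks) - 1L))
  )
}

# vectorised per-class counts for a character vector of CIGARs (NA allowed).
# Indels are counted both as events and as bases; mismatches require =/X ops
# (NA otherwise).
cigar_counts <- function(cigars) {
  n <- length(cigars)
  out <- tibble(
    matches = rep(NA_integer_, n), mismatches = rep(NA_integer_, n),
    ins_events = rep(NA_integer_, n), ins_bases = rep(NA_integer_, n),
    del_events = rep(NA_integer_, n), del_bases = rep(NA_integer_, n),
    aln_ref_len = rep(NA_integer_, n), aln_query_len = rep(NA_integer_, n),
    block_len = rep(NA_integer_, n)
  )
  idx <- which(!is.na(cigars) & nzchar(cigars))
  for (i in idx) {
    ops <- parse_cigar(cigars[i])
    s <- function(o) sum(ops$len[ops$op %in% o])
    e <- function(o) sum(ops$op %in% o)
    has_eq <- any(ops$op %in% c("=", "X"))
    out$matches[i] <- if (has_eq) s("=") else s(c("M", "="))
    out$mismatches[i] <- if (has_eq) s("X") else NA_integer_
    out$ins_events[i] <- e("I"); out$ins_bases[i] <- s("I")
    out$del_events[i] <- e("D"); out$del_bases[i] <- s("D")
    out$aln_ref_len[i] <- s(c("M", "=", "X", "D", "N"))
    out$aln_query_len[i] <- s(c("M", "=", "X", "I"))
    out$block_len[i] <- s(c("M", "=", "X", "I", "D"))
  }
  out
}

# Walk one CIGAR: return parallel vectors of reference positions and query
# positions (both 0-based) for every aligned (M/=/X) base. Query positions are
# in alignment orientation (i.e. along the possibly reverse-complemented read).
cigar_aligned_pairs <- function(cigar, target_start, query_aln_start = 0L) {
  ops <- parse_cigar(cigar)
  rp <- target_start
  qp <- query_aln_start
  ref_out <- vector("list", nrow(ops))
  qry_out <- vector("list", nrow(ops))
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      ref_out[[k]] <- seq.int(rp, length.out = len)
      qry_out[[k]] <- seq.int(qp, length.out = len)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    } # H consumes neither
  }
  list(ref = unlist(ref_out) %||% integer(), qry = unlist(qry_out) %||% integer())
}

#' Build a per-position base pileup for one contig
#'
#' Reimplements mpileup-style column construction from CIGAR-bearing
#' alignments: each aligned (`M`/`=`/`X`) read base whose base quality passes
#' `min_base_quality` contributes one count at its contig position. Deleted
#' positions contribute nothing; `N` read bases are never counted. For
#' `-`-strand alignments the read is reverse-complemented before the walk, so
#' counts are always in contig orientation.
#'
#' The default `min_base_quality = 20` carries the intent of a PHRED < 20
#' variant-quality filter down to the base level, since no external variant
#' caller is involved.
#'
#' @param alignments Alignment tibble with `cigar`; `target_id` must equal
#'   `contig_id` for every row.
#' @param reads Read tibble (`read_id`, `sequence`, `quality`) supplying
#'   bases; alternatively alignments may carry their own `seq`/`qual` columns
#'   (as from [read_sam()]), in which case `seq` is already in alignment
#'   orientation.
#' @param contig One-row contig tibble (or any list with `contig_id`,
#'   `length`).
#' @param min_base_quality Minimum Phred base quality for a base to count.
#' @return A pileup tibble: `contig_id`, `pos` (0-based), `A`, `C`, `G`, `T`,
#'   `depth`, one row per position with at least one counted base.
#' @export
build_pileup <- function(alignments, reads = NULL, contig,
                         min_base_quality = 20L) {
  cid <- contig$contig_id[[1]]
  clen <- as.integer(contig$length[[1]] %||% nchar(contig$sequence[[1]]))
  if (!all(alignments$target_id == cid)) {
    abort("all alignments must target the given contig")
  }
  if (any(is.na(alignments$cigar))) abort("build_pileup requires CIGARs")
  if (any(alignments$target_end > clen | alignments$target_start < 0L)) {
    abort("alignment exceeds contig bounds")
  }
  own_seq <- !is.null(alignments[["seq"]])
  if (!own_seq) {
    if (is.null(reads)) abort("supply `reads` or seq/qual columns")
    ridx <- match(alignments$query_id, reads$read_id)
    if (anyNA(ridx)) abort("alignment references unknown read id")
  }

  # fast path: gapless alignments (single M/= op spanning the query slice)
  simple <- grepl("^\\d+[M=]$", alignments$cigar)
  codes_fast <- integer(0)
  if (any(simple)) {
    al <- alignments[simple, , drop = FALSE]
    if (own_seq) {
      sq <- al$seq; ql <- al$qual
    } else {
      ri <- match(al$query_id, reads$read_id)
      sq <- substr(reads$sequence[ri], al$query_start + 1L, al$query_end)
      ql <- substr(reads$quality[ri], al$query_start + 1L, al$query_end)
      neg <- al$strand == "-"
      if (any(neg)) {
        sq[neg] <- revcomp(sq[neg])
        ql[neg] <- vapply(ql[neg], function(q) {
          intToUtf8(rev(utf8ToInt(q)))
        }, character(1), USE.NAMES = FALSE)
      }
    }
    lens <- nchar(sq)
    refpos <- sequence(lens, from = al$target_start)  # 0-based, vectorised
    bases <- unlist(strsplit(sq, "", fixed = TRUE), use.names = FALSE)
    quals <- unlist(lapply(ql, function(q) utf8ToInt(q) - 33L),
                    use.names = FALSE)
    bi <- match(bases, DNA_BASES)
    keep <- !is.na(bi) & quals >= min_base_quality
    codes_fast <- 4L * refpos[keep] + bi[keep]
    alignments <- alignments[!simple, , drop = FALSE]
    if (!own_seq) ridx <- match(alignments$query_id, reads$read_id)
  }

  codes <- vector("list", nrow(alignments))  # 4*pos + base, tallied at the end
  for (i in seq_len(nrow(alignments))) {
    if (own_seq) {
      # SAM-style: seq/qual already in alignment orientation and include any
      # soft-clipped bases (the S op advances the query pointer)
      sq <- alignments$seq[i]
      ql <- alignments$qual[i]
    } else {
      sq <- reads$sequence[ridx[i]]
      ql <- reads$quality[ridx[i]]
      qs <- alignments$query_start[i]; qe <- alignments$query_end[i]
      if (alignments$strand[i] == "-") {
        # alignment orientation: revcomp the aligned slice of the read
        sq <- revcomp(substr(sq, qs + 1L, qe))
        ql <- paste(rev(strsplit(substr(ql, qs + 1L, qe), "")[[1]]),
                    collapse = "")
      } else {
        sq <- substr(sq, qs + 1L, qe)
        ql <- substr(ql, qs + 1L, qe)
      }
    }
    pr <- cigar_aligned_pairs(alignments$cigar[i],
                              alignments$target_start[i], 0L)
    if (length(pr$ref) == 0L) next
    bases <- strsplit(sq, "", fixed = TRUE)[[1]][pr$qry + 1L]
    quals <- (utf8ToInt(ql) - 33L)[pr$qry + 1L]
    bi <- match(bases, DNA_BASES)           # N and gaps -> NA
    keep <- !is.na(bi) & quals >= min_base_quality
    if (any(keep)) codes[[i]] <- 4L * pr$ref[keep] + bi[keep]
  }

  tal <- tabulate(c(codes_fast, unlist(codes)), nbins = 4L * clen)
  mat <- matrix(tal, nrow = 4L)             # rows = A,C,G,T
  depth <- colSums(mat)
  pos <- which(depth > 0L) - 1L
  tibble(
    contig_id = cid, pos = as.integer(pos),
    A = mat[1L, pos + 1L], C = mat[2L, pos + 1L],
    G = mat[3L, pos + 1L], T = mat[4L, pos + 1L],
    depth = as.integer(depth[pos + 1L])
  )
}
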