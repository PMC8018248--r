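# Independent brute-force oracles and tiny fixture builders. These
# deliberately share no code with the package implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

const_qual <- function(q, n) strrep(intToUtf8(q + 33L), n)

empty_aln <- function() {
  alignment_tbl(character(), character(), integer(), integer(), integer(),
                integer(), integer(), integer(), character(), integer(),
                integer())[0, ]
}

# --- pileup oracle: scalar cigar walk, per-position tally ------------------

oracle_pileup <- function(alignments, reads, contig, min_bq) {
  clen <- nchar(contig$sequence[[1]])
  counts <- matrix(0L, nrow = clen, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    rd <- reads[reads$read_id == a$query_id, ]
    sq <- substr(rd$sequence, a$query_start + 1, a$query_end)
    ql <- substr(rd$quality, a$query_start + 1, a$query_end)
    if (a$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      sq <- paste(rev(unname(comp[strsplit(sq, "")[[1]]])), collapse = "")
      ql <- paste(rev(strsplit(ql, "")[[1]]), collapse = "")
    }
    sqc <- strsplit(sq, "")[[1]]
    qlc <- utf8ToInt(ql) - 33L
    # scalar walk
    ops <- regmatches(a$cigar, gregexpr("\\d+[MIDNSHP=X]", a$cigar))[[1]]
    rp <- a$target_start
    qp <- 0L
    for (tok in ops) {
      len <- as.integer(sub("[A-Z=]", "", tok))
      op <- sub("\\d+", "", tok)
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          b <- sqc[qp + k]
          if (b %in% c("A", "C", "G", "T") && qlc[qp + k] >= min_bq) {
            counts[rp + k, b] <- counts[rp + k, b] + 1L
          }
        }
        rp <- rp + len; qp <- qp + len
      } else if (op %in% c("D", "N")) {
        rp <- rp + len
      } else if (op %in% c("I", "S")) {
        qp <- qp + len
      }
    }
  }
  counts
}

# --- merged-interval coverage oracle ---------------------------------------

oracle_covered_bp <- function(starts, ends, len) {
  hit <- logical(len)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) hit[(starts[k] + 1):min(ends[k], len)] <- TRUE
  }
  sum(hit)
}

# --- greedy dereplication oracle -------------------------------------------

oracle_pair_sim <- function(id_a, id_b, lens, alignments) {
  rows <- alignments[
    (alignments$query_id == id_a & alignments$target_id == id_b) |
    (alignments$query_id == id_b & alignments$target_id == id_a), ,
    drop = FALSE]
  if (nrow(rows) == 0) return(c(0, 0))
  shorter <- if (lens[id_a] <= lens[id_b]) id_a else id_b
  hit <- logical(lens[shorter])
  for (k in seq_len(nrow(rows))) {
    s <- if (rows$query_id[k] == shorter) rows$query_start[k] else rows$target_start[k]
    e <- if (rows$query_id[k] == shorter) rows$query_end[k] else rows$target_end[k]
    if (e > s) hit[(s + 1):e] <- TRUE
  }
  ident <- sum(rows$matches) / sum(rows$block_len)  # block-weighted mean
  c(ident, sum(hit) / lens[shorter])
}

oracle_greedy_derep <- function(contigs, alignments, min_id = 0.95,
                                min_cov = 0.70) {
  ord <- order(-contigs$length, contigs$contig_id)
  ids <- contigs$contig_id[ord]
  lens <- setNames(contigs$length, contigs$contig_id)
  reps <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (r in reps) {
      s <- oracle_pair_sim(id, r, lens, alignments)
      if (s[1] >= min_id && s[2] >= min_cov) {
        assign[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- id
    }
  }
  assign
}

# --- Mann-Whitney enumeration oracle ---------------------------------------

oracle_mwu_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  obs <- oracle_mwu_u(a, b)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) oracle_mwu_u(pooled[ii], pooled[-ii]))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# --- six-frame ORF oracle: positionwise scan -------------------------------

oracle_orf_lengths <- function(seq, min_aa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(unname(comp[strsplit(seq, "")[[1]]])), collapse = "")
  lens <- integer(0)
  for (s in c(seq, rc)) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    for (f in 0:2) {
      atg_pending <- NA_integer_
      p <- f
      while (p + 3 <= L) {
        codon <- paste(ch[(p + 1):(p + 3)], collapse = "")
        if (codon %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(atg_pending)) {
            aa <- (p - atg_pending) / 3
            if (aa >= min_aa) lens <- c(lens, aa)
          }
          atg_pending <- NA_integer_
        } else if (codon == "ATG" && is.na(atg_pending)) {
          atg_pending <- p
        }
        p <- p + 3
      }
    }
  }
  sort(lens)
}

# --- small helpers ---------------------------------------------------------

make_read <- function(id, seq, q = 30L, library = "lib") {
  tibble::tibble(read_id = id, sequence = seq,
                 quality = const_qual(q, nchar(seq)),
                 length = nchar(seq), library = library)
}

make_contig <- function(id, seq) {
  tibble::tibble(contig_id = id, sequence = seq, length = nchar(seq))
}

# simple full-match alignment of a read slice onto a contig
full_match_aln <- function(read, contig, target_start, strand = "+") {
  n <- read$length
  alignment_tbl(
    query_id = read$read_id, target_id = contig$contig_id,
    query_len = n, target_len = contig$length,
    query_start = 0L, query_end = n,
    target_start = target_start, target_end = target_start + n,
    strand = strand, matches = n, block_len = n, cigar = paste0(n, "M")
  )
}
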