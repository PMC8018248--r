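#' Simulate phage-like genomes
#'
#' I.i.d. bases at a per-genome GC fraction; genome sizes and GC defaults
#' emulate a small dsDNA phage mock community (tens to ~130 kbp, GC around
#' 36-45%).
#'
#' @param n_genomes Number of genomes.
#' @param length_range Length range in bp (uniform), or use `lengths` for
#'   exact sizes.
#' @param gc_range GC-fraction range (uniform per genome).
#' @param lengths Optional exact genome lengths (overrides `length_range`).
#' @param seed Integer seed (mandatory; generation is fully deterministic).
#' @return A genome tibble: `genome_id`, `sequence`, `length`, `gc`.
#' @export
sim_genomes <- function(n_genomes = 3L, length_range = c(38200L, 129400L),
                        gc_range = c(0.357, 0.447), lengths = NULL, seed) {
  with_seed(seed, {
    lens <- if (!is.null(lengths)) as.integer(lengths) else {
      as.integer(round(stats::runif(n_genomes, length_range[1], length_range[2])))
    }
    gc <- stats::runif(n_genomes, gc_range[1], gc_range[2])
    seqs <- purrr::map2_chr(lens, gc, function(L, g) {
      paste(sample(DNA_BASES, L, replace = TRUE,
                   prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
            collapse = "")
    })
    tibble(genome_id = sprintf("genome_%02d", seq_len(n_genomes)),
           sequence = seqs, length = lens, gc = gc)
  })
}

#' Derive a strain variant of a genome
#'
#' Plants `n_sites` substitution SNPs (no indels) at distinct positions; the
#' strain's population frequency is recorded for read sampling.
#'
#' @param genome One-row genome tibble.
#' @param minor_freq Population frequency of the variant strain, in (0, 0.5].
#' @param n_sites Number of variant sites.
#' @param seed Integer seed.
#' @return A list: `sequence` (variant genome string) and `snps` tibble
#'   (`pos` 0-based, `ref`, `alt`, `freq`).
#' @export
sim_strain <- function(genome, minor_freq = 0.1, n_sites = 40L, seed) {
  s <- genome$sequence[[1]]
  L <- nchar(s)
  if (n_sites > L) abort("n_sites exceeds genome length")
  with_seed(seed, {
    pos <- sort(sample.int(L, n_sites)) - 1L
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ref <- chars[pos + 1L]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    chars[pos + 1L] <- alt
    list(sequence = paste(chars, collapse = ""),
         snps = tibble(pos = pos, ref = ref, alt = alt, freq = minor_freq))
  })
}

# substitution/insertion/deletion errors on a character vector; single-base
# events at the given per-base probabilities
apply_seq_errors <- function(chars, sub_rate, ins_rate, del_rate) {
  L <- length(chars)
  if (L == 0L) return(list(chars = chars, n_sub = 0L))
  r <- stats::runif(L)
  is_del <- r < del_rate
  is_sub <- !is_del & r < del_rate + sub_rate
  if (any(is_sub)) {
    old <- chars[is_sub]
    pick <- sample.int(3L, sum(is_sub), replace = TRUE)
    chars[is_sub] <- vapply(seq_along(old), function(i) {
      setdiff(DNA_BASES, old[i])[pick[i]]
    }, character(1))
  }
  kept <- chars[!is_del]
  n1 <- length(kept)
  ins_here <- stats::runif(n1) < ins_rate
  if (any(ins_here)) {
    k <- sum(ins_here)
    newbase <- sample(DNA_BASES, k, replace = TRUE)
    shift <- cumsum(ins_here)
    # inserted base goes immediately before the base it was drawn with
    out <- character(n1 + k)
    out[seq_len(n1) + shift] <- kept
    out[which(ins_here) + shift[ins_here] - 1L] <- newbase
    kept <- out
  }
  list(chars = kept, n_sub = sum(is_sub))
}

# extract a (possibly wrapped) fragment from a genome string
fragment_seq <- function(genome_seq, start, len, circular) {
  L <- nchar(genome_seq)
  if (start + len <= L) {
    substr(genome_seq, start + 1L, start + len)
  } else if (circular) {
    paste0(substr(genome_seq, start + 1L, L),
           substr(genome_seq, 1L, start + len - L))
  } else {
    abort("fragment exceeds linear genome")
  }
}

#' Simulate error-bearing long reads with optional chimeras
#'
#' Fragment starts are uniform on the (circular by default) genomes; lengths
#' are log-normal with the given median; strands are random. Per-base
#' substitution/insertion/deletion errors use an indel-dominated
#' Nanopore-like default profile. With probability `chimera_rate`, a read is
#' the concatenation of two independent fragments - the PCR-chimera artifact.
#' Truth records use pre-error coordinates.
#'
#' @param genomes Genome tibble from [sim_genomes()].
#' @param n_reads Number of reads.
#' @param read_median_bp Median read length target.
#' @param read_len_sd_log Log-scale SD of the length distribution.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities (defaults
#'   0.01/0.02/0.03).
#' @param chimera_rate Fraction of reads formed as two-fragment chimeras.
#' @param abundance Optional genome sampling weights (default uniform).
#' @param circular Treat genomes as circular (default TRUE; phage genomes).
#' @param q_mean Mean read quality used to draw Phred scores.
#' @param library Library tag.
#' @param seed Integer seed.
#' @return A list: `reads` (read tibble) and `truth` (one row per fragment:
#'   `read_id`, `part`, `is_chimera`, `genome_id`, `strand`, `genome_start`,
#'   `genome_end` unwrapped (may exceed genome length on circular wrap),
#'   `read_start`, `read_end` pre-error, `junction` read coordinate for
#'   chimeras).
#' @export
sim_long_reads <- function(genomes, n_reads, read_median_bp = 7000L,
                           read_len_sd_log = 0.55, sub_rate = 0.01,
                           ins_rate = 0.02, del_rate = 0.03,
                           chimera_rate = 0, abundance = NULL,
                           circular = TRUE, q_mean = 12, library = "sim",
                           seed) {
  w <- abundance %||% rep(1, nrow(genomes))
  with_seed(seed, {
    is_chim <- stats::runif(n_reads) < chimera_rate
    n_frags <- ifelse(is_chim, 2L, 1L)
    total <- sum(n_frags)
    gi <- sample.int(nrow(genomes), total, replace = TRUE, prob = w)
    gl <- genomes$length[gi]
    flen <- pmin(pmax(as.integer(round(stats::rlnorm(
      total, log(read_median_bp), read_len_sd_log))), 200L),
      if (circular) gl else pmax(gl - 1L, 200L))
    fstart <- if (circular) {
      as.integer(floor(stats::runif(total, 0, gl)))
    } else {
      as.integer(floor(stats::runif(total, 0, gl - flen + 1)))
    }
    fstrand <- sample(c("+", "-"), total, replace = TRUE)
    fseq <- vapply(seq_len(total), function(k) {
      fragment_seq(genomes$sequence[gi[k]], fstart[k], flen[k], circular)
    }, character(1))
    neg <- fstrand == "-"
    if (any(neg)) fseq[neg] <- revcomp(fseq[neg])

    read_of <- rep(seq_len(n_reads), n_frags)
    part <- unlist(lapply(n_frags, seq_len))
    ids <- sprintf("read_%06d", seq_len(n_reads))

    # pre-error read coordinates of each fragment
    read_start <- integer(total)
    off <- integer(n_reads)
    for (k in seq_len(total)) {
      read_start[k] <- off[read_of[k]]
      off[read_of[k]] <- off[read_of[k]] + flen[k]
    }

    pre_seq <- unname(vapply(split(fseq, read_of), paste, character(1),
                             collapse = ""))
    noisy <- pre_seq
    if (sub_rate + ins_rate + del_rate > 0) {
      noisy <- vapply(pre_seq, function(s) {
        paste(apply_seq_errors(strsplit(s, "", fixed = TRUE)[[1]],
                               sub_rate, ins_rate, del_rate)$chars,
              collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    rq <- pmin(pmax(round(stats::rnorm(n_reads, q_mean, 2)), 2L), 40L)
    reads <- tibble(
      read_id = ids,
      sequence = noisy,
      quality = stringr::str_dup(vapply(rq, function(q) intToUtf8(q + 33L),
                                        character(1)), nchar(noisy)),
      length = nchar(noisy),
      library = library
    )
    truth <- tibble(
      read_id = ids[read_of], part = part,
      is_chimera = is_chim[read_of],
      genome_id = genomes$genome_id[gi],
      strand = fstrand,
      genome_start = fstart, genome_end = fstart + flen,
      read_start = read_start, read_end = read_start + flen,
      junction = ifelse(is_chim[read_of],
                        rep(tapply(flen, read_of, function(x) x[1])[
                          as.character(seq_len(n_reads))], n_frags),
                        NA_integer_)
    )
    list(reads = reads, truth = truth)
  })
}

#' Derive all-vs-all read overlaps from simulation truth
#'
#' Projects genuine genomic overlaps between fragments onto read coordinates
#' so chimera detection can run without an external aligner. A fixed margin
#' (`end_trim`) is removed from both ends of every overlap, emulating local
#' alignments failing to extend across sequence breakpoints - this is what
#' makes chimeric junctions visible as coverage gaps.
#'
#' @param truth Truth tibble from [sim_long_reads()].
#' @param genomes Genome tibble (for lengths / circular wrap).
#' @param end_trim Margin trimmed from each overlap end (default 250 bp).
#' @param min_overlap_bp Minimum genomic overlap before trimming.
#' @param circular Genomes are circular (default TRUE).
#' @return An alignment tibble of read-vs-read overlaps (each unordered pair
#'   once).
#' @export
sim_read_overlaps <- function(truth, genomes, end_trim = 250L,
                              min_overlap_bp = 500L, circular = TRUE) {
  read_len <- truth |>
    group_by(.data$read_id) |>
    summarise(len = max(.data$read_end), .groups = "drop")
  rl <- stats::setNames(read_len$len, read_len$read_id)
  out <- vector("list", nrow(genomes))
  for (g in seq_len(nrow(genomes))) {
    L <- genomes$length[g]
    rec <- truth[truth$genome_id == genomes$genome_id[g], , drop = FALSE]
    n <- nrow(rec)
    if (n < 2L) next
    pr <- expand.grid(i = seq_len(n), j = seq_len(n))
    pr <- pr[pr$i < pr$j, , drop = FALSE]
    pr <- pr[rec$read_id[pr$i] != rec$read_id[pr$j], , drop = FALSE]
    if (nrow(pr) == 0L) next
    shifts <- if (circular) c(-L, 0L, L) else 0L
    hits <- list()
    for (k in shifts) {
      os <- pmax(rec$genome_start[pr$i], rec$genome_start[pr$j] + k)
      oe <- pmin(rec$genome_end[pr$i], rec$genome_end[pr$j] + k)
      ok <- (oe - os) >= min_overlap_bp
      if (!any(ok)) next
      hits[[length(hits) + 1L]] <-
        project_overlaps(rec, pr[ok, , drop = FALSE], os[ok], oe[ok], k,
                         end_trim, rl)
    }
    out[[g]] <- if (length(hits)) purrr::list_rbind(hits) else NULL
  }
  res <- purrr::list_rbind(out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) {
    return(alignment_tbl(character(), character(), integer(), integer(),
                         integer(), integer(), integer(), integer(),
                         character(), integer(), integer())[0, ])
  }
  res
}

# project genomic overlap [os, oe) onto both fragments' read coordinates
project_overlaps <- function(rec, pr, os, oe, shift, end_trim, rl) {
  proj <- function(idx, s, e) {
    gs <- rec$genome_start[idx]; ge <- rec$genome_end[idx]
    ro <- rec$read_start[idx]
    fwd <- rec$strand[idx] == "+"
    start <- ifelse(fwd, ro + (s - gs), ro + (ge - e))
    end <- ifelse(fwd, ro + (e - gs), ro + (ge - s))
    cbind(start, end)
  }
  a <- proj(pr$i, os, oe)
  b <- proj(pr$j, os - shift, oe - shift)
  a[, 1] <- a[, 1] + end_trim; a[, 2] <- a[, 2] - end_trim
  b[, 1] <- b[, 1] + end_trim; b[, 2] <- b[, 2] - end_trim
  keep <- a[, 2] - a[, 1] > 0L
  if (!any(keep)) return(NULL)
  qa <- rec$read_id[pr$i][keep]; qb <- rec$read_id[pr$j][keep]
  len <- (a[keep, 2] - a[keep, 1])
  alignment_tbl(
    query_id = qa, target_id = qb,
    query_len = unname(rl[qa]), target_len = unname(rl[qb]),
    query_start = a[keep, 1], query_end = a[keep, 2],
    target_start = b[keep, 1], target_end = b[keep, 2],
    strand = ifelse(rec$strand[pr$i][keep] == rec$strand[pr$j][keep],
                    "+", "-"),
    matches = len, block_len = len
  )
}

#' Simulate paired-end short reads, optionally from a strain mixture
#'
#' Inserts are placed uniformly on the (linear) genome; mates of
#' `read_len` bases come from opposite strands of each insert. Errors are
#' substitution-only. When a strain variant is supplied, each insert is drawn
#' from the variant haplotype with probability `minor_freq`, so alternate
#' alleles appear at their population frequency. Truth alignments (full-match
#' CIGARs, pre-error coordinates) are returned alongside.
#'
#' @param genome One-row genome tibble (the reference haplotype).
#' @param depth Target mean coverage.
#' @param read_len Read length (default 125, paired).
#' @param insert_mean,insert_sd Insert size distribution.
#' @param sub_rate Per-base substitution error rate.
#' @param strain Optional result of [sim_strain()].
#' @param minor_freq Probability an insert comes from the strain haplotype.
#' @param q_const Constant per-base Phred quality (default 30).
#' @param seed Integer seed.
#' @return A list: `reads` (read tibble), `alignments` (truth alignment
#'   tibble incl. `matches` reduced by planted errors) and `n_pairs`.
#' @export
sim_short_reads <- function(genome, depth = 50, read_len = 125L,
                            insert_mean = 400L, insert_sd = 40L,
                            sub_rate = 0, strain = NULL, minor_freq = 0,
                            q_const = 30L, seed) {
  gseq <- genome$sequence[[1]]
  L <- nchar(gseq)
  gid <- genome$genome_id[[1]]
  n_pairs <- as.integer(round(depth * L / (2 * read_len)))
  with_seed(seed, {
    ins_len <- pmin(pmax(as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                                       insert_sd))),
                         read_len), L)
    s <- as.integer(floor(stats::runif(n_pairs, 0, L - ins_len + 1)))
    e <- s + ins_len
    from_minor <- if (!is.null(strain)) stats::runif(n_pairs) < minor_freq
                  else rep(FALSE, n_pairs)
    hap <- ifelse(from_minor, strain$sequence %||% gseq, gseq)
    r1 <- substr(hap, s + 1L, s + read_len)
    r2 <- revcomp(substr(hap, e - read_len + 1L, e))
    seqs <- c(r1, r2)
    n_sub <- integer(2L * n_pairs)
    if (sub_rate > 0) {
      m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = read_len)
      err <- matrix(stats::runif(length(m)) < sub_rate, nrow = read_len)
      if (any(err)) {
        old <- m[err]
        pick <- sample.int(3L, sum(err), replace = TRUE)
        m[err] <- vapply(seq_along(old), function(i) {
          setdiff(DNA_BASES, old[i])[pick[i]]
        }, character(1))
      }
      n_sub <- as.integer(colSums(err))
      seqs <- do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
    }
    ids <- c(sprintf("pair_%06d/1", seq_len(n_pairs)),
             sprintf("pair_%06d/2", seq_len(n_pairs)))
    qual <- strrep(intToUtf8(q_const + 33L), read_len)
    reads <- tibble(read_id = ids, sequence = seqs, quality = qual,
                    length = read_len, library = "short")
    aln <- alignment_tbl(
      query_id = ids, target_id = gid,
      query_len = read_len, target_len = L,
      query_start = 0L, query_end = read_len,
      target_start = c(s, e - read_len), target_end = c(s + read_len, e),
      strand = rep(c("+", "-"), each = n_pairs),
      matches = read_len - n_sub, block_len = read_len,
      cigar = paste0(read_len, "M")
    )
    list(reads = reads, alignments = aln, n_pairs = n_pairs)
  })
}

#' Simulate a QC test library with planted filter violations
#'
#' Builds reads around the trim/length/quality rule and records ground truth
#' by applying the rule's arithmetic (trim first, then post-trim length and
#' mean quality) to each constructed read.
#'
#' @param n_reads Number of reads (default 1000).
#' @param trim_leading_bases,min_length_bp,min_mean_q Rule parameters the
#'   truth labels are computed against.
#' @param seed Integer seed.
#' @return A list: `reads` and `truth` tibble (`read_id`, `keep`, `reason`
#'   in `"length"`/`"quality"`/`NA`).
#' @export
sim_qc_library <- function(n_reads = 1000L, trim_leading_bases = 50L,
                           min_length_bp = 1000L, min_mean_q = 9, seed) {
  with_seed(seed, {
    kind <- sample(c("keep", "short", "lowq", "edge"), n_reads,
                   replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
    post_len <- dplyr::case_when(
      kind == "short" ~ sample(100:999, n_reads, replace = TRUE),
      kind == "edge" ~ sample(980:1020, n_reads, replace = TRUE),
      TRUE ~ sample(1000:8000, n_reads, replace = TRUE)
    )
    raw_len <- post_len + trim_leading_bases
    q0 <- dplyr::case_when(
      kind == "lowq" ~ stats::runif(n_reads, 4, 8.5),
      kind == "edge" ~ stats::runif(n_reads, 8.2, 9.8),
      TRUE ~ stats::runif(n_reads, 10, 20)
    )
    ids <- sprintf("qcread_%04d", seq_len(n_reads))
    seqs <- vapply(raw_len, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    quals <- character(n_reads)
    keep <- logical(n_reads)
    reason <- rep(NA_character_, n_reads)
    for (i in seq_len(n_reads)) {
      q <- pmin(pmax(round(stats::rnorm(raw_len[i], q0[i], 1.5)), 0L), 40L)
      quals[i] <- int_to_phred(q)
      post_q <- q[(trim_leading_bases + 1L):raw_len[i]]
      if (post_len[i] < min_length_bp) {
        reason[i] <- "length"
      } else if (mean(post_q) < min_mean_q) {
        reason[i] <- "quality"
      } else {
        keep[i] <- TRUE
      }
    }
    list(
      reads = tibble(read_id = ids, sequence = seqs, quality = quals,
                     length = raw_len, library = "qc_sim"),
      truth = tibble(read_id = ids, keep = keep, reason = reason)
    )
  })
}

#' Simulate a related-contig set with truth alignments
#'
#' Contigs are partial, lightly diverged copies of a handful of ancestor
#' sequences; alignments between contigs sharing an ancestor are emitted
#' directly from the designed coordinates and identities (no aligner). Useful
#' for exercising dereplication.
#'
#' @param n_contigs Number of contigs.
#' @param n_ancestors Number of ancestor sequences (default
#'   `max(2, n_contigs %/% 3)`).
#' @param len_range Ancestor length range in bp.
#' @param seed Integer seed.
#' @return A list: `contigs` (ids and lengths), `alignments`.
#' @export
sim_contig_set <- function(n_contigs, n_ancestors = NULL,
                           len_range = c(6000L, 20000L), seed) {
  n_anc <- n_ancestors %||% max(2L, n_contigs %/% 3L)
  with_seed(seed, {
    anc_len <- as.integer(round(stats::runif(n_anc, len_range[1], len_range[2])))
    anc <- sample.int(n_anc, n_contigs, replace = TRUE)
    frac <- stats::runif(n_contigs, 0.35, 1)
    clen <- as.integer(round(frac * anc_len[anc]))
    off <- as.integer(floor(stats::runif(n_contigs, 0,
                                         anc_len[anc] - clen + 1)))
    ident <- stats::runif(n_contigs, 0.95, 0.999)  # per-copy identity to ancestor
    contigs <- tibble(
      contig_id = sprintf("ctg_%03d", seq_len(n_contigs)),
      length = clen
    )
    rows <- list()
    for (i in seq_len(n_contigs - 1L)) {
      for (j in (i + 1L):n_contigs) {
        if (anc[i] != anc[j]) next
        os <- max(off[i], off[j]); oe <- min(off[i] + clen[i], off[j] + clen[j])
        if (oe - os < 500L) next
        o <- oe - os
        pid <- ident[i] * ident[j]
        rows[[length(rows) + 1L]] <- alignment_tbl(
          query_id = contigs$contig_id[i], target_id = contigs$contig_id[j],
          query_len = clen[i], target_len = clen[j],
          query_start = os - off[i], query_end = oe - off[i],
          target_start = os - off[j], target_end = oe - off[j],
          matches = as.integer(round(pid * o)), block_len = o
        )
      }
    }
    aln <- if (length(rows)) purrr::list_rbind(rows) else
      alignment_tbl(character(), character(), integer(), integer(),
                    integer(), integer(), integer(), integer(), character(),
                    integer(), integer())[0, ]
    list(contigs = contigs, alignments = aln)
  })
}

#' Simulate a multi-assembly virome with designed population overlap
#'
#' Builds one contig set per assembly label such that each designed
#' population appears in a known subset of assemblies, plus decoy contigs
#' that the viral-contig filter must drop (too short, or non-viral VirSorter
#' categories). Cross-assembly alignments between copies of the same
#' population are emitted from truth at high identity and full coverage.
#'
#' @param design A tibble with columns `population` (id) and `present`
#'   (list-column of assembly labels), or NULL for the default 10-population
#'   design over labels `short`, `hybrid`, `olc`: 6 populations in all
#'   three, 2 hybrid-only, 1 olc-only, 1 short-only.
#' @param seed Integer seed.
#' @return A list: `assemblies` (named list of `contigs` + `calls`),
#'   `alignments`, `design`.
#' @export
sim_virome_assemblies <- function(design = NULL, seed) {
  if (is.null(design)) {
    design <- tibble(
      population = sprintf("pop_%02d", 1:10),
      present = c(rep(list(c("short", "hybrid", "olc")), 6),
                  rep(list("hybrid"), 2), list("olc"), list("short"))
    )
  }
  labels <- sort(unique(unlist(design$present)))
  with_seed(seed, {
    plen <- as.integer(round(stats::runif(nrow(design), 8000, 30000)))
    pseq <- vapply(plen, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    assemblies <- stats::setNames(
      lapply(labels, function(l) list(contigs = NULL, calls = NULL)), labels)
    aln_rows <- list()
    copy_ids <- list()
    for (p in seq_len(nrow(design))) {
      present <- design$present[[p]]
      ids <- sprintf("%s_ctg_%s", present, design$population[p])
      copy_ids[[p]] <- stats::setNames(ids, present)
      for (ii in seq_along(present)) {
        l <- present[ii]
        # lightly diverged full-length copy
        chars <- strsplit(pseq[p], "", fixed = TRUE)[[1]]
        nm <- max(1L, round(0.005 * plen[p]))
        at <- sample.int(plen[p], nm)
        chars[at] <- vapply(chars[at], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
        ctg <- tibble(contig_id = ids[ii],
                      sequence = paste(chars, collapse = ""),
                      length = plen[p])
        cat_ <- sample(c(1L, 2L, 4L, 5L), 1L)
        assemblies[[l]]$contigs <- bind_rows(assemblies[[l]]$contigs, ctg)
        assemblies[[l]]$calls <- bind_rows(
          assemblies[[l]]$calls, tibble(contig_id = ids[ii], category = cat_))
      }
      if (length(present) > 1L) {
        cmb <- utils::combn(seq_along(present), 2)
        for (k in seq_len(ncol(cmb))) {
          i <- cmb[1, k]; j <- cmb[2, k]
          aln_rows[[length(aln_rows) + 1L]] <- alignment_tbl(
            query_id = ids[i], target_id = ids[j],
            query_len = plen[p], target_len = plen[p],
            query_start = 0L, query_end = plen[p],
            target_start = 0L, target_end = plen[p],
            matches = as.integer(round(0.99 * plen[p])), block_len = plen[p]
          )
        }
      }
    }
    # decoys per assembly: short viral, sub-input-length, non-viral category
    for (l in labels) {
      dec <- tibble(
        contig_id = paste0(l, c("_decoy_shortviral", "_decoy_tiny",
                                "_decoy_nonviral")),
        sequence = vapply(c(4000L, 2000L, 9000L), function(L) {
          paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
        }, character(1)),
        length = c(4000L, 2000L, 9000L)
      )
      calls <- tibble(contig_id = dec$contig_id, category = c(1L, 1L, 3L))
      assemblies[[l]]$contigs <- bind_rows(assemblies[[l]]$contigs, dec)
      assemblies[[l]]$calls <- bind_rows(assemblies[[l]]$calls, calls)
    }
    list(assemblies = assemblies,
         alignments = purrr::list_rbind(aln_rows),
         design = design)
  })
}

#' Plant exact substitutions and single-base indels into a reference copy
#'
#' Produces a mutated copy of a reference sequence together with the exact
#' truth alignment (CIGAR using `=`/`X`/`I`/`D`), for error-profile
#' exactness checks.
#'
#' @param reference One-row contig tibble.
#' @param n_sub,n_ins,n_del Numbers of substitutions, single-base insertions
#'   and single-base deletions.
#' @param margin Keep events at least this far from the sequence ends.
#' @param seed Integer seed.
#' @return A list: `contig` (mutated copy tibble) and `alignment` (one-row
#'   truth alignment tibble with CIGAR).
#' @export
sim_mutated_copy <- function(reference, n_sub = 0L, n_ins = 0L, n_del = 0L,
                             margin = 100L, seed) {
  s <- reference$sequence[[1]]
  L <- nchar(s)
  n_ev <- n_sub + n_ins + n_del
  with_seed(seed, {
    # distinct, separated event positions (ref coordinate, 0-based)
    pos <- sort(sample(seq.int(margin, L - margin - 1L, by = 2L), n_ev))
    type <- sample(rep(c("X", "I", "D"), c(n_sub, n_ins, n_del)))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    cig <- character(0)
    prev <- 0L
    for (k in seq_len(n_ev)) {
      p <- pos[k]
      if (p > prev) {
        out <- c(out, chars[(prev + 1L):p])
        cig <- c(cig, paste0(p - prev, "="))
      }
      if (type[k] == "X") {
        out <- c(out, sample(setdiff(DNA_BASES, chars[p + 1L]), 1L))
        cig <- c(cig, "1X")
        prev <- p + 1L
      } else if (type[k] == "I") {
        out <- c(out, sample(DNA_BASES, 1L), chars[p + 1L])
        cig <- c(cig, "1I", "1=")
        prev <- p + 1L
      } else {
        cig <- c(cig, "1D")
        prev <- p + 1L
      }
    }
    if (prev < L) {
      out <- c(out, chars[(prev + 1L):L])
      cig <- c(cig, paste0(L - prev, "="))
    }
    mut <- paste(out, collapse = "")
    cigar <- paste(cig, collapse = "")
    cc <- cigar_counts(cigar)
    contig <- tibble(contig_id = paste0(reference$contig_id[[1]], "_mut"),
                     sequence = mut, length = nchar(mut))
    aln <- alignment_tbl(
      query_id = contig$contig_id, target_id = reference$contig_id[[1]],
      query_len = nchar(mut), target_len = L,
      query_start = 0L, query_end = nchar(mut),
      target_start = 0L, target_end = L,
      matches = cc$matches, block_len = cc$block_len, cigar = cigar
    )
    list(contig = contig, alignment = aln)
  })
}
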