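#' Read a FASTA file into a contig tibble
#'
#' Sequences are uppercased; ids must be unique. Gzip-compressed files are
#' handled transparently.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `sequence`, `length`,
#'   `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0L) abort(sprintf("no FASTA records in %s", path))
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  stop_if_dup_ids(ids, "contig")
  tibble(
    contig_id = ids,
    sequence = unname(toupper(as.character(ss))),
    length = Biostrings::width(ss),
    description = desc
  )
}

#' Write a contig tibble to FASTA
#'
#' @param contigs Tibble with `contig_id` and `sequence` (optional
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(contigs$sequence)
  nm <- contigs$contig_id
  if (!is.null(contigs[["description"]])) {
    has <- nzchar(contigs$description)
    nm[has] <- paste(nm[has], contigs$description[has])
  }
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a long-read tibble
#'
#' Qualities are decoded from Phred+33 and kept as the encoded string in the
#' `quality` column (see [phred_to_int()]). Gzip is handled transparently.
#'
#' @param path Path to a FASTQ file.
#' @param library Library tag recorded in the `library` column (defaults to
#'   the file name without extension).
#' @return A tibble with columns `read_id`, `sequence`, `quality`, `length`,
#'   `library`.
#' @export
read_fastq <- function(path, library = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  validate_fastq(path)
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- sub("\\s.*$", "", names(ss))
  stop_if_dup_ids(ids, "read")
  tibble(
    read_id = ids,
    sequence = unname(toupper(as.character(ss))),
    quality = unname(as.character(Biostrings::quality(ss))),
    length = Biostrings::width(ss),
    library = library %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  )
}

# cheap structural check so malformed files fail with a line number
validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0L) break
    if (length(block) < 4L) {
      abort(sprintf("truncated FASTQ record at line %d in %s", i + 1L, path))
    }
    if (!startsWith(block[1], "@")) {
      abort(sprintf("FASTQ parse error at line %d: header must start with '@'",
                    i + 1L))
    }
    if (!startsWith(block[3], "+")) {
      abort(sprintf("FASTQ parse error at line %d: separator must start with '+'",
                    i + 3L))
    }
    if (nchar(block[2]) != nchar(block[4])) {
      abort(sprintf("FASTQ parse error at line %d: sequence/quality length mismatch",
                    i + 2L))
    }
    i <- i + 4L
  }
  invisible(TRUE)
}

#' Write a long-read tibble to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path (`.gz` suffix triggers gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

paf_core_cols <- c("query_id", "query_len", "query_start", "query_end",
                   "strand", "target_id", "target_len", "target_start",
                   "target_end", "matches", "block_len", "mapq")

#' Parse a PAF alignment file
#'
#' Reads minimap2-style 12+ column PAF. Coordinates are 0-based half-open as
#' in the format itself. Identity is defined as column-10 residue matches over
#' the column-11 alignment block length. An optional `cg:Z` tag is retained in
#' the `cigar` column; per-class mismatch/indel counts are derived from it
#' when it uses `=`/`X` operations.
#'
#' @param path Path to a PAF file.
#' @return An alignment tibble (see [alignment_tbl()]) with the extra columns
#'   `mapq`, `identity` and `is_self`.
#' @export
parse_paf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_lines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) abort(sprintf("empty PAF file: %s", path))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(sprintf("PAF parse error at line %d: fewer than 12 columns",
                  which(nf < 12L)[1]))
  }
  core <- t(vapply(fields, function(f) f[1:12], character(12)))
  colnames(core) <- paf_core_cols
  num <- c("query_len", "query_start", "query_end", "target_len",
           "target_start", "target_end", "matches", "block_len", "mapq")
  out <- as_tibble(as.data.frame(core, stringsAsFactors = FALSE))
  out[num] <- lapply(out[num], function(x) as.integer(as.numeric(x)))
  if (any(vapply(out[num], function(x) any(is.na(x) | x < 0), logical(1)))) {
    abort("PAF parse error: negative or non-numeric coordinate field")
  }
  cg <- vapply(fields, function(f) {
    hit <- grep("^cg:Z:", f, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, character(1))
  out$cigar <- cg
  counts <- cigar_counts(cg)
  out <- dplyr::bind_cols(
    out, counts[c("mismatches", "ins_events", "ins_bases", "del_events",
                  "del_bases")])
  out$identity <- out$matches / out$block_len
  out$is_self <- out$query_id == out$target_id
  out
}

#' Write an alignment tibble as PAF
#'
#' @param aln Alignment tibble with the 12 core PAF columns (missing `mapq`
#'   defaults to 60).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  aln$mapq <- aln[["mapq"]] %||% 60L
  core <- aln[paf_core_cols]
  lines <- do.call(paste, c(unname(as.list(core)), sep = "\t"))
  if (!is.null(aln[["cigar"]])) {
    has <- !is.na(aln$cigar)
    lines[has] <- paste0(lines[has], "\tcg:Z:", aln$cigar[has])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a SAM file into an alignment tibble
#'
#' The file is converted to BAM with Rsamtools (htslib) and scanned; 1-based
#' SAM positions are converted to the package-wide 0-based half-open
#' convention. Soft/hard clips are excluded from the query interval.
#'
#' @param path Path to a SAM file with an `@SQ` header.
#' @return An alignment tibble with `cigar`, `seq` and `qual` columns.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual", "strand",
             "qwidth", "mapq"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  cig <- as.character(x$cigar)[keep]
  counts <- cigar_counts(cig)
  clip_lead <- as.integer(
    ifelse(grepl("^\\d+[SH]", cig), sub("^(\\d+)[SH].*$", "\\1", cig), "0"))
  clip_tail <- as.integer(
    ifelse(grepl("(\\d+)[SH]$", cig), sub("^.*?(\\d+)[SH]$", "\\1", cig), "0"))
  qlen <- x$qwidth[keep]
  qalen <- qlen - clip_lead - clip_tail
  tibble(
    query_id = as.character(x$qname)[keep],
    query_len = qlen,
    query_start = clip_lead,
    query_end = clip_lead + qalen,
    strand = as.character(x$strand)[keep],
    target_id = as.character(x$rname)[keep],
    target_start = x$pos[keep] - 1L,
    target_end = x$pos[keep] - 1L + counts$aln_ref_len,
    matches = counts$matches,
    block_len = counts$block_len,
    cigar = cig,
    seq = as.character(x$seq)[keep],
    qual = as.character(x$qual)[keep],
    nm = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM[keep]
  ) |> dplyr::bind_cols(counts[c("mismatches", "ins_events", "ins_bases",
                                 "del_events", "del_bases")])
}

#' Read a VirSorter category table
#'
#' Accepts CSV or TSV with columns `contig_id` and `category` (1-6).
#'
#' @param path Path to the table.
#' @return A tibble with `contig_id` and integer `category`.
#' @export
read_virsorter <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("contig_id", "category") %in% names(x))) {
    abort("VirSorter table must have columns contig_id and category")
  }
  x$category <- as.integer(x$category)
  if (any(is.na(x$category) | x$category < 1L | x$category > 6L)) {
    abort("VirSorter categories must be integers in 1..6")
  }
  as_tibble(x[c("contig_id", "category")])
}

#' Construct an alignment tibble
#'
#' Canonical container for pairwise alignments (PAF/SAM records or simulated
#' truth). All coordinates are 0-based half-open; `strand` is `"+"` or `"-"`.
#'
#' @param query_id,target_id Sequence ids.
#' @param query_len,target_len Full sequence lengths.
#' @param query_start,query_end,target_start,target_end Aligned intervals.
#' @param strand `"+"` or `"-"`.
#' @param matches Number of identical aligned bases.
#' @param block_len Alignment block length (aligned columns incl. gaps).
#' @param cigar Optional CIGAR string (`M=XIDSH` ops).
#' @param ... Further columns carried through (e.g. `seq`, `qual`).
#' @return A tibble with one row per alignment.
#' @export
alignment_tbl <- function(query_id, target_id, query_len, target_len,
                          query_start, query_end, target_start, target_end,
                          strand = "+", matches, block_len,
                          cigar = NA_character_, ...) {
  tibble(
    query_id = query_id, query_len = as.integer(query_len),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    strand = strand, target_id = target_id,
    target_len = as.integer(target_len),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    matches = as.integer(matches), block_len = as.integer(block_len),
    cigar = cigar, ...
  )
}
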