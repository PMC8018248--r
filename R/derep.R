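#' Filter contigs to putative viral sequences
#'
#' Applies the standard virome contig filter: only contigs at least
#' `min_input_len` long are considered (the length floor fed to the viral
#' classifier), and of those, contigs are kept when they are at least
#' `min_keep_len` long and carry a VirSorter category in `keep_categories`
#' (1, 2, 4, 5 by default - confident phage and prophage calls).
#'
#' @param contigs Contig tibble.
#' @param calls VirSorter call tibble (`contig_id`, `category`); every call
#'   must reference a supplied contig. Contigs without a call are dropped.
#' @param min_input_len Length floor before classification (default 2500).
#' @param min_keep_len Length floor for kept viral contigs (default 5000).
#' @param keep_categories Integer categories retained (default `c(1,2,4,5)`).
#' @return The filtered contig tibble, with a `category` column.
#' @export
filter_viral_contigs <- function(contigs, calls, min_input_len = 2500L,
                                 min_keep_len = 5000L,
                                 keep_categories = c(1L, 2L, 4L, 5L)) {
  missing <- setdiff(calls$contig_id, contigs$contig_id)
  if (length(missing) > 0L) {
    abort(sprintf("VirSorter call references unknown contig: %s", missing[1]))
  }
  if (is.null(contigs[["length"]])) contigs$length <- nchar(contigs$sequence)
  contigs |>
    filter(.data$length >= min_input_len) |>
    dplyr::inner_join(calls, by = "contig_id") |>
    filter(.data$length >= min_keep_len,
           .data$category %in% keep_categories)
}

#' Identity and coverage between two contigs from their alignments
#'
#' Coverage is the fraction of the *shorter* sequence covered by the merged
#' (overlap-collapsed) aligned intervals; identity is the
#' block-length-weighted mean identity of the contributing alignments. These
#' are the quantities the 95% identity / 70% coverage population definition
#' thresholds act on.
#'
#' @param a,b One-row contig tibbles (need `contig_id` and `length`).
#' @param alignments Alignment tibble; rows between `a` and `b` in either
#'   orientation are used, self-hits ignored.
#' @return A one-row tibble: `identity`, `coverage` (both 0 when no
#'   alignments connect the pair).
#' @export
pairwise_similarity <- function(a, b, alignments) {
  ai <- a$contig_id[[1]]; bi <- b$contig_id[[1]]
  al <- contig_len1(a); bl <- contig_len1(b)
  rows <- alignments[
    (alignments$query_id == ai & alignments$target_id == bi) |
    (alignments$query_id == bi & alignments$target_id == ai), , drop = FALSE]
  rows <- rows[rows$query_id != rows$target_id, , drop = FALSE]
  if (nrow(rows) == 0L) return(tibble(identity = 0, coverage = 0))
  shorter <- if (al <= bl) ai else bi
  s <- ifelse(rows$query_id == shorter, rows$query_start, rows$target_start)
  e <- ifelse(rows$query_id == shorter, rows$query_end, rows$target_end)
  merged <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
  cov <- sum(IRanges::width(merged)) / min(al, bl)
  ident <- stats::weighted.mean(rows$matches / rows$block_len,
                                w = rows$block_len)
  tibble(identity = ident, coverage = cov)
}

#' Dereplicate contigs into viral populations
#'
#' Greedy longest-first clustering at ANI-style thresholds: contigs are
#' sorted by length descending (ties broken by id), and each contig joins the
#' first existing cluster whose representative it matches at
#' `>= min_identity` identity over `>= min_coverage` of the shorter sequence;
#' otherwise it seeds a new cluster. Every contig ends up in exactly one
#' cluster and each representative is the longest member.
#'
#' @param contigs Contig tibble.
#' @param alignments All-vs-all alignment tibble (self-hits ignored).
#' @param min_identity Identity threshold (default 0.95).
#' @param min_coverage Coverage threshold on the shorter sequence
#'   (default 0.70).
#' @return A membership tibble: `member_id`, `rep_id`, `member_length`, plus
#'   any `source` column present on `contigs`. Summarise with
#'   [population_summary()].
#' @export
dereplicate <- function(contigs, alignments, min_identity = 0.95,
                        min_coverage = 0.70) {
  if (is.null(contigs[["length"]])) contigs$length <- nchar(contigs$sequence)
  contigs <- contigs |>
    arrange(desc(.data$length), .data$contig_id)
  stop_if_dup_ids(contigs$contig_id, "contig")
  sims <- pair_similarity_table(contigs, alignments)
  reps <- character(0)
  assign <- character(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$contig_id[i]
    hit <- NA_character_
    for (r in reps) {
      key <- pair_key(id, r)
      s <- sims[[key]]
      if (!is.null(s) && s[1] >= min_identity && s[2] >= min_coverage) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      hit <- id
    }
    assign[i] <- hit
  }
  out <- tibble(member_id = contigs$contig_id, rep_id = assign,
                member_length = contigs$length)
  if (!is.null(contigs[["source"]])) out$source <- contigs$source
  out
}

contig_len1 <- function(x) {
  if (!is.null(x[["length"]])) as.integer(x$length[[1]]) else nchar(x$sequence[[1]])
}

pair_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = "\r")
}

# precompute identity/coverage for every aligned unordered pair
pair_similarity_table <- function(contigs, alignments) {
  lens <- stats::setNames(contigs$length, contigs$contig_id)
  aln <- alignments[alignments$query_id != alignments$target_id, , drop = FALSE]
  aln <- aln[aln$query_id %in% names(lens) & aln$target_id %in% names(lens), ,
             drop = FALSE]
  if (nrow(aln) == 0L) return(list())
  key <- purrr::map2_chr(aln$query_id, aln$target_id, pair_key)
  out <- new.env(parent = emptyenv())
  for (k in unique(key)) {
    rows <- aln[key == k, , drop = FALSE]
    ids <- sort(c(rows$query_id[1], rows$target_id[1]))
    shorter <- ids[which.min(lens[ids])]
    s <- ifelse(rows$query_id == shorter, rows$query_start, rows$target_start)
    e <- ifelse(rows$query_id == shorter, rows$query_end, rows$target_end)
    merged <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
    cov <- sum(IRanges::width(merged)) / min(lens[ids])
    ident <- stats::weighted.mean(rows$matches / rows$block_len,
                                  w = rows$block_len)
    assign(k, c(ident, cov), envir = out)
  }
  as.list(out)
}

#' Summarise population clusters
#'
#' @param members Membership tibble from [dereplicate()].
#' @return One row per cluster: `rep_id`, `n_members`, `members`
#'   (list-column), `sources` (list-column, if `source` present), `n_sources`
#'   and `unique_to` (the single source label, or `NA` when shared).
#' @export
population_summary <- function(members) {
  has_src <- !is.null(members[["source"]])
  members |>
    group_by(.data$rep_id) |>
    summarise(
      n_members = dplyr::n(),
      members = list(.data$member_id),
      sources = if (has_src) list(sort(unique(.data$source))) else list(character()),
      .groups = "drop"
    ) |>
    mutate(
      n_sources = lengths(.data$sources),
      unique_to = purrr::map_chr(.data$sources,
                                 ~ if (length(.x) == 1L) .x else NA_character_)
    )
}

#' Pool several assemblies into an enhanced virome
#'
#' Each assembly's contigs are passed through [filter_viral_contigs()],
#' pooled (ids namespaced as `label:id` if any id collides across
#' assemblies), and dereplicated into populations. Each population records
#' which assemblies contributed members, giving shared/unique attribution
#' counts.
#'
#' @param assemblies Named list; each element is a list with `contigs` and
#'   `calls` tibbles. At least two assemblies.
#' @param alignments All-vs-all alignment tibble across the pooled contigs
#'   (same id namespace).
#' @param ... Passed to [filter_viral_contigs()] and [dereplicate()].
#' @param min_identity,min_coverage Dereplication thresholds.
#' @return A list: `populations` (from [population_summary()]), `members`
#'   (membership tibble) and `attribution` (tibble with `n_populations`,
#'   `n_in_all`, `n_shared_some`, and one `unique_<label>` count per
#'   assembly).
#' @export
build_enhanced_virome <- function(assemblies, alignments,
                                  min_identity = 0.95, min_coverage = 0.70,
                                  ...) {
  if (length(assemblies) < 2L) abort("need at least two assemblies")
  labels <- names(assemblies)
  filtered <- purrr::imap(assemblies, function(a, lab) {
    filter_viral_contigs(a$contigs, a$calls, ...) |>
      mutate(source = lab)
  })
  pooled <- purrr::list_rbind(filtered)
  if (anyDuplicated(pooled$contig_id)) {
    pooled$contig_id <- paste(pooled$source, pooled$contig_id, sep = ":")
  }
  members <- dereplicate(pooled, alignments, min_identity, min_coverage)
  pops <- population_summary(members)
  n_all <- sum(pops$n_sources == length(labels))
  uniq <- vapply(labels, function(l) {
    sum(!is.na(pops$unique_to) & pops$unique_to == l)
  }, integer(1))
  attribution <- tibble(
    n_populations = nrow(pops),
    n_in_all = n_all,
    n_shared_some = nrow(pops) - n_all - sum(uniq)
  )
  attribution[paste0("unique_", labels)] <- as.list(uniq)
  list(populations = pops, members = members, attribution = attribution)
}

#' Rank populations by short-read abundance
#'
#' Abundance of a population is the mean mapped-read depth over its
#' representative (total aligned bases / representative length), normalised
#' per million mapped reads in the alignment set. Populations with no mapped
#' reads get abundance 0. Ties in rank are broken by representative id.
#'
#' @param populations Population tibble with `rep_id` and representative
#'   length in `rep_length` (or a `members` tibble to derive it from).
#' @param read_alignments Alignment tibble of (already threshold-filtered)
#'   short-read mappings onto the representatives.
#' @return An abundance tibble: `rep_id`, `abundance`, `rank` (1..N,
#'   non-increasing abundance).
#' @export
rank_abundance <- function(populations, read_alignments) {
  if (is.null(populations[["rep_length"]])) {
    pl <- populations |>
      filter(.data$member_id == .data$rep_id) |>
      select(rep_id = "member_id", rep_length = "member_length") |>
      dplyr::distinct()
  } else {
    pl <- populations[c("rep_id", "rep_length")]
  }
  n_mapped <- dplyr::n_distinct(read_alignments$query_id)
  per_rep <- read_alignments |>
    mutate(aligned = .data$target_end - .data$target_start) |>
    group_by(rep_id = .data$target_id) |>
    summarise(total_bases = sum(.data$aligned), .groups = "drop")
  pl |>
    left_join(per_rep, by = "rep_id") |>
    mutate(
      total_bases = dplyr::coalesce(.data$total_bases, 0),
      abundance = .data$total_bases / .data$rep_length /
        pmax(n_mapped, 1L) * 1e6
    ) |>
    arrange(desc(.data$abundance), .data$rep_id) |>
    mutate(rank = row_number()) |>
    select("rep_id", "abundance", "rank")
}

#' Most abundant decile of populations
#'
#' @param abundance Abundance tibble from [rank_abundance()] (or any tibble
#'   with `rank`).
#' @return The first `floor(N/10)` records by rank.
#' @export
top_decile <- function(abundance) {
  n <- floor(nrow(abundance) / 10)
  abundance |> arrange(.data$rank) |> dplyr::slice_head(n = n)
}
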