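#' Trim and filter long reads
#'
#' Applies the standard long-read virome QC rule: trim the first
#' `trim_leading_bases` bases of every read (residual barcode removal), then
#' remove reads shorter than `min_length_bp` or with mean per-base Phred
#' quality below `min_mean_q`. Trimming happens before the length and quality
#' tests. A `qc_trimmed` column records that trimming has been applied, so
#' re-running the filter on its own output does not trim again.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`, `library`).
#' @param trim_leading_bases Bases to cut from the 5' end (default 50).
#' @param min_length_bp Minimum post-trim read length (default 1000).
#' @param min_mean_q Minimum post-trim mean Phred quality (default 9). A read
#'   failing both tests is reported under reason `"length"`.
#' @return A list with `kept` (trimmed read tibble, `qc_trimmed = TRUE`) and
#'   `removed` (tibble of `read_id`, `reason` in `"length"`/`"quality"`).
#' @export
qc_filter <- function(reads, trim_leading_bases = 50L, min_length_bp = 1000L,
                      min_mean_q = 9) {
  if (nrow(reads) == 0L) {
    return(list(kept = dplyr::mutate(reads, qc_trimmed = logical(0)),
                removed = tibble(read_id = character(), reason = character())))
  }
  already <- isTRUE(reads[["qc_trimmed"]][1])
  if (!already && trim_leading_bases > 0L) {
    reads <- reads |>
      mutate(
        sequence = substr(.data$sequence, trim_leading_bases + 1L, nchar(.data$sequence)),
        quality = substr(.data$quality, trim_leading_bases + 1L, nchar(.data$quality))
      )
  }
  reads <- reads |> mutate(length = nchar(.data$sequence), qc_trimmed = TRUE)
  mq <- mean_quality(reads$quality)
  too_short <- reads$length < min_length_bp
  low_q <- !too_short & (is.nan(mq) | mq < min_mean_q)
  removed <- tibble(
    read_id = reads$read_id[too_short | low_q],
    reason = c("length", "quality")[1L + low_q[too_short | low_q]]
  )
  list(kept = reads[!(too_short | low_q), , drop = FALSE], removed = removed)
}

#' Subsample read libraries to a common size
#'
#' Mirrors the smallest-library subsampling used to remove library-size bias
#' before assembly comparisons: each library is sampled without replacement
#' down to `target_n` reads (or the size of the smallest library when
#' `target_n = "min"`).
#'
#' @param reads Read tibble with a `library` column.
#' @param target_n Integer target size, or `"min"`.
#' @param seed Integer seed (sampling is reproducible).
#' @return A read tibble with `target_n` reads per library.
#' @export
subsample_reads <- function(reads, target_n = "min", seed) {
  sizes <- table(reads$library)
  n <- if (identical(target_n, "min")) min(sizes) else as.integer(target_n)
  if (any(sizes < n)) {
    abort(sprintf("target_n = %d exceeds library size %d (%s)",
                  n, min(sizes), names(sizes)[which.min(sizes)]))
  }
  with_seed(seed, {
    reads |>
      group_by(.data$library) |>
      dplyr::slice_sample(n = n) |>
      ungroup()
  })
}

#' Bootstrap confidence interval for the median read length
#'
#' Resamples `n_per_boot` lengths with replacement `n_boot` times; the 95%
#' interval is the 2.5/97.5 percentile of the bootstrap medians. Defaults
#' match the standard large-library comparison (50,000 draws, 1,000
#' replicates).
#'
#' @param lengths Numeric vector of read lengths (bp), non-empty.
#' @param n_per_boot Draws per replicate.
#' @param n_boot Number of replicates.
#' @param seed Integer seed.
#' @return An object of class `median_ci` with fields `median`, `ci_low`,
#'   `ci_high`, `n`, `n_per_boot`, `n_boot`, `seed` and the replicate medians
#'   in `boot_medians`. Has [tidy()]/[glance()] methods.
#' @export
bootstrap_median <- function(lengths, n_per_boot = 50000L, n_boot = 1000L,
                             seed) {
  if (length(lengths) == 0L) abort("lengths must be non-empty")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(sample(lengths, n_per_boot, replace = TRUE))
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  structure(
    list(median = stats::median(lengths), ci_low = ci[1], ci_high = ci[2],
         n = length(lengths), n_per_boot = n_per_boot, n_boot = n_boot,
         seed = seed, boot_medians = boots),
    class = "median_ci"
  )
}

#' @export
print.median_ci <- function(x, ...) {
  cat(sprintf("Median %s bp (95%% bootstrap CI %s-%s; n=%d, %d x %d resamples)\n",
              format(x$median), format(x$ci_low), format(x$ci_high),
              x$n, x$n_boot, x$n_per_boot))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.median_ci <- function(x, ...) {
  tibble(replicate = seq_along(x$boot_medians), median = x$boot_medians)
}

#' @exportS3Method generics::glance
glance.median_ci <- function(x, ...) {
  tibble(median = x$median, ci_low = x$ci_low, ci_high = x$ci_high,
         n = x$n, n_per_boot = x$n_per_boot, n_boot = x$n_boot)
}

#' Compare two read-length distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with normal approximation
#' and tie correction, as used for read-length distribution contrasts.
#'
#' @param a,b Numeric vectors of lengths, non-empty.
#' @return A one-row tibble: `u` (U statistic for `a` vs `b`), `p_value`,
#'   `n_a`, `n_b`, `median_a`, `median_b`.
#' @export
compare_lengths <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    u <- length(a) * length(b) / 2
    p <- 1
  } else {
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    u <- unname(w$statistic)
    p <- w$p.value
  }
  tibble(u = u, p_value = p, n_a = length(a), n_b = length(b),
         median_a = stats::median(a), median_b = stats::median(b))
}

#' Detect chimeric reads from all-vs-all overlap coverage
#'
#' Scrubber-style chimera detection: for each read, a coverage profile is
#' accumulated from the intervals that other reads' overlaps cover on it. A
#' read is flagged when an internal interval of at least `min_gap_bp`, lying
#' at least `end_slack_bp` from both read ends, has coverage below `min_cov`
#' while positions on both sides reach `min_cov` - the signature of a PCR
#' junction no genuine overlap spans.
#'
#' @param reads Read tibble (lengths taken from `length` or `sequence`).
#' @param overlaps Alignment tibble of all-vs-all read overlaps; self-hits
#'   (`query_id == target_id`) are ignored.
#' @param min_cov Minimum supporting overlap coverage (default 4).
#' @param end_slack_bp Ignored margin at each read end (default 200).
#' @param min_gap_bp Minimum internal low-coverage span (default 300).
#' @return Object of class `chimera_scan`: `per_read` tibble (`read_id`,
#'   `flagged`, `gaps` list-column of `start`/`end` tibbles), and summary
#'   counts (`n_reads`, `n_flagged`, `rate`). Has [tidy()]/[glance()] methods.
#' @export
detect_chimeras <- function(reads, overlaps, min_cov = 4L,
                            end_slack_bp = 200L, min_gap_bp = 300L) {
  lens <- reads[["length"]] %||% nchar(reads$sequence)
  names(lens) <- reads$read_id
  ov <- overlaps[overlaps$query_id != overlaps$target_id, , drop = FALSE]
  unknown <- setdiff(unique(c(ov$query_id, ov$target_id)), reads$read_id)
  if (length(unknown) > 0L) {
    abort(sprintf("overlap references unknown read id: %s", unknown[1]))
  }
  # every overlap covers an interval on both of its reads
  iv <- tibble(
    read_id = c(ov$query_id, ov$target_id),
    start = c(ov$query_start, ov$target_start),
    end = c(ov$query_end, ov$target_end)
  )
  iv_by <- split(iv[c("start", "end")], iv$read_id)

  per_read <- purrr::map2(reads$read_id, lens, function(rid, L) {
    gaps <- find_low_cov_gaps(iv_by[[rid]], L, min_cov, end_slack_bp,
                              min_gap_bp)
    tibble(read_id = rid, flagged = nrow(gaps) > 0L, gaps = list(gaps))
  }) |> purrr::list_rbind()

  structure(
    list(per_read = per_read, n_reads = nrow(per_read),
         n_flagged = sum(per_read$flagged),
         rate = if (nrow(per_read)) mean(per_read$flagged) else 0,
         params = list(min_cov = min_cov, end_slack_bp = end_slack_bp,
                       min_gap_bp = min_gap_bp)),
    class = "chimera_scan"
  )
}

# low-coverage runs with covered flanks, intersected with the internal window
find_low_cov_gaps <- function(iv, L, min_cov, end_slack, min_gap) {
  empty <- tibble(start = integer(), end = integer())
  if (is.null(iv) || nrow(iv) == 0L) return(empty)
  s <- pmax(iv$start, 0L); e <- pmin(iv$end, L)
  ok <- s < e
  if (!any(ok)) return(empty)
  delta <- tabulate(s[ok] + 1L, nbins = L + 1L) -
    tabulate(e[ok] + 1L, nbins = L + 1L)
  cov <- cumsum(delta)[seq_len(L)]
  high <- cov >= min_cov
  if (!any(high)) return(empty)
  low <- !high
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  left_high <- cummax(high)                    # any covered position so far
  right_high <- rev(cummax(rev(high)))
  for (k in runs) {
    a <- starts[k]; b <- ends[k]               # 1-based inclusive
    if (a > 1L && b < L &&
        left_high[a - 1L] && right_high[b + 1L]) {
      ga <- max(a - 1L, end_slack)             # 0-based clip to window
      gb <- min(b, L - end_slack)
      if (gb - ga >= min_gap) {
        out[[length(out) + 1L]] <- tibble(start = ga, end = gb)
      }
    }
  }
  if (length(out)) purrr::list_rbind(out) else empty
}

#' @export
print.chimera_scan <- function(x, ...) {
  cat(sprintf("Chimera scan: %d/%d reads flagged (rate %.4f)\n",
              x$n_flagged, x$n_reads, x$rate))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chimera_scan <- function(x, ...) x$per_read

#' @exportS3Method generics::glance
glance.chimera_scan <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_flagged = x$n_flagged, rate = x$rate,
         min_cov = x$params$min_cov, end_slack_bp = x$params$end_slack_bp,
         min_gap_bp = x$params$min_gap_bp)
}
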