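#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number desc across
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores in `[0, 93]`.
#' @return A single character string.
#' @export
int_to_phred <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) == 0L) return("")
  if (any(scores < 0L | scores > 93L)) {
    abort("Phred scores must lie in [0, 93].")
  }
  intToUtf8(scores + 33L)
}

#' Mean per-base Phred quality of reads
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities (`NaN` for empty strings).
#' @export
mean_quality <- function(quality) {
  vapply(quality, function(q) {
    if (nchar(q) == 0L) return(NaN)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

# reverse-complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded evaluation that does not disturb the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_if_dup_ids <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d) > 0L) {
    abort(sprintf("duplicate %s id(s): %s", what,
                  paste(utils::head(d, 5), collapse = ", ")))
  }
}

#' @export
generics::tidy

#' @export
generics::glance
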