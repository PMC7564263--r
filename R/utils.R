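#' Format a back-splice junction identifier
#'
#' Junction identifiers follow the `chrom:start-end` convention, with 1-based
#' fully-closed coordinates: `start` is the first and `end` the last base
#' inside the circle.
#'
#' @param chrom Chromosome name.
#' @param start First base inside the circle (1-based).
#' @param end Last base inside the circle (1-based).
#' @return Character vector of identifiers.
#' @export
#' @examples
#' circ_id("3", 11289661, 11291634)
circ_id <- function(chrom, start, end) {
  stopifnot(all(start < end))
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse junction identifiers back to coordinates
#'
#' @param id Character vector of `chrom:start-end` identifiers.
#' @return A tibble with columns `circ_id`, `chrom`, `start`, `end`.
#' @export
parse_circ_id <- function(id) {
  m <- stringr::str_match(id, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) {
    stop("malformed junction id(s): ", paste(id[is.na(m[, 1])], collapse = ", "))
  }
  tibble::tibble(
    circ_id = id,
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}

# reverse complement of plain character vectors (vectorized, no XString
# round-trip: this sits in the read-emission hot path)
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# derive a stream-specific seed from the master seed; stays well below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

# extract plus-strand sequence [start, end] from a genome bundle
genome_seq <- function(genome, chrom, start, end) {
  s <- genome$seqs[[chrom]]
  as.character(Biostrings::subseq(s, start = start, end = end))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# uniform draw from an integer range, immune to R's scalar-sample trap
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq.int(lo, hi), n, replace = TRUE)
}

# safe single pick from a vector of any length
sample_one <- function(x) x[sample.int(length(x), 1L)]
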