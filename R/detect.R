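#' Call back-splice junctions from split-read groups
#'
#' A read end supports a back-splice junction when two of its aligned
#' segments share chromosome and strand, their read intervals are
#' complementary (overlap at most `slack` bases), and their genomic order is
#' chiastic — the segment earlier in read orientation maps transcript-downstream
#' of the later segment. In transcript orientation the read prefix ends at
#' the last base inside the circle and the read suffix starts at the first
#' base inside it; on the plus strand this means the prefix segment ends at
#' genomic `end` and the suffix segment starts at genomic `start < end`, and
#' on the minus strand the genomic roles of the two arms swap. Junction
#' coordinates are reported 1-based closed, first and last base inside the
#' circle.
#'
#' Groups with more than two usable segments contribute the pair maximizing
#' total aligned read length; ties are rejected as ambiguous and counted in
#' the `ambiguous` attribute.
#'
#' @param segments A [read_sam()] segment tibble (one sample).
#' @param slack Maximum tolerated overlap (bases) between the two segments'
#'   read intervals.
#' @return Tibble of per-read-end junctions: `qname`, `mate`, `chrom`,
#'   `strand`, `start`, `end`; attribute `ambiguous` counts rejected groups.
#' @export
call_backsplice <- function(segments, slack = 5L) {
  usable <- segments |>
    dplyr::filter(!is_unmapped, !is_secondary) |>
    dplyr::mutate(group_id = paste0(qname, "/", mate)) |>
    dplyr::add_count(group_id, name = "n_segments")

  multi <- dplyr::filter(usable, n_segments >= 2L)
  ambiguous <- 0L
  empty <- tibble::tibble(
    qname = character(), mate = integer(), chrom = character(),
    strand = character(), start = integer(), end = integer()
  )
  if (nrow(multi) == 0) {
    attr(empty, "ambiguous") <- 0L
    return(empty)
  }

  # reduce >2-segment groups to the best pair (or drop them on ties)
  over2 <- dplyr::filter(multi, n_segments > 2L)
  pair2 <- dplyr::filter(multi, n_segments == 2L)
  if (nrow(over2) > 0) {
    kept <- over2 |>
      dplyr::group_by(group_id) |>
      dplyr::group_map(function(g, key) {
        alen <- g$read_end - g$read_start + 1L
        cmb <- utils::combn(nrow(g), 2L)
        tot <- alen[cmb[1, ]] + alen[cmb[2, ]]
        best <- which(tot == max(tot))
        if (length(best) > 1L) return(NULL)
        g[cmb[, best], ] |> dplyr::mutate(group_id = key$group_id)
      }) |>
      purrr::compact()
    ambiguous <- sum(dplyr::count(over2, group_id)$n >= 0) - length(kept)
    pair2 <- dplyr::bind_rows(pair2, dplyr::bind_rows(kept))
  }
  if (nrow(pair2) == 0) {
    attr(empty, "ambiguous") <- ambiguous
    return(empty)
  }

  paired <- pair2 |>
    dplyr::arrange(group_id, read_start, read_end) |>
    dplyr::group_by(group_id) |>
    dplyr::summarise(
      qname = qname[1], mate = mate[1],
      same = chrom[1] == chrom[2] && strand[1] == strand[2],
      chrom = chrom[1], strand = strand[1],
      p_rs = ref_start[1], p_re = ref_end[1],
      q_rs = ref_start[2], q_re = ref_end[2],
      overlap = max(0L, read_end[1] - read_start[2] + 1L),
      .groups = "drop"
    ) |>
    dplyr::filter(same, overlap <= slack) |>
    dplyr::mutate(
      chiastic = dplyr::if_else(strand == "+", q_rs < p_rs, q_re > p_re),
      start = dplyr::if_else(strand == "+", q_rs, p_rs),
      end = dplyr::if_else(strand == "+", p_re, q_re)
    ) |>
    dplyr::filter(chiastic, start < end)

  out <- dplyr::select(paired, qname, mate, chrom, strand, start, end)
  attr(out, "ambiguous") <- ambiguous
  out
}

# vectorized canonical splice-signal test at back-splice coordinates:
# transcript-orientation donor GT just downstream of the circle end and
# acceptor AG just upstream of its start; on the minus strand this reads
# AC / CT on the plus-strand sequence
has_splice_signal <- function(genome, chrom, strand, start, end) {
  lens <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
  vapply(seq_along(chrom), function(i) {
    cl <- lens[[chrom[i]]]
    if (is.null(cl) || start[i] < 3L || end[i] > cl - 2L) return(FALSE)
    up <- genome_seq(genome, chrom[i], start[i] - 2L, start[i] - 1L)
    down <- genome_seq(genome, chrom[i], end[i] + 1L, end[i] + 2L)
    if (strand[i] == "+") up == "AG" && down == "GT" else up == "AC" && down == "CT"
  }, logical(1))
}

#' Check canonical GT-AG splice signals at back-splice junctions
#'
#' @param junctions Tibble with `chrom`, `strand`, `start`, `end`.
#' @param genome A genome bundle.
#' @return The tibble with a logical `canonical_signal` column. Junctions
#'   within 2 bases of a chromosome edge are FALSE.
#' @export
check_splice_signal <- function(junctions, genome) {
  junctions$canonical_signal <- has_splice_signal(
    genome, junctions$chrom, junctions$strand, junctions$start, junctions$end
  )
  junctions
}

#' Call circRNAs from split-read alignments
#'
#' Aggregates per-read back-splice evidence (see [call_backsplice()]) by
#' exact junction, counting distinct templates (a junction supported by both
#' mates of one template counts once), then applies the standard filters: at
#' least `min_reads` supporting templates and, when `require_signal` is on,
#' a canonical GT-AG splice signal at the back-splice site. Junctions on
#' organelle-class chromosomes are excluded from calling (organelle reads
#' only enter library accounting).
#'
#' @param segments A [read_sam()] tibble for one sample, or a SAM path.
#' @param genome A genome bundle.
#' @param min_reads Minimum supporting back-spliced templates (default 2).
#' @param require_signal Drop junctions without the canonical signal.
#' @param exclude_organelle Drop junctions on organelle chromosomes.
#' @param slack Read-interval overlap slack passed to [call_backsplice()].
#' @return Tibble of calls sorted by chromosome and start: `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_junction_reads`,
#'   `canonical_signal`, `supporting_reads` (list column of template names).
#' @export
call_circrnas <- function(segments, genome, min_reads = 2L, require_signal = TRUE,
                          exclude_organelle = TRUE, slack = 5L) {
  if (is.character(segments)) segments <- read_sam(segments)
  bs <- call_backsplice(segments, slack = slack)
  if (exclude_organelle) {
    org <- genome$chroms$chrom[genome$chroms$class == "organelle"]
    bs <- dplyr::filter(bs, !chrom %in% org)
  }
  calls <- bs |>
    dplyr::distinct(qname, chrom, strand, start, end) |>
    dplyr::group_by(chrom, strand, start, end) |>
    dplyr::summarise(
      n_junction_reads = dplyr::n_distinct(qname),
      supporting_reads = list(sort(unique(qname))),
      .groups = "drop"
    )
  calls <- check_splice_signal(calls, genome)
  calls <- dplyr::filter(calls, n_junction_reads >= min_reads)
  if (require_signal) calls <- dplyr::filter(calls, canonical_signal)
  calls |>
    dplyr::arrange(chrom, start, end) |>
    dplyr::mutate(circ_id = circ_id(chrom, start, end)) |>
    dplyr::select(
      circ_id, chrom, start, end, strand,
      n_junction_reads, canonical_signal, supporting_reads
    )
}

#' Concordance between two circRNA call sets
#'
#' Reports the fraction of `calls_a` recovered in `calls_b`, the reciprocal
#' fraction, and the Jaccard index of the two id sets.
#'
#' @param calls_a,calls_b Call tibbles (as from [call_circrnas()]) for the
#'   same sample.
#' @return One-row tibble: `n_a`, `n_b`, `n_common`, `frac_a_in_b`,
#'   `frac_b_in_a`, `jaccard`. With empty `calls_a` the fractions are `NA`
#'   (with a warning): the quantity is undefined.
#' @export
concordance <- function(calls_a, calls_b) {
  a <- unique(calls_a$circ_id)
  b <- unique(calls_b$circ_id)
  common <- length(intersect(a, b))
  if (length(a) == 0) {
    warning("calls_a is empty; concordance fractions are undefined")
    return(tibble::tibble(
      n_a = 0L, n_b = length(b), n_common = 0L,
      frac_a_in_b = NA_real_, frac_b_in_a = NA_real_, jaccard = NA_real_
    ))
  }
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_common = common,
    frac_a_in_b = common / length(a),
    frac_b_in_a = if (length(b) > 0) common / length(b) else NA_real_,
    jaccard = common / length(union(a, b))
  )
}
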