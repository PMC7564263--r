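#' Anchor-based circRNA detection from raw reads
#'
#' An independent second detector that never looks at alignments: it takes
#' `anchor_len`-mers from both ends of each read, finds their exact genomic
#' placements (both strands), and when the two anchors land on the same
#' chromosome and strand in chiastic order — the head anchor downstream of
#' the tail anchor — extends both inward over exact matches. A back-splice
#' breakpoint is reported where the extensions meet with canonical GT-AG
#' flanks at the implied donor/acceptor positions. Junctions are then
#' aggregated per template and thresholded exactly as in [call_circrnas()],
#' so the two detectors are comparable call for call.
#'
#' Reads with an anchor matching more than one genomic position are dropped
#' as ambiguous (counted in the `ambiguous` attribute); reads whose anchors
#' are collinear are linear evidence and never produce a call.
#'
#' @param fastq Path(s) to FASTQ files of one sample.
#' @param genome A genome bundle (small enough for exact k-mer lookup).
#' @param anchor_len Anchor length in bases (default 20).
#' @param min_reads Minimum supporting templates (default 2).
#' @param exclude_organelle Drop junctions on organelle chromosomes.
#' @return A call tibble shaped like [call_circrnas()] output.
#' @export
call_circrnas_anchor <- function(fastq, genome, anchor_len = 20L, min_reads = 2L,
                                 exclude_organelle = TRUE) {
  reads <- Biostrings::readDNAStringSet(unlist(fastq), format = "fastq")
  L <- Biostrings::width(reads)
  if (anchor_len > min(L) / 2) {
    stop("anchor_len (", anchor_len, ") must not exceed half the read length (", min(L), ")")
  }
  rid <- sub("\\s.*$", "", names(reads))
  template <- sub("/[12]$", "", rid)

  # search frames: every chromosome in both orientations; minus-frame
  # coordinates are converted back to plus coordinates at the end
  frames <- list()
  for (i in seq_along(genome$seqs)) {
    chrom <- names(genome$seqs)[i]
    frames[[paste0(chrom, "+")]] <- genome$seqs[[i]]
    frames[[paste0(chrom, "-")]] <- Biostrings::reverseComplement(genome$seqs[[i]])
  }
  if (exclude_organelle) {
    org <- genome$chroms$chrom[genome$chroms$class == "organelle"]
    frames <- frames[!sub("[+-]$", "", names(frames)) %in% org]
  }
  frame_str <- vapply(frames, as.character, "")

  head_anchor <- Biostrings::subseq(reads, 1L, anchor_len)
  tail_anchor <- Biostrings::subseq(reads, L - anchor_len + 1L, L)

  locate <- function(anchors) {
    pd <- Biostrings::PDict(anchors)
    hits <- vector("list", length(frames))
    for (fi in seq_along(frames)) {
      m <- Biostrings::matchPDict(pd, frames[[fi]])
      st <- IRanges::start(m)
      n <- lengths(st)
      hits[[fi]] <- tibble::tibble(
        read = rep(seq_along(anchors), n),
        frame = names(frames)[fi],
        at = unlist(st, use.names = FALSE)
      )
    }
    dplyr::bind_rows(hits)
  }
  hh <- locate(head_anchor)
  tt <- locate(tail_anchor)

  n_head <- tabulate(hh$read, nbins = length(reads))
  n_tail <- tabulate(tt$read, nbins = length(reads))
  unique_both <- n_head == 1L & n_tail == 1L
  ambiguous <- sum(n_head > 1L | n_tail > 1L)

  cand <- dplyr::inner_join(
    dplyr::filter(hh, unique_both[read]),
    dplyr::filter(tt, unique_both[read]),
    by = "read", suffix = c("_h", "_t")
  ) |>
    dplyr::filter(frame_h == frame_t, at_t < at_h) # chiastic: tail upstream of head

  # per candidate read, every breakpoint in the ambiguity window whose flanks
  # read GT/AG; ambiguity between windows is resolved afterwards by voting
  read_str <- as.character(reads)
  c_read <- cand$read; c_frame <- cand$frame_h
  c_ah <- cand$at_h; c_at <- cand$at_t
  per_read <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fs <- frame_str[[c_frame[i]]]
    fl <- nchar(fs)
    rs <- read_str[c_read[i]]
    Lr <- nchar(rs)
    # inward extension of both anchors over exact matches
    m1 <- anchor_len
    while (m1 < Lr && c_ah[i] + m1 <= fl &&
           substr(rs, m1 + 1L, m1 + 1L) == substr(fs, c_ah[i] + m1, c_ah[i] + m1)) {
      m1 <- m1 + 1L
    }
    m2 <- anchor_len
    tail_end <- c_at[i] + anchor_len - 1L
    while (m2 < Lr && tail_end - m2 >= 1L &&
           substr(rs, Lr - m2, Lr - m2) == substr(fs, tail_end - m2, tail_end - m2)) {
      m2 <- m2 + 1L
    }
    if (m1 + m2 < Lr) next # extensions never meet: no clean breakpoint
    found <- character(0)
    for (b in seq(max(Lr - m2, anchor_len), min(m1, Lr - anchor_len))) {
      e_f <- c_ah[i] + b - 1L
      s_f <- tail_end - (Lr - b) + 1L
      if (s_f >= 3L && e_f + 2L <= fl &&
          substr(fs, e_f + 1L, e_f + 2L) == "GT" &&
          substr(fs, s_f - 2L, s_f - 1L) == "AG") {
        found <- c(found, paste0(c_frame[i], ":", s_f, "-", e_f))
      }
    }
    if (length(found) > 0) per_read[[i]] <- found
  }
  keep <- lengths(per_read) > 0
  votes <- table(unlist(lapply(per_read[keep], unique), use.names = FALSE))
  jx <- purrr::map_dfr(which(keep), function(i) {
    cands <- unique(per_read[[i]])
    v <- votes[cands]
    best <- cands[v == max(v)]
    if (length(best) > 1) return(NULL) # irresolvably ambiguous breakpoint
    m <- stringr::str_match(best, "^(.*)([+-]):(\\d+)-(\\d+)$")
    chrom <- m[2]; ori <- m[3]
    s_f <- as.integer(m[4]); e_f <- as.integer(m[5])
    if (ori == "+") {
      tibble::tibble(read = c_read[i], chrom = chrom, strand = "+",
                     start = s_f, end = e_f)
    } else {
      cl <- nchar(frame_str[[paste0(chrom, ori)]])
      tibble::tibble(read = c_read[i], chrom = chrom, strand = "-",
                     start = cl - e_f + 1L, end = cl - s_f + 1L)
    }
  })

  empty <- tibble::tibble(
    circ_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(),
    n_junction_reads = integer(), canonical_signal = logical(),
    supporting_reads = list()
  )
  if (nrow(jx) == 0) {
    attr(empty, "ambiguous") <- ambiguous
    return(empty)
  }
  out <- jx |>
    dplyr::mutate(template = template[read]) |>
    dplyr::distinct(template, chrom, strand, start, end) |>
    dplyr::group_by(chrom, strand, start, end) |>
    dplyr::summarise(
      n_junction_reads = dplyr::n_distinct(template),
      supporting_reads = list(sort(unique(template))),
      .groups = "drop"
    ) |>
    dplyr::filter(n_junction_reads >= min_reads) |>
    dplyr::arrange(chrom, start, end) |>
    dplyr::mutate(circ_id = circ_id(chrom, start, end), canonical_signal = TRUE) |>
    dplyr::select(
      circ_id, chrom, start, end, strand,
      n_junction_reads, canonical_signal, supporting_reads
    )
  attr(out, "ambiguous") <- ambiguous
  out
}
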