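# Transcript-coordinate machinery shared by the simulator.
#
# A "map" is a tibble of exon blocks in *transcript* order with cumulative
# transcript offsets; projection turns transcript intervals into ascending
# genomic blocks (the building blocks of spliced CIGARs).

# exon map of a gene in transcript orientation
gene_exon_map <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, ]
  if (nrow(ex) == 0) stop("unknown gene: ", gene_id)
  ex <- ex[order(ex$exon_rank), ]
  len <- ex$end - ex$start + 1L
  t_end <- cumsum(len)
  tibble::tibble(
    chrom = ex$chrom, strand = ex$strand, exon_rank = ex$exon_rank,
    gstart = ex$start, gend = ex$end, len = len,
    t_start = t_end - len + 1L, t_end = t_end
  )
}

# exon-slice map of a circle [s, e] inside its host gene (transcript orientation)
circle_exon_map <- function(genome, gene_id, s, e) {
  map <- gene_exon_map(genome, gene_id)
  keep <- map$gend >= s & map$gstart <= e
  map <- map[keep, ]
  map$gstart <- pmax(map$gstart, s)
  map$gend <- pmin(map$gend, e)
  map$len <- map$gend - map$gstart + 1L
  t_end <- cumsum(map$len)
  map$t_start <- t_end - map$len + 1L
  map$t_end <- t_end
  map
}

# spliced transcript sequence in transcript orientation: the genomically
# ascending spliced sequence, reverse-complemented as a whole on the minus
# strand (chunk order and complementation must flip together)
map_transcript_seq <- function(genome, map) {
  ord <- order(map$gstart)
  chunks <- vapply(
    ord,
    function(i) genome_seq(genome, map$chrom[i], map$gstart[i], map$gend[i]),
    ""
  )
  plus <- paste0(chunks, collapse = "")
  if (map$strand[1] == "+") plus else revcomp(plus)
}

# plain-vector form of a map, for the projection hot path
as_proj_map <- function(map) {
  list(
    chrom = map$chrom[1], strand = map$strand[1], n = nrow(map),
    t_start = map$t_start, t_end = map$t_end,
    gstart = map$gstart, gend = map$gend
  )
}

# project transcript intervals [t1, t2] onto the genome; vectorized over
# intervals; returns pos (leftmost), end (rightmost) and spliced CIGAR cores
project_many <- function(pm, t1, t2) {
  k <- length(t1)
  pos <- integer(k); endp <- integer(k); cig <- character(k)
  for (i in seq_len(k)) {
    i1 <- findInterval(t1[i], pm$t_start)
    i2 <- findInterval(t2[i], pm$t_start)
    gs <- pm$gstart[i1:i2]
    ge <- pm$gend[i1:i2]
    off1 <- t1[i] - pm$t_start[i1]
    off2 <- pm$t_end[i2] - t2[i]
    if (pm$strand == "+") {
      gs[1] <- gs[1] + off1
      ge[length(ge)] <- ge[length(ge)] - off2
    } else {
      # transcript runs right-to-left on the genome
      ge[1] <- ge[1] - off1
      gs[length(gs)] <- gs[length(gs)] + off2
      gs <- rev(gs); ge <- rev(ge)
    }
    w <- ge - gs + 1L
    nb <- length(w)
    cig[i] <- if (nb == 1L) {
      paste0(w, "M")
    } else {
      paste0(w[1], "M", paste0(gs[-1] - ge[-nb] - 1L, "N", w[-1], "M", collapse = ""))
    }
    pos[i] <- gs[1]
    endp[i] <- ge[nb]
  }
  list(pos = pos, end = endp, cigar = cig)
}

# single-interval convenience wrapper (kept for constructed-fixture tests)
project_interval <- function(map, t1, t2) {
  p <- project_many(as_proj_map(map), t1, t2)
  list(pos = p$pos[1], end = p$end[1], cigar = p$cigar[1])
}
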