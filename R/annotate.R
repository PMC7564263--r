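#' Assign host genes to back-splice junctions
#'
#' A junction's host gene is the gene whose span contains the full circle
#' interval on the junction's strand. Among several candidates the gene with
#' maximal exonic overlap with the circle wins; ties go to the smaller gene
#' span. If no same-strand gene contains the junction, the search is retried
#' strand-agnostically (flagged); junctions in gene deserts come back
#' intergenic.
#'
#' @param junctions Tibble with `circ_id`, `chrom`, `strand`, `start`, `end`.
#' @param genome A genome bundle.
#' @return The junction tibble with `host_gene` (NA when intergenic) and
#'   `host_strand_mismatch` columns.
#' @export
assign_host_gene <- function(junctions, genome) {
  genes <- genome$genes
  exons <- genome$exons
  pick <- function(chrom, strand, s, e, strand_specific) {
    cand <- genes[genes$chrom == chrom & genes$start <= s & genes$end >= e, ]
    if (strand_specific) cand <- cand[cand$strand == strand, ]
    if (nrow(cand) == 0) return(NA_character_)
    if (nrow(cand) == 1) return(cand$gene_id)
    ov <- vapply(cand$gene_id, function(g) {
      ex <- exons[exons$gene_id == g, ]
      sum(pmax(0L, pmin(ex$end, e) - pmax(ex$start, s) + 1L))
    }, integer(1))
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      span <- cand$end[best] - cand$start[best]
      best <- best[which.min(span)]
    }
    cand$gene_id[best[1]]
  }
  res <- purrr::map_dfr(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    g <- pick(j$chrom, j$strand, j$start, j$end, TRUE)
    mismatch <- FALSE
    if (is.na(g)) {
      g <- pick(j$chrom, j$strand, j$start, j$end, FALSE)
      mismatch <- !is.na(g)
    }
    tibble::tibble(host_gene = g, host_strand_mismatch = mismatch)
  })
  dplyr::bind_cols(junctions, res)
}

# exon index (transcript orientation) containing a coordinate; intronic
# coordinates take the next downstream exon (transcript orientation) with a
# flag; coordinates outside the gene span are a structural inconsistency
locate_exon <- function(gene_map, coord) {
  n <- nrow(gene_map)
  span_lo <- min(gene_map$gstart)
  span_hi <- max(gene_map$gend)
  if (coord < span_lo || coord > span_hi) {
    stop("coordinate ", coord, " lies outside the host gene span [", span_lo, ", ", span_hi, "]")
  }
  inside <- which(gene_map$gstart <= coord & gene_map$gend >= coord)
  if (length(inside) == 1) {
    return(list(index = gene_map$exon_rank[inside], intronic = FALSE))
  }
  # intronic: next exon downstream in transcript orientation
  if (gene_map$strand[1] == "+") {
    nxt <- which(gene_map$gstart > coord)
    nxt <- nxt[which.min(gene_map$gstart[nxt])]
  } else {
    nxt <- which(gene_map$gend < coord)
    nxt <- nxt[which.max(gene_map$gend[nxt])]
  }
  list(index = gene_map$exon_rank[nxt], intronic = TRUE)
}

#' Start-exon index of a junction within its host gene
#'
#' The index (counted 5'-to-3' in transcript orientation; on the minus
#' strand exon 1 is the rightmost genomic exon) of the exon containing the
#' junction's transcript-5' endpoint — the genomic start on the plus strand,
#' the genomic end on the minus strand. Intronic endpoints are assigned the
#' next downstream exon with `intronic = TRUE`.
#'
#' @param junction One-row tibble (`chrom`, `strand`, `start`, `end`).
#' @param genome A genome bundle.
#' @param gene_id Host gene.
#' @return List with `index`, `intronic`, `first_exon` (index == 1).
#' @export
start_exon_index <- function(junction, genome, gene_id) {
  map <- gene_exon_map(genome, gene_id)
  coord <- if (junction$strand == "+") junction$start else junction$end
  loc <- locate_exon(map, coord)
  list(index = loc$index, intronic = loc$intronic, first_exon = loc$index == 1L)
}

#' Classify a junction endpoint against the gene model
#'
#' `exon_boundary` when the coordinate matches (within `tolerance`) the
#' annotated splice boundary appropriate to its side in transcript
#' orientation — the acceptor boundary (exon 5' edge) for the circle start,
#' the donor boundary (exon 3' edge) for the circle end; otherwise
#' `exon_internal` inside any exon, `intron` inside the gene span, or
#' `intergenic`.
#'
#' @param coordinate Genomic coordinate (1-based).
#' @param side `"start"` (transcript-5' endpoint, acceptor side) or
#'   `"end"` (transcript-3' endpoint, donor side).
#' @param gene_map A [gene_exon_map()] tibble (or gene id + genome below).
#' @param tolerance Allowed distance in bases from the exact boundary
#'   (default 0).
#' @return One of `"exon_boundary"`, `"exon_internal"`, `"intron"`,
#'   `"intergenic"`.
#' @export
boundary_class <- function(coordinate, side = c("start", "end"), gene_map,
                           tolerance = 0L) {
  side <- match.arg(side)
  strand <- gene_map$strand[1]
  # acceptor = transcript-5' exon edge; donor = transcript-3' edge
  boundary <- if ((side == "start") == (strand == "+")) gene_map$gstart else gene_map$gend
  if (any(abs(coordinate - boundary) <= tolerance)) return("exon_boundary")
  if (any(gene_map$gstart <= coordinate & gene_map$gend >= coordinate)) {
    return("exon_internal")
  }
  if (coordinate >= min(gene_map$gstart) && coordinate <= max(gene_map$gend)) {
    return("intron")
  }
  "intergenic"
}

#' Full structural annotation of junctions
#'
#' Combines host-gene assignment, start/end exon indexing and endpoint
#' boundary classes into one record per junction. Sides are interpreted in
#' transcript orientation: the circle's transcript-5' endpoint is the
#' genomic start on plus-strand genes and the genomic end on minus-strand
#' genes.
#'
#' @param junctions Tibble with `circ_id`, `chrom`, `strand`, `start`, `end`.
#' @param genome A genome bundle.
#' @param tolerance Boundary-match tolerance in bases (default 0).
#' @return Tibble: `circ_id`, `host_gene`, `start_exon_index`,
#'   `end_exon_index`, `start_class`, `end_class`, `first_exon_flag`,
#'   `start_intronic`, `end_intronic`, `host_strand_mismatch`.
#' @export
annotate_junctions <- function(junctions, genome, tolerance = 0L) {
  hosted <- assign_host_gene(junctions, genome)
  purrr::map_dfr(seq_len(nrow(hosted)), function(i) {
    j <- hosted[i, ]
    if (is.na(j$host_gene)) {
      return(tibble::tibble(
        circ_id = j$circ_id, host_gene = NA_character_,
        start_exon_index = NA_integer_, end_exon_index = NA_integer_,
        start_class = "intergenic", end_class = "intergenic",
        first_exon_flag = NA, start_intronic = NA, end_intronic = NA,
        host_strand_mismatch = j$host_strand_mismatch
      ))
    }
    map <- gene_exon_map(genome, j$host_gene)
    strand <- map$strand[1]
    t5 <- if (strand == "+") j$start else j$end # transcript-5' endpoint
    t3 <- if (strand == "+") j$end else j$start
    loc5 <- locate_exon(map, t5)
    loc3 <- locate_exon(map, t3)
    tibble::tibble(
      circ_id = j$circ_id, host_gene = j$host_gene,
      start_exon_index = loc5$index, end_exon_index = loc3$index,
      start_class = boundary_class(t5, "start", map, tolerance),
      end_class = boundary_class(t3, "end", map, tolerance),
      first_exon_flag = loc5$index == 1L,
      start_intronic = loc5$intronic, end_intronic = loc3$intronic,
      host_strand_mismatch = j$host_strand_mismatch
    )
  })
}

#' Start-exon distribution and boundary fractions for a genotype
#'
#' The start-exon histogram, the first-exon fraction, and the fraction of
#' circRNAs that "start or end in a known exon" under both readings of that
#' phrase: at an annotated exon boundary exactly, or anywhere within an exon
#' body. Both are reported because either reading is defensible.
#'
#' @param structures [annotate_junctions()] output for one genotype's
#'   consensus set.
#' @return List: `histogram` (tibble `start_exon_index`, `n`, `fraction`),
#'   `frac_first_exon`, `frac_boundary_exact`, `frac_in_exon_body`, `n`.
#' @export
exon_start_distribution <- function(structures) {
  st <- dplyr::filter(structures, !is.na(start_exon_index))
  if (nrow(st) == 0) {
    message("no annotated structures; empty distribution")
    return(list(
      histogram = tibble::tibble(start_exon_index = integer(), n = integer(), fraction = numeric()),
      frac_first_exon = NA_real_, frac_boundary_exact = NA_real_,
      frac_in_exon_body = NA_real_, n = 0L
    ))
  }
  hist <- dplyr::count(st, start_exon_index) |>
    dplyr::mutate(fraction = n / sum(n))
  list(
    histogram = hist,
    frac_first_exon = mean(st$first_exon_flag),
    frac_boundary_exact = mean(st$start_class == "exon_boundary" |
                                 st$end_class == "exon_boundary"),
    frac_in_exon_body = mean(st$start_class %in% c("exon_boundary", "exon_internal") |
                               st$end_class %in% c("exon_boundary", "exon_internal")),
    n = nrow(st)
  )
}
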