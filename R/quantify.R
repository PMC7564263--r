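#' Per-sample library accounting
#'
#' Counts templates by category and derives the effective library size used
#' for normalization: total mapped templates minus templates mapped to the
#' organelle chromosome and to annotated rRNA loci. A template is
#' organelle-mapped when its primary segment lies on an organelle-class
#' chromosome; it is rRNA-mapped when any segment overlaps an annotated rRNA
#' interval by at least `rrna_overlap` of the segment length. The categories
#' are disjoint with precedence organelle > rRNA.
#'
#' @param segments A [read_sam()] tibble for one sample.
#' @param genome A genome bundle carrying chromosome classes and rRNA loci.
#' @param rrna_overlap Minimum fraction of a segment covered by an rRNA
#'   interval (default 0.5).
#' @return One-row tibble: `total_mapped`, `organelle_mapped`,
#'   `rrna_mapped`, `effective_size` (all template counts).
#' @export
count_library_components <- function(segments, genome, rrna_overlap = 0.5) {
  if (!"class" %in% names(genome$chroms)) {
    stop("annotation lacks the chromosome_class attribute needed for library accounting")
  }
  mapped <- dplyr::filter(segments, !is_unmapped, !is_secondary)
  total <- dplyr::n_distinct(mapped$qname)

  org_chroms <- genome$chroms$chrom[genome$chroms$class == "organelle"]
  org_templates <- mapped |>
    dplyr::filter(!is_supplementary, chrom %in% org_chroms) |>
    dplyr::pull(qname) |>
    unique()

  rrna_templates <- character(0)
  if (nrow(genome$rrna) > 0) {
    seg_gr <- GenomicRanges::GRanges(
      mapped$chrom, IRanges::IRanges(mapped$ref_start, mapped$ref_end)
    )
    rrna_gr <- GenomicRanges::GRanges(
      genome$rrna$chrom, IRanges::IRanges(genome$rrna$start, genome$rrna$end)
    )
    ov <- GenomicRanges::findOverlaps(seg_gr, rrna_gr)
    if (length(ov) > 0) {
      qi <- S4Vectors::queryHits(ov)
      inter <- GenomicRanges::pintersect(seg_gr[qi], rrna_gr[S4Vectors::subjectHits(ov)])
      frac <- GenomicRanges::width(inter) / GenomicRanges::width(seg_gr[qi])
      rrna_templates <- unique(mapped$qname[qi[frac >= rrna_overlap]])
    }
  }
  rrna_templates <- setdiff(rrna_templates, org_templates)

  eff <- total - length(org_templates) - length(rrna_templates)
  if (eff <= 0) stop("effective library size is not positive")
  tibble::tibble(
    total_mapped = total,
    organelle_mapped = length(org_templates),
    rrna_mapped = length(rrna_templates),
    effective_size = eff
  )
}

# normalization shared by all matrices: counts per million effective templates
normalize_counts <- function(raw, effective_size) {
  raw / effective_size * 1e6
}

#' Build the circular count matrix across samples
#'
#' The union of junction ids over all samples forms the feature axis; a
#' circRNA absent from a sample gets raw count 0 (never missing). Normalized
#' values are counts per million effective library templates.
#'
#' @param calls Tibble binding per-sample [call_circrnas()] outputs with a
#'   `sample_id` column.
#' @param libraries Tibble with `sample_id` and `effective_size` (see
#'   [count_library_components()]); every sample in `calls` must be present.
#' @return A long tibble (`circ_id`, `sample_id`, `raw`, `norm`) with
#'   attribute `kind = "circular"`; every feature has an entry in every
#'   library sample.
#' @export
build_circ_matrix <- function(calls, libraries) {
  missing <- setdiff(unique(calls$sample_id), libraries$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) absent from library table: ", paste(missing, collapse = ", "))
  }
  feats <- sort(unique(calls$circ_id))
  out <- tidyr::expand_grid(circ_id = feats, sample_id = libraries$sample_id) |>
    dplyr::left_join(
      dplyr::select(calls, circ_id, sample_id, raw = n_junction_reads),
      by = c("circ_id", "sample_id")
    ) |>
    dplyr::mutate(raw = dplyr::coalesce(raw, 0L)) |>
    dplyr::left_join(dplyr::select(libraries, sample_id, effective_size), by = "sample_id") |>
    dplyr::mutate(norm = normalize_counts(raw, effective_size)) |>
    dplyr::select(circ_id, sample_id, raw, norm)
  attr(out, "kind") <- "circular"
  out
}

#' Count linear counterparts of circRNAs
#'
#' Two counters, both restricted to templates that do not support any
#' back-splice junction:
#' * **boundary**: templates with a linearly aligned segment crossing the
#'   circRNA's start or end coordinate, i.e. covering the boundary base and
#'   at least one base outside the circle;
#' * **gene**: templates with any segment overlapping a gene's exon union
#'   (the coarser proxy).
#'
#' @param segments_by_sample Named list of [read_sam()] tibbles
#'   (names = sample ids).
#' @param junctions Tibble of circRNAs (`circ_id`, `chrom`, `start`, `end`)
#'   whose linear counterparts are counted; typically the union of calls.
#' @param genome A genome bundle.
#' @param libraries Library table with `sample_id`, `effective_size`.
#' @param slack Passed to [call_backsplice()] when identifying back-spliced
#'   templates to exclude.
#' @return List of two long tibbles, `boundary` (`circ_id`, `sample_id`,
#'   `raw`, `norm`; kind `linear_boundary`) and `gene` (`gene_id`, ...; kind
#'   `linear_gene`).
#' @export
quantify_linear <- function(segments_by_sample, junctions, genome, libraries, slack = 5L) {
  exon_gr <- GenomicRanges::GRanges(
    genome$exons$chrom, IRanges::IRanges(genome$exons$start, genome$exons$end)
  )
  probe_start <- GenomicRanges::GRanges(
    junctions$chrom, IRanges::IRanges(junctions$start - 1L, junctions$start)
  )
  probe_end <- GenomicRanges::GRanges(
    junctions$chrom, IRanges::IRanges(junctions$end, junctions$end + 1L)
  )

  per_sample <- purrr::imap(segments_by_sample, function(segs, sid) {
    bs_templates <- unique(call_backsplice(segs, slack = slack)$qname)
    lin <- segs |>
      dplyr::filter(!is_unmapped, !is_secondary, !qname %in% bs_templates)
    seg_gr <- GenomicRanges::GRanges(
      lin$chrom, IRanges::IRanges(lin$ref_start, lin$ref_end)
    )
    hit_s <- GenomicRanges::findOverlaps(probe_start, seg_gr, type = "within")
    hit_e <- GenomicRanges::findOverlaps(probe_end, seg_gr, type = "within")
    bnd <- dplyr::bind_rows(
      tibble::tibble(
        circ_id = junctions$circ_id[S4Vectors::queryHits(hit_s)],
        qname = lin$qname[S4Vectors::subjectHits(hit_s)]
      ),
      tibble::tibble(
        circ_id = junctions$circ_id[S4Vectors::queryHits(hit_e)],
        qname = lin$qname[S4Vectors::subjectHits(hit_e)]
      )
    ) |>
      dplyr::distinct() |>
      dplyr::count(circ_id, name = "raw")

    hit_g <- GenomicRanges::findOverlaps(seg_gr, exon_gr)
    gene <- tibble::tibble(
      gene_id = genome$exons$gene_id[S4Vectors::subjectHits(hit_g)],
      qname = lin$qname[S4Vectors::queryHits(hit_g)]
    ) |>
      dplyr::distinct() |>
      dplyr::count(gene_id, name = "raw")
    list(boundary = dplyr::mutate(bnd, sample_id = sid),
         gene = dplyr::mutate(gene, sample_id = sid))
  })

  finish <- function(tabs, feat_col, universe) {
    long <- dplyr::bind_rows(tabs)
    out <- tidyr::expand_grid(
      "{feat_col}" := universe, sample_id = libraries$sample_id
    ) |>
      dplyr::left_join(long, by = c(feat_col, "sample_id")) |>
      dplyr::mutate(raw = dplyr::coalesce(raw, 0L)) |>
      dplyr::left_join(dplyr::select(libraries, sample_id, effective_size), by = "sample_id") |>
      dplyr::mutate(norm = normalize_counts(raw, effective_size)) |>
      dplyr::select(dplyr::all_of(c(feat_col, "sample_id", "raw", "norm")))
    out
  }
  boundary <- finish(purrr::map(per_sample, "boundary"), "circ_id", sort(unique(junctions$circ_id)))
  attr(boundary, "kind") <- "linear_boundary"
  gene <- finish(purrr::map(per_sample, "gene"), "gene_id", sort(unique(genome$genes$gene_id)))
  attr(gene, "kind") <- "linear_gene"
  list(boundary = boundary, gene = gene)
}

#' Per-base read coverage across a gene with a circRNA overlay
#'
#' Depth counts every aligned block (CIGAR M segments) of every mapped
#' record — linear and circular reads alike — across the gene span.
#'
#' @param segments A [read_sam()] tibble for one sample.
#' @param genome A genome bundle.
#' @param gene_id Host gene to profile.
#' @param junction Optional one-row tibble (`start`, `end`) of the circRNA
#'   interval to annotate.
#' @return A `circleaf_coverage` tibble (`chrom`, `pos`, `depth`) with the
#'   gene and junction interval stored as attributes; see
#'   [autoplot.circleaf_coverage()].
#' @export
coverage_profile <- function(segments, genome, gene_id, junction = NULL) {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  segs <- segments |>
    dplyr::filter(!is_unmapped, !is_secondary, chrom == g$chrom,
                  ref_start <= g$end, ref_end >= g$start)
  if (nrow(segs) > 0) {
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      segs$cigar, pos = segs$ref_start, ops = c("M", "=", "X")
    )
    ir <- unlist(blocks, use.names = FALSE)
    cov <- IRanges::coverage(ir, width = g$end + 1L)
    depth <- as.integer(cov)[g$start:g$end]
  } else {
    depth <- rep(0L, g$end - g$start + 1L)
  }
  out <- tibble::tibble(chrom = g$chrom, pos = g$start:g$end, depth = depth)
  attr(out, "gene") <- g
  attr(out, "junction") <- junction
  class(out) <- c("circleaf_coverage", class(out))
  out
}

#' Write a coverage profile as BEDGRAPH
#'
#' @param profile A [coverage_profile()] tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  runs <- rle(profile$depth)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lines <- sprintf(
    "%s\t%d\t%d\t%d",
    profile$chrom[1], profile$pos[starts] - 1L, profile$pos[ends], runs$values
  )
  writeLines(lines, path)
  invisible(path)
}
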