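#' Generate a synthetic multi-chromosome genome with gene models
#'
#' Builds random nuclear chromosomes carrying non-overlapping multi-exon genes
#' on both strands, one organelle chromosome, and annotated rRNA loci. Every
#' intron begins with GT and ends with AG in transcript orientation, and
#' canonical splice signals (acceptor AG upstream, donor GT downstream, in
#' transcript orientation) are placed around *every* exon boundary — including
#' the outer boundaries of first and last exons — so that any exon-bounded
#' back-splice junction carries a canonical signal.
#'
#' @param config A [sim_config()] object.
#' @return A `circleaf_genome` bundle: `seqs` (a
#'   [Biostrings::DNAStringSet]), and tibbles `chroms` (chrom, length, class),
#'   `genes`, `exons` (with `exon_rank` in transcript orientation; on the
#'   minus strand exon 1 is the rightmost genomic exon), and `rrna`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  bases <- c("A", "C", "G", "T")

  nuclear <- sprintf("chr%d", seq_len(config$n_nuclear_chroms))
  genes_per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_nuclear_chroms + 1)))

  rrna_reserve <- config$n_rrna_loci * (config$rrna_length + 100L) + 200L
  seqs <- list()
  genes <- list()
  exons <- list()
  gene_counter <- 0L

  for (ci in seq_along(nuclear)) {
    chrom <- nuclear[ci]
    chars <- sample(bases, config$chrom_length, replace = TRUE)
    usable <- config$chrom_length - if (ci == 1L) rrna_reserve else 0L
    cursor <- 10L
    for (g in seq_len(genes_per_chrom[ci])) {
      gene_counter <- gene_counter + 1L
      gap <- sample(200:800, 1L)
      n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2])
      ex_len <- sample_range(config$exon_length[1], config$exon_length[2], n_ex)
      in_len <- sample_range(config$intron_length[1], config$intron_length[2],
                             max(n_ex - 1L, 0L))
      glen <- sum(ex_len) + sum(in_len)
      gstart <- cursor + gap
      gend <- gstart + glen - 1L
      if (gend + 10L > usable) {
        stop(
          "requested gene content exceeds chromosome capacity on ", chrom,
          ": gene ", gene_counter, " would end at ", gend,
          " but only ", usable, " usable bases are available; reduce n_genes",
          " or increase chrom_length"
        )
      }
      strand <- sample(c("+", "-"), 1L)
      ex_start <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ex_end <- ex_start + ex_len - 1L
      gene_id <- sprintf("G%04d", gene_counter)

      # splice-signal planting (plus-strand letters, transcript orientation rules)
      if (strand == "+") {
        acc <- c("A", "G"); don <- c("G", "T")
      } else {
        acc <- c("A", "C"); don <- c("C", "T")
      }
      for (i in seq_len(n_ex)) {
        chars[(ex_start[i] - 2L):(ex_start[i] - 1L)] <- acc
        chars[(ex_end[i] + 1L):(ex_end[i] + 2L)] <- don
      }

      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      genes[[gene_counter]] <- tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = gstart, end = gend, n_exons = n_ex
      )
      exons[[gene_counter]] <- tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        exon_rank = rank, start = ex_start, end = ex_end
      )
      cursor <- gend
    }
    seqs[[chrom]] <- chars
  }

  # rRNA loci in the reserved tail of chr1
  rrna_start <- config$chrom_length - rrna_reserve + 100L +
    (seq_len(config$n_rrna_loci) - 1L) * (config$rrna_length + 100L)
  rrna <- tibble::tibble(
    rrna_id = sprintf("rRNA%d", seq_len(config$n_rrna_loci)),
    chrom = nuclear[1],
    start = as.integer(rrna_start),
    end = as.integer(rrna_start + config$rrna_length - 1L)
  )

  seqs[["chrC"]] <- sample(bases, config$organelle_length, replace = TRUE)

  seq_set <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  chroms <- tibble::tibble(
    chrom = names(seq_set),
    length = Biostrings::width(seq_set),
    class = c(rep("nuclear", length(nuclear)), "organelle")
  )

  structure(
    list(
      seqs = seq_set,
      chroms = chroms,
      genes = dplyr::bind_rows(genes),
      exons = dplyr::bind_rows(exons) |> dplyr::arrange(gene_id, start),
      rrna = rrna
    ),
    class = "circleaf_genome"
  )
}

#' @export
print.circleaf_genome <- function(x, ...) {
  cat("<circleaf genome bundle>\n")
  cat(sprintf(
    "  %d chromosome(s), %s bp total; %d genes, %d exons, %d rRNA loci\n",
    nrow(x$chroms), format(sum(x$chroms$length), big.mark = ","),
    nrow(x$genes), nrow(x$exons), nrow(x$rrna)
  ))
  invisible(x)
}

#' Write a genome bundle as FASTA + GFF3
#'
#' The organelle chromosome is flagged through a `chromosome_class` attribute
#' on its `region` feature; exons carry `exon_rank` (transcript orientation)
#' and a `Parent` gene attribute; rRNA loci are typed `rRNA`.
#'
#' @param genome A `circleaf_genome` bundle.
#' @param fasta,gff Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  Biostrings::writeXStringSet(genome$seqs, fasta)

  region <- GenomicRanges::GRanges(
    genome$chroms$chrom, IRanges::IRanges(1, genome$chroms$length),
    type = "region",
    ID = genome$chroms$chrom,
    chromosome_class = genome$chroms$class
  )
  gene_gr <- GenomicRanges::GRanges(
    genome$genes$chrom, IRanges::IRanges(genome$genes$start, genome$genes$end),
    strand = genome$genes$strand, type = "gene", ID = genome$genes$gene_id
  )
  exon_gr <- GenomicRanges::GRanges(
    genome$exons$chrom, IRanges::IRanges(genome$exons$start, genome$exons$end),
    strand = genome$exons$strand, type = "exon",
    ID = sprintf("%s.e%d", genome$exons$gene_id, genome$exons$exon_rank),
    Parent = genome$exons$gene_id,
    exon_rank = genome$exons$exon_rank
  )
  rrna_gr <- GenomicRanges::GRanges(
    genome$rrna$chrom, IRanges::IRanges(genome$rrna$start, genome$rrna$end),
    type = "rRNA", ID = genome$rrna$rrna_id
  )
  gr <- suppressWarnings(c(region, gene_gr, exon_gr, rrna_gr))
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a FASTA + GFF3 pair back into a genome bundle
#'
#' Expects the conventions written by [write_genome()]: `region` features
#' carrying a `chromosome_class` attribute, `exon` features with `Parent` and
#' `exon_rank`, and `rRNA` features. A GFF3 without `chromosome_class`
#' attributes is rejected because downstream library accounting needs the
#' organelle flag.
#'
#' @param fasta,gff Input paths.
#' @return A `circleaf_genome` bundle.
#' @export
read_genome <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))

  regions <- dplyr::filter(df, type == "region")
  if (nrow(regions) == 0 || !"chromosome_class" %in% names(df)) {
    stop("annotation lacks chromosome_class attributes on region features")
  }
  chroms <- tibble::tibble(
    chrom = as.character(regions$seqnames),
    length = Biostrings::width(seqs)[match(as.character(regions$seqnames), names(seqs))],
    class = as.character(regions$chromosome_class)
  )
  genes_df <- dplyr::filter(df, type == "gene")
  exons_df <- dplyr::filter(df, type == "exon")
  parent <- vapply(exons_df$Parent, function(p) as.character(p)[1], "")
  genes <- tibble::tibble(
    gene_id = as.character(genes_df$ID),
    chrom = as.character(genes_df$seqnames),
    strand = as.character(genes_df$strand),
    start = genes_df$start, end = genes_df$end
  )
  exons <- tibble::tibble(
    gene_id = parent,
    chrom = as.character(exons_df$seqnames),
    strand = as.character(exons_df$strand),
    exon_rank = as.integer(exons_df$exon_rank),
    start = exons_df$start, end = exons_df$end
  ) |> dplyr::arrange(gene_id, start)
  cnt <- dplyr::count(exons, gene_id)
  genes$n_exons <- cnt$n[match(genes$gene_id, cnt$gene_id)]
  rrna_df <- dplyr::filter(df, type == "rRNA")
  rrna <- tibble::tibble(
    rrna_id = as.character(rrna_df$ID),
    chrom = as.character(rrna_df$seqnames),
    start = rrna_df$start, end = rrna_df$end
  )
  structure(
    list(seqs = seqs, chroms = chroms, genes = genes, exons = exons, rrna = rrna),
    class = "circleaf_genome"
  )
}
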