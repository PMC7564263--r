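# Shared fixtures, all built in code.

# A small constructed genome: one nuclear chromosome with a 4-exon gene on
# each strand (canonical splice signals planted around every exon boundary),
# an rRNA locus, and an organelle chromosome. Coordinates are hand-picked so
# tests can reason about them explicitly.
tiny_genome <- function(seed = 42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, 3000, replace = TRUE)

  plus_exons <- cbind(start = c(101L, 301L, 521L, 741L), end = c(200L, 420L, 640L, 860L))
  for (i in seq_len(4)) {
    chars[(plus_exons[i, 1] - 2L):(plus_exons[i, 1] - 1L)] <- c("A", "G")
    chars[(plus_exons[i, 2] + 1L):(plus_exons[i, 2] + 2L)] <- c("G", "T")
  }
  minus_exons <- cbind(start = c(1101L, 1301L, 1521L, 1741L), end = c(1200L, 1420L, 1640L, 1860L))
  for (i in seq_len(4)) {
    chars[(minus_exons[i, 1] - 2L):(minus_exons[i, 1] - 1L)] <- c("A", "C")
    chars[(minus_exons[i, 2] + 1L):(minus_exons[i, 2] + 2L)] <- c("C", "T")
  }

  seqs <- Biostrings::DNAStringSet(c(
    chrT = paste0(chars, collapse = ""),
    chrM = paste0(sample(bases, 500, replace = TRUE), collapse = "")
  ))
  structure(
    list(
      seqs = seqs,
      chroms = tibble::tibble(
        chrom = c("chrT", "chrM"), length = c(3000L, 500L),
        class = c("nuclear", "organelle")
      ),
      genes = tibble::tibble(
        gene_id = c("GP", "GM"), chrom = "chrT", strand = c("+", "-"),
        start = c(101L, 1101L), end = c(860L, 1860L), n_exons = 4L
      ),
      exons = tibble::tibble(
        gene_id = rep(c("GP", "GM"), each = 4),
        chrom = "chrT",
        strand = rep(c("+", "-"), each = 4),
        exon_rank = c(1:4, 4:1),
        start = c(plus_exons[, 1], minus_exons[, 1]),
        end = c(plus_exons[, 2], minus_exons[, 2])
      ),
      rrna = tibble::tibble(rrna_id = "rRNA1", chrom = "chrT", start = 2501L, end = 2700L)
    ),
    class = "circleaf_genome"
  )
}

# build a segment tibble row the way read_sam() would represent it
seg_row <- function(qname, chrom, strand, ref_start, ref_end,
                    read_start, read_end, mate = 1L, flag = NULL,
                    is_supplementary = FALSE) {
  tibble::tibble(
    qname = qname, flag = flag %||% 0L, chrom = chrom,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    mapq = 60L, cigar = "*", strand = strand, mate = as.integer(mate),
    is_supplementary = is_supplementary, is_secondary = FALSE,
    is_unmapped = FALSE,
    read_start = as.integer(read_start), read_end = as.integer(read_end),
    read_len = as.integer(read_end), seq = "*"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# plus-strand sequence extraction used by oracle checks
genome_seq_test <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome$seqs[[chrom]], start, end))
}

# transcript-orientation exon map rebuilt independently of the package
gene_exon_map_test <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$exon_rank), ]
  tibble::tibble(
    chrom = ex$chrom, strand = ex$strand, exon_rank = ex$exon_rank,
    gstart = ex$start, gend = ex$end
  )
}

# small simulated study shared across tests (cheaper than the full demo)
small_config <- function(seed = 11) {
  sim_config(
    seed = seed,
    n_nuclear_chroms = 1L, chrom_length = 400000L, n_genes = 60L,
    organelle_length = 50000L, n_rrna_loci = 2L,
    genotypes = c("wt", "mutA"), n_replicates = 3L,
    depth = 15, n_circ = 14L,
    circ_fold_changes = list(mutA = list(n_up = 2, fold_up = 4, n_down = 1, fold_down = 0.25))
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_study <- function() {
  cached("small_study", {
    cfg <- small_config()
    genome <- simulate_genome(cfg)
    manifest <- simulate_truth(cfg, genome)
    dir <- file.path(tempdir(), "circleaf_small_study")
    files <- simulate_reads(manifest, genome, cfg, dir)
    segs <- stats::setNames(lapply(files$sam, read_sam), files$sample_id)
    calls <- dplyr::bind_rows(purrr::imap(segs, function(s, sid) {
      dplyr::mutate(call_circrnas(s, genome), sample_id = sid)
    }))
    list(config = cfg, genome = genome, manifest = manifest, files = files,
         segments = segs, calls = calls)
  })
}

# full-scale demo study used by the acceptance tests
demo_study <- function(seed = 101) {
  cached(paste0("demo_study_", seed), {
    cfg <- sim_config(seed = seed)
    genome <- simulate_genome(cfg)
    manifest <- simulate_truth(cfg, genome)
    dir <- file.path(tempdir(), paste0("circleaf_demo_", seed))
    files <- simulate_reads(manifest, genome, cfg, dir)
    segs <- stats::setNames(lapply(files$sam, read_sam), files$sample_id)
    calls <- dplyr::bind_rows(purrr::imap(segs, function(s, sid) {
      dplyr::mutate(call_circrnas(s, genome), sample_id = sid)
    }))
    list(config = cfg, genome = genome, manifest = manifest, files = files,
         segments = segs, calls = calls)
  })
}
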