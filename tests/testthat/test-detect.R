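test_that("only the chiastic segment ordering yields a junction call", {
  # enumerate segment arrangements of a constructed two-segment read group
  make_group <- function(p_rs, p_re, q_rs, q_re, chrom2 = "chrT", strand2 = "+") {
    dplyr::bind_rows(
      seg_row("r1", "chrT", "+", p_rs, p_re, read_start = 1L, read_end = 60L),
      seg_row("r1", chrom2, strand2, q_rs, q_re, read_start = 61L, read_end = 120L,
              is_supplementary = TRUE)
    )
  }
  # chiastic: prefix maps downstream [981..1040], suffix upstream [201..260]
  bs <- call_backsplice(make_group(981, 1040, 201, 260))
  expect_identical(nrow(bs), 1L)
  expect_identical(bs$start, 201L)
  expect_identical(bs$end, 1040L)
  # forward-spliced order: prefix upstream -> no call
  expect_identical(nrow(call_backsplice(make_group(201, 260, 981, 1040))), 0L)
  # different chromosomes -> no call
  expect_identical(nrow(call_backsplice(make_group(981, 1040, 201, 260, chrom2 = "chrX"))), 0L)
  # different strands -> no call
  expect_identical(nrow(call_backsplice(make_group(981, 1040, 201, 260, strand2 = "-"))), 0L)
})

test_that("minus-strand chiastic geometry swaps the genomic roles of the arms", {
  grp <- dplyr::bind_rows(
    seg_row("m1", "chrT", "-", 201, 260, read_start = 1L, read_end = 60L),
    seg_row("m1", "chrT", "-", 981, 1040, read_start = 61L, read_end = 120L,
            is_supplementary = TRUE)
  )
  bs <- call_backsplice(grp)
  expect_identical(nrow(bs), 1L)
  expect_identical(bs$start, 201L)
  expect_identical(bs$end, 1040L)
  expect_identical(bs$strand, "-")
  # the mirrored arrangement is forward splicing on the minus strand
  grp2 <- dplyr::bind_rows(
    seg_row("m2", "chrT", "-", 981, 1040, read_start = 1L, read_end = 60L),
    seg_row("m2", "chrT", "-", 201, 260, read_start = 61L, read_end = 120L,
            is_supplementary = TRUE)
  )
  expect_identical(nrow(call_backsplice(grp2)), 0L)
})

test_that("read-interval overlap beyond the slack rejects a group", {
  grp <- function(overlap) {
    dplyr::bind_rows(
      seg_row("r", "chrT", "+", 981, 1040, read_start = 1L, read_end = 60L),
      seg_row("r", "chrT", "+", 201, 260, read_start = 61L - overlap, read_end = 120L - overlap,
              is_supplementary = TRUE)
    )
  }
  expect_identical(nrow(call_backsplice(grp(5L))), 1L)
  expect_identical(nrow(call_backsplice(grp(6L))), 0L)
})

test_that("splice-signal check matches definitions on both strands", {
  g <- tiny_genome()
  # plus-strand gene GP: circle over exons 2..3 has AG upstream, GT downstream
  jp <- tibble::tibble(chrom = "chrT", strand = "+", start = 301L, end = 640L)
  expect_true(check_splice_signal(jp, g)$canonical_signal)
  # shifted by one base the signal is gone
  expect_false(check_splice_signal(dplyr::mutate(jp, start = 302L), g)$canonical_signal)
  # minus-strand gene GM: plus-strand text shows AC upstream / CT downstream
  jm <- tibble::tibble(chrom = "chrT", strand = "-", start = 1301L, end = 1640L)
  expect_true(check_splice_signal(jm, g)$canonical_signal)
  # chromosome edge: junction too close to the edge is never canonical
  je <- tibble::tibble(chrom = "chrT", strand = "+", start = 1L, end = 2999L)
  expect_false(check_splice_signal(je, g)$canonical_signal)
})

test_that("minus-strand signal equals the reverse-complement oracle on a constructed sequence", {
  # 30-nt sequence with a minus-strand circle at [11, 20]: in transcript
  # orientation (reverse complement) the donor GT must follow position 11
  # and the acceptor AG precede position 20
  seq30 <- paste0(
    "AAAAAAAA", "AC", "CCCCCCCCCC", "CT", "AAAAAAAA"
  )
  g <- structure(list(
    seqs = Biostrings::DNAStringSet(c(c30 = seq30)),
    chroms = tibble::tibble(chrom = "c30", length = 30L, class = "nuclear"),
    genes = tibble::tibble(), exons = tibble::tibble(),
    rrna = tibble::tibble(rrna_id = character(), chrom = character(),
                          start = integer(), end = integer())
  ), class = "circleaf_genome")
  j <- tibble::tibble(chrom = "c30", strand = "-", start = 11L, end = 20L)
  expect_true(check_splice_signal(j, g)$canonical_signal)
  # oracle: on the reverse complement, bases right after the (flipped) end
  # must read G,T and right before the (flipped) start A,G
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq30)))
  rc_start <- 30 - 20 + 1; rc_end <- 30 - 11 + 1
  expect_identical(substr(rc, rc_end + 1, rc_end + 2), "GT")
  expect_identical(substr(rc, rc_start - 2, rc_start - 1), "AG")
})

test_that("read thresholds and the signal filter behave exactly", {
  study <- small_study()
  genome <- study$genome
  segs <- study$segments[[1]]
  truth <- study$manifest$circ_counts
  sid <- names(study$segments)[1]
  t1 <- truth[truth$sample_id == sid, ]

  calls2 <- call_circrnas(segs, genome, min_reads = 2)
  # a junction with exactly 1 supporting template is never called at min_reads = 2
  singletons <- t1$circ_id[t1$count == 1]
  expect_false(any(singletons %in% calls2$circ_id))
  # with >= 2 supporting templates (and a canonical signal) always called
  expect_true(all(t1$circ_id[t1$count >= 2] %in% calls2$circ_id))

  # permissive mode reports every chiastic junction
  calls1 <- call_circrnas(segs, genome, min_reads = 1, require_signal = FALSE)
  expect_true(all(t1$circ_id[t1$count >= 1] %in% calls1$circ_id))

  # monotonicity: raising min_reads never adds a call; relaxing the signal
  # filter never removes one
  calls3 <- call_circrnas(segs, genome, min_reads = 3)
  expect_true(all(calls3$circ_id %in% calls2$circ_id))
  expect_true(all(calls2$circ_id %in% calls1$circ_id))
})

test_that("junction evidence is counted per template, not per mate", {
  # both mates of one template supporting the same junction count once
  grp <- dplyr::bind_rows(
    seg_row("t1", "chrT", "+", 981, 1040, read_start = 1L, read_end = 60L, mate = 1L),
    seg_row("t1", "chrT", "+", 201, 260, read_start = 61L, read_end = 120L, mate = 1L,
            is_supplementary = TRUE),
    seg_row("t1", "chrT", "+", 981, 1040, read_start = 1L, read_end = 60L, mate = 2L),
    seg_row("t1", "chrT", "+", 201, 260, read_start = 61L, read_end = 120L, mate = 2L,
            is_supplementary = TRUE),
    seg_row("t2", "chrT", "+", 981, 1040, read_start = 1L, read_end = 60L, mate = 1L),
    seg_row("t2", "chrT", "+", 201, 260, read_start = 61L, read_end = 120L, mate = 1L,
            is_supplementary = TRUE)
  )
  g <- tiny_genome()
  calls <- call_circrnas(grp, g, min_reads = 1, require_signal = FALSE)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_junction_reads, 2L)
})

test_that("junction ids round-trip through the parser", {
  study <- small_study()
  calls <- study$calls
  parsed <- parse_circ_id(calls$circ_id)
  expect_identical(parsed$chrom, calls$chrom)
  expect_identical(parsed$start, calls$start)
  expect_identical(parsed$end, calls$end)
  expect_error(parse_circ_id("chr1:banana"), "malformed")
})

test_that("SAM parsing flags malformed records and rejects headerless files", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrT\tLN:3000",
    "ok1\t0\tchrT\t100\t60\t50M\t*\t0\t0\tAAAA\tIIII",
    "broken\trecord",
    "ok2\t16\tchrT\t200\t60\t10S40M\t*\t0\t0\tAAAA\tIIII"
  ), p)
  expect_warning(segs <- read_sam(p), "malformed")
  expect_identical(nrow(segs), 2L)
  expect_identical(attr(segs, "malformed"), 1L)
  # clip-aware original-read offsets: reverse strand counts from the read 3' clip
  expect_identical(segs$read_start[segs$qname == "ok2"], 1L)
  expect_identical(segs$read_end[segs$qname == "ok2"], 40L)
  expect_identical(segs$ref_end[segs$qname == "ok2"], 239L)

  writeLines("noheader\t0\tchrT\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII", p)
  expect_error(read_sam(p), "header")
})

test_that("concordance arithmetic and degenerate cases", {
  mk <- function(ids) tibble::tibble(circ_id = ids)
  same <- concordance(mk(c("a", "b")), mk(c("a", "b")))
  expect_identical(same$frac_a_in_b, 1)
  expect_identical(concordance(mk("a"), mk("b"))$frac_a_in_b, 0)
  x <- concordance(mk(c("x", "y", "z", "w", "v")), mk(c("x", "y", "z", "w", "q")))
  expect_identical(x$frac_a_in_b, 0.8)
  expect_identical(x$jaccard, 4 / 6)
  expect_warning(e <- concordance(mk(character(0)), mk("a")), "empty")
  expect_true(is.na(e$frac_a_in_b))
})
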