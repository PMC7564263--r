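test_that("host-gene assignment: containment, exonic-overlap tie-break, deserts", {
  g <- tiny_genome()
  # junction inside the plus-strand gene
  j1 <- tibble::tibble(circ_id = "chrT:301-640", chrom = "chrT", strand = "+",
                       start = 301L, end = 640L)
  expect_identical(assign_host_gene(j1, g)$host_gene, "GP")
  # gene desert
  j2 <- tibble::tibble(circ_id = "chrT:2000-2300", chrom = "chrT", strand = "+",
                       start = 2000L, end = 2300L)
  expect_true(is.na(assign_host_gene(j2, g)$host_gene))
  # wrong-strand junction falls back strand-agnostically with a flag
  j3 <- tibble::tibble(circ_id = "chrT:301-640", chrom = "chrT", strand = "-",
                       start = 301L, end = 640L)
  a3 <- assign_host_gene(j3, g)
  expect_identical(a3$host_gene, "GP")
  expect_true(a3$host_strand_mismatch)
})

test_that("overlapping genes resolve by exonic overlap, computed brute force", {
  # two nested genes on one strand; gene B's exons cover more of the junction
  g <- tiny_genome()
  g$genes <- tibble::tibble(
    gene_id = c("GA", "GB"), chrom = "chrT", strand = "+",
    start = c(100L, 100L), end = c(1000L, 900L), n_exons = c(2L, 1L)
  )
  g$exons <- tibble::tibble(
    gene_id = c("GA", "GA", "GB"), chrom = "chrT", strand = "+",
    exon_rank = c(1L, 2L, 1L),
    start = c(100L, 900L, 150L), end = c(180L, 1000L, 850L)
  )
  j <- tibble::tibble(circ_id = "chrT:200-800", chrom = "chrT", strand = "+",
                      start = 200L, end = 800L)
  # brute-force overlap: GA exons cover 0 bases of [200, 800], GB covers 651
  brute <- vapply(c("GA", "GB"), function(id) {
    ex <- g$exons[g$exons$gene_id == id, ]
    sum(pmax(0, pmin(ex$end, 800) - pmax(ex$start, 200) + 1))
  }, numeric(1))
  expect_identical(names(which.max(brute)), "GB")
  # assignment must require span containment first, then prefer GB
  expect_identical(assign_host_gene(j, g)$host_gene, "GB")
})

test_that("start-exon indexing follows transcript orientation on both strands", {
  g <- tiny_genome()
  # plus-strand gene: start at exon 2's genomic start -> index 2, not first
  jp <- tibble::tibble(chrom = "chrT", strand = "+", start = 301L, end = 640L)
  sp <- start_exon_index(jp, g, "GP")
  expect_identical(sp$index, 2L)
  expect_false(sp$first_exon)
  expect_false(sp$intronic)
  # minus-strand gene: the junction's genomic END at the rightmost exon is exon 1
  jm <- tibble::tibble(chrom = "chrT", strand = "-", start = 1301L, end = 1860L)
  sm <- start_exon_index(jm, g, "GM")
  expect_identical(sm$index, 1L)
  expect_true(sm$first_exon)
  # strand-flip oracle: on the minus strand the transcript-5' endpoint is the
  # genomic end, and exon ranks run right to left
  ex <- g$exons[g$exons$gene_id == "GM", ]
  oracle_rank <- ex$exon_rank[ex$start <= 1860 & ex$end >= 1860]
  expect_identical(sm$index, oracle_rank)
  # mid-intron start: next downstream exon with the intronic flag
  ji <- tibble::tibble(chrom = "chrT", strand = "+", start = 450L, end = 640L)
  si <- start_exon_index(ji, g, "GP")
  expect_identical(si$index, 3L)
  expect_true(si$intronic)
  # endpoint outside the gene span is a structural inconsistency
  jo <- tibble::tibble(chrom = "chrT", strand = "+", start = 50L, end = 640L)
  expect_error(start_exon_index(jo, g, "GP"), "outside")
})

test_that("boundary classes match an exhaustive brute-force scan on both strands", {
  g <- tiny_genome()
  for (gene in c("GP", "GM")) {
    map <- gene_exon_map_test(g, gene)
    strand <- map$strand[1]
    lo <- min(map$gstart) - 30L
    hi <- max(map$gend) + 30L
    for (side in c("start", "end")) {
      # independent oracle: plain interval scan over the exon table
      acceptor_side <- (side == "start")
      for (pos in seq(lo, hi, by = 1L)) {
        edge <- if (acceptor_side == (strand == "+")) map$gstart else map$gend
        oracle <- if (pos %in% edge) {
          "exon_boundary"
        } else if (any(map$gstart <= pos & map$gend >= pos)) {
          "exon_internal"
        } else if (pos >= min(map$gstart) && pos <= max(map$gend)) {
          "intron"
        } else {
          "intergenic"
        }
        expect_identical(boundary_class(pos, side, map), oracle,
                         label = sprintf("%s %s at %d", gene, side, pos))
      }
    }
  }
})

test_that("boundary tolerance admits near-boundary coordinates", {
  g <- tiny_genome()
  map <- gene_exon_map_test(g, "GP")
  expect_identical(boundary_class(303L, "start", map, tolerance = 0L), "exon_internal")
  expect_identical(boundary_class(303L, "start", map, tolerance = 2L), "exon_boundary")
})

test_that("full annotation is strand-symmetric and matches the manifest", {
  study <- small_study()
  man <- study$manifest
  jx <- dplyr::select(man$circ_ref, circ_id, chrom, strand, start, end)
  st <- annotate_junctions(jx, study$genome)
  expect_identical(nrow(st), nrow(jx))
  merged <- dplyr::inner_join(st, man$circ_ref, by = "circ_id")
  # host gene and transcript-orientation start exon agree with the truth
  expect_identical(merged$host_gene.x, merged$host_gene.y)
  expect_identical(merged$start_exon_index, as.integer(merged$exon_from))
  # endpoints on annotated boundaries classify as exon_boundary; shifted
  # endpoints as exon_internal (start side in transcript orientation)
  t5_at_boundary <- ifelse(merged$strand == "+", merged$at_start_boundary,
                           merged$at_end_boundary)
  expect_identical(merged$start_class == "exon_boundary", t5_at_boundary)
  expect_true(all(merged$start_class[!t5_at_boundary] == "exon_internal"))
})

test_that("exon-start distributions normalize and expose the first-exon fraction", {
  st <- tibble::tibble(
    circ_id = sprintf("c%d", 1:5),
    host_gene = "G", start_exon_index = c(2L, 2L, 2L, 1L, 3L),
    end_exon_index = 3L,
    start_class = c("exon_boundary", "exon_boundary", "exon_internal", "exon_boundary", "intron"),
    end_class = c("exon_boundary", "intron", "intron", "exon_boundary", "intron"),
    first_exon_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    start_intronic = FALSE, end_intronic = FALSE, host_strand_mismatch = FALSE
  )
  d <- exon_start_distribution(st)
  expect_equal(sum(d$histogram$fraction), 1)
  expect_equal(d$histogram$fraction[d$histogram$start_exon_index == 2], 0.6)
  expect_equal(d$frac_first_exon, 0.2)
  # both readings of "starts or ends in a known exon"
  expect_equal(d$frac_boundary_exact, 3 / 5)
  expect_equal(d$frac_in_exon_body, 4 / 5)
  # empty input yields an empty table, not an error
  expect_message(e <- exon_start_distribution(st[0, ]), "empty")
  expect_identical(e$n, 0L)
})
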