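test_that("config validation rejects impossible designs", {
  expect_error(sim_config(frac_sporadic_circ = 0.7, frac_reproducible_circ = 0.5), "<= 1")
  expect_error(sim_config(sporadic_inclusion = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(exon_length = c(300, 80)), "range")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(circ_fold_changes = list(nope = list(n_up = 1, fold_up = 2))),
               "unknown genotype")
  expect_error(sim_config(circ_fold_changes = list(col0 = list(n_up = 1, fold_up = 2))),
               "wild-type")
  expect_error(sim_config(read_length = 250L), "read_length")
})

test_that("generated genes have GT..AG introns and requested structure", {
  cfg <- sim_config(
    seed = 3, n_nuclear_chroms = 1L, chrom_length = 200000L, n_genes = 20L,
    exons_per_gene = c(3L, 3L), n_rrna_loci = 2L
  )
  g <- simulate_genome(cfg)
  expect_true(all(dplyr::count(g$exons, gene_id)$n == 3L))
  # every intron starts GT and ends AG in transcript orientation
  introns <- g$exons |>
    dplyr::arrange(gene_id, start) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      istart = list(end[-dplyr::n()] + 1L), iend = list(start[-1] - 1L),
      strand = strand[1], chrom = chrom[1], .groups = "drop"
    ) |>
    tidyr::unnest(c(istart, iend))
  for (i in seq_len(nrow(introns))) {
    don <- genome_seq_test(g, introns$chrom[i], introns$istart[i], introns$istart[i] + 1L)
    acc <- genome_seq_test(g, introns$chrom[i], introns$iend[i] - 1L, introns$iend[i])
    if (introns$strand[i] == "+") {
      expect_identical(paste0(don, acc), "GTAG")
    } else {
      # minus strand: plus-strand text reads CT (acceptor) ... AC (donor)
      expect_identical(paste0(don, acc), "CTAC")
    }
  }
  expect_identical(nrow(g$rrna), 2L)
  expect_identical(g$chroms$class, c("nuclear", "organelle"))
})

test_that("same config and seed give byte-identical FASTA/GFF3 and manifests", {
  cfg <- sim_config(seed = 5, n_nuclear_chroms = 1L, chrom_length = 120000L,
                    n_genes = 10L, n_circ = 6L, organelle_length = 20000L,
                    genotypes = c("wt", "m1"), n_replicates = 2L, depth = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    g <- simulate_genome(cfg)
    write_genome(g, file.path(d, "g.fa"), file.path(d, "g.gff3"))
    m <- simulate_truth(cfg, g)
    write_manifest(m, file.path(d, "m.json"))
    simulate_reads(m, g, cfg, file.path(d, "aln"), write_fastq = FALSE)
  }
  for (f in c("g.fa", "g.gff3", "m.json", "aln/wt_r1.sam", "aln/m1_r2.sam")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
})

test_that("oversized gene content triggers a capacity error", {
  cfg <- sim_config(n_nuclear_chroms = 1L, chrom_length = 50000L, n_genes = 100L)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("genome bundle round-trips through FASTA + GFF3", {
  cfg <- small_config()
  g <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_genome(g, file.path(d, "g.fa"), file.path(d, "g.gff3"))
  g2 <- read_genome(file.path(d, "g.fa"), file.path(d, "g.gff3"))
  expect_identical(as.character(g2$seqs), as.character(g$seqs))
  expect_equal(g2$chroms, g$chroms)
  expect_equal(
    dplyr::arrange(g2$exons, gene_id, start),
    dplyr::arrange(g$exons[names(g2$exons)], gene_id, start)
  )
  expect_equal(g2$rrna, g$rrna)
})

test_that("fold changes scale circRNA means only; empty map leaves genotypes exchangeable", {
  study <- small_study()
  man <- study$manifest
  # spiked circRNA: manifest realized counts should track fold * base mean
  spikes <- man$fold_map
  expect_gt(nrow(spikes), 0)
  counts <- dplyr::left_join(man$circ_counts, man$samples, by = "sample_id")
  for (i in seq_len(nrow(spikes))) {
    base <- man$circ_ref$base_mean[man$circ_ref$circ_id == spikes$circ_id[i]]
    mut_mean <- mean(counts$count[counts$circ_id == spikes$circ_id[i] &
                                    counts$genotype == spikes$genotype[i]])
    # NB noise at n = 3: generous band around fold * base
    expect_gt(mut_mean, 0.25 * spikes$fold[i] * base)
    expect_lt(mut_mean, 4 * spikes$fold[i] * base)
  }
  # linear gene counts: same means in all genotypes by construction
  gm <- dplyr::left_join(man$gene_counts, man$samples, by = "sample_id") |>
    dplyr::group_by(gene_id, genotype) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = genotype, values_from = m)
  expect_gt(stats::cor(gm$wt, gm$mutA), 0.6)
  # and no systematic genotype shift in linear abundance
  expect_lt(abs(log2(mean(gm$mutA) / mean(gm$wt))), 0.2)

  # null case: empty fold map leaves per-genotype circ means exchangeable
  cfg0 <- sim_config(seed = 21, n_nuclear_chroms = 1L, chrom_length = 300000L,
                     n_genes = 40L, n_circ = 10L, genotypes = c("a", "b"),
                     n_replicates = 4L, depth = 5, circ_fold_changes = list())
  g0 <- simulate_genome(cfg0)
  m0 <- simulate_truth(cfg0, g0)
  expect_identical(nrow(m0$fold_map), 0L)
})

test_that("sporadic all-replicate fraction matches the binomial oracle", {
  # all-sporadic pool: P(present in all n replicates) = p^n per genotype;
  # estimated across many seeds against the analytic value
  p <- 0.45; n_rep <- 3L; n_circ <- 30L
  cfg <- sim_config(
    seed = 1, n_nuclear_chroms = 1L, chrom_length = 300000L, n_genes = 40L,
    n_circ = n_circ, frac_sporadic_circ = 1, frac_reproducible_circ = 0,
    sporadic_inclusion = p, genotypes = c("wt", "m1"), n_replicates = n_rep,
    depth = 5, circ_fold_changes = list()
  )
  genome <- simulate_genome(cfg)
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    cfg$seed <- s
    man <- simulate_truth(cfg, genome)
    pres <- man$circ_counts |>
      dplyr::left_join(man$samples, by = "sample_id") |>
      dplyr::filter(genotype == "wt") |>
      dplyr::group_by(circ_id) |>
      dplyr::summarise(all_reps = all(count > 0), .groups = "drop")
    hits <- hits + sum(pres$all_reps)
    total <- total + nrow(pres)
  }
  est <- hits / total
  analytic <- p^n_rep
  se <- sqrt(analytic * (1 - analytic) / total)
  expect_lt(abs(est - analytic), 4 * se + 0.005)
})

test_that("emitted junction reads have the chiastic endpoint geometry", {
  study <- small_study()
  segs <- study$segments[[1]]
  bs <- call_backsplice(segs)
  truth <- study$manifest$circ_ref
  # every back-spliced read's junction matches a manifest circRNA exactly
  ids <- circ_id(bs$chrom, bs$start, bs$end)
  expect_true(all(ids %in% truth$circ_id))
  # prefix segment ends at the circle end, suffix starts at the circle start
  one <- bs[1, ]
  pair <- segs |>
    dplyr::filter(qname == one$qname, mate == 1L) |>
    dplyr::arrange(read_start)
  if (one$strand == "+") {
    expect_identical(pair$ref_end[1], one$end)
    expect_identical(pair$ref_start[2], one$start)
  } else {
    expect_identical(pair$ref_start[1], one$start)
    expect_identical(pair$ref_end[2], one$end)
  }
})

test_that("per-sample record counts and library categories are conserved", {
  study <- small_study()
  man <- study$manifest
  for (i in seq_len(2)) {
    sid <- study$files$sample_id[i]
    segs <- study$segments[[sid]]
    libr <- man$library[man$library$sample_id == sid, ]
    expect_identical(dplyr::n_distinct(segs$qname), as.integer(libr$total))
    expect_identical(sum(startsWith(segs$qname, paste0(sid, ":O"))) ,
                     as.integer(libr$organelle))
    # manifest totals are internally consistent
    expect_identical(
      as.integer(libr$total),
      as.integer(libr$junction + libr$linear + libr$organelle + libr$rrna)
    )
  }
})

test_that("a circRNA-free manifest yields no chiastic read groups", {
  cfg <- sim_config(seed = 9, n_nuclear_chroms = 1L, chrom_length = 200000L,
                    n_genes = 25L, n_circ = 0L, frac_sporadic_circ = 0,
                    frac_reproducible_circ = 0, genotypes = c("wt", "m1"),
                    n_replicates = 2L, depth = 8, circ_fold_changes = list())
  g <- simulate_genome(cfg)
  man <- simulate_truth(cfg, g)
  d <- withr::local_tempdir()
  files <- simulate_reads(man, g, cfg, d, write_fastq = FALSE)
  for (p in files$sam) {
    expect_identical(nrow(call_backsplice(read_sam(p))), 0L)
  }
})

test_that("canonical splice signals flank every manifest circRNA", {
  study <- small_study()
  cr <- study$manifest$circ_ref
  expect_true(all(cr$canonical_signal))
  expect_true(all(check_splice_signal(cr, study$genome)$canonical_signal))
})
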