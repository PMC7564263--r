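#' Emit per-sample alignments (SAM) and reads (FASTQ) for a manifest
#'
#' For every true junction template, the junction-spanning mate is written as
#' a chiastic pair of records: the read prefix aligns to a downstream genomic
#' segment ending at the circRNA end, the read suffix to an upstream segment
#' starting at the circRNA start (strand-aware; on the minus strand the
#' genomic roles of the two arms swap). The longer arm becomes the primary
#' record, the shorter a supplementary record; both carry soft clips and SA
#' tags. The other mate aligns contiguously (possibly forward-spliced) inside
#' the circle. Linear templates produce contiguous or forward-spliced (N
#' CIGAR) pairs from the host transcript; contamination reads map inside the
#' organelle chromosome or rRNA loci.
#'
#' Junction reads are emitted with at least 20 bases on each side of the
#' back-splice site, and exon sizes guarantee each arm stays within a single
#' exon, so both the split-alignment detector and the anchor detector face
#' the same evidence.
#'
#' @param manifest A [simulate_truth()] manifest.
#' @param genome The matching genome bundle.
#' @param config The originating [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param write_fastq Also write per-sample FASTQ of the same reads.
#' @return A tibble with per-sample file paths and record/template counts.
#' @export
simulate_reads <- function(manifest, genome, config, outdir, write_fastq = TRUE) {
  set.seed(derive_seed(config$seed, 3L))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  L <- config$read_length
  qual <- strrep("I", L)

  chr_str <- lapply(as.character(genome$seqs), identity)
  tx_pm <- list(); tx_seq <- list()
  for (g in genome$genes$gene_id) {
    m <- gene_exon_map(genome, g)
    tx_pm[[g]] <- as_proj_map(m)
    tx_seq[[g]] <- map_transcript_seq(genome, m)
  }
  cr <- manifest$circ_ref
  c_pm <- list(); c_seq <- list()
  for (i in seq_len(nrow(cr))) {
    m <- circle_exon_map(genome, cr$host_gene[i], cr$start[i], cr$end[i])
    c_pm[[cr$circ_id[i]]] <- as_proj_map(m)
    c_seq[[cr$circ_id[i]]] <- map_transcript_seq(genome, m)
  }

  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chroms$chrom, genome$chroms$length),
    "@PG\tID:circleaf\tPN:circleaf"
  )
  org_chrom <- genome$chroms$chrom[genome$chroms$class == "organelle"][1]
  org_len <- genome$chroms$length[genome$chroms$chrom == org_chrom]

  out <- purrr::map_dfr(seq_len(nrow(manifest$samples)), function(si) {
    sm <- manifest$samples[si, ]
    acc <- list() # each element: a list of parallel record-field vectors

    # --- linear templates ---
    gc <- manifest$gene_counts[manifest$gene_counts$sample_id == sm$sample_id, ]
    gc <- gc[gc$count > 0, ]
    li <- 0L
    for (gi in seq_len(nrow(gc))) {
      g <- gc$gene_id[gi]
      k <- gc$count[gi]
      pm <- tx_pm[[g]]
      tx <- tx_seq[[g]]
      minus <- pm$strand == "-"
      Tl <- pm$t_end[pm$n]
      ins <- min(Tl, config$insert_size)
      a <- if (Tl == ins) rep(1L, k) else sample.int(Tl - ins + 1L, k, replace = TRUE)
      b <- a + ins - L
      p1 <- project_many(pm, a, a + L - 1L)
      p2 <- project_many(pm, b, b + L - 1L)
      s1 <- substring(tx, a, a + L - 1L)
      s2 <- substring(tx, b, b + L - 1L)
      if (minus) { s1 <- revcomp(s1); s2 <- revcomp(s2) }
      f1 <- 1L + 2L + 64L + (if (minus) 16L else 32L)
      f2 <- 1L + 2L + 128L + (if (minus) 32L else 16L)
      qn <- sprintf("%s:L%06d", sm$sample_id, li + seq_len(k))
      li <- li + k
      acc[[length(acc) + 1L]] <- list(
        qname = c(qn, qn), flag = c(rep(f1, k), rep(f2, k)),
        chrom = rep(pm$chrom, 2L * k),
        pos = c(p1$pos, p2$pos), cigar = c(p1$cigar, p2$cigar),
        rnext = rep("=", 2L * k), pnext = c(p2$pos, p1$pos),
        seq = c(s1, s2), tag = rep(NA_character_, 2L * k)
      )
    }

    # --- junction templates ---
    cc <- manifest$circ_counts[manifest$circ_counts$sample_id == sm$sample_id, ]
    cc <- cc[cc$count > 0, ]
    ji <- 0L
    for (ci in seq_len(nrow(cc))) {
      id <- cc$circ_id[ci]
      k <- cc$count[ci]
      pm <- c_pm[[id]]
      ct <- c_seq[[id]]
      C <- pm$t_end[pm$n]
      minus <- pm$strand == "-"
      o <- sample(20L:(L - 20L), k, replace = TRUE)
      read <- paste0(substring(ct, C - o + 1L, C), substring(ct, 1L, L - o))
      stored <- if (minus) revcomp(read) else read
      pre <- project_many(pm, C - o + 1L, rep(C, k))
      suf <- project_many(pm, rep(1L, k), L - o)
      if (!minus) {
        cig_pre <- paste0(pre$cigar, L - o, "S")
        cig_suf <- paste0(o, "S", suf$cigar)
      } else {
        cig_pre <- paste0(L - o, "S", pre$cigar)
        cig_suf <- paste0(suf$cigar, o, "S")
      }
      sa_pre <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", pm$chrom, suf$pos, pm$strand, cig_suf)
      sa_suf <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", pm$chrom, pre$pos, pm$strand, cig_pre)
      pre_primary <- o >= L - o
      f1 <- 1L + 2L + 64L + (if (minus) 16L else 32L)
      f2 <- 1L + 2L + 128L + (if (minus) 32L else 16L)

      w <- sample.int(C - L + 1L, k, replace = TRUE)
      p2 <- project_many(pm, w, w + L - 1L)
      s2 <- substring(ct, w, w + L - 1L)
      if (minus) s2 <- revcomp(s2)

      prim_pos <- ifelse(pre_primary, pre$pos, suf$pos)
      prim_cig <- ifelse(pre_primary, cig_pre, cig_suf)
      prim_sa <- ifelse(pre_primary, sa_pre, sa_suf)
      supp_pos <- ifelse(pre_primary, suf$pos, pre$pos)
      supp_cig <- ifelse(pre_primary, cig_suf, cig_pre)
      supp_sa <- ifelse(pre_primary, sa_suf, sa_pre)
      qn <- sprintf("%s:J%05d", sm$sample_id, ji + seq_len(k))
      ji <- ji + k
      acc[[length(acc) + 1L]] <- list(
        qname = c(qn, qn, qn),
        flag = c(rep(f1, k), rep(f1 + 2048L, k), rep(f2, k)),
        chrom = rep(pm$chrom, 3L * k),
        pos = c(prim_pos, supp_pos, p2$pos),
        cigar = c(prim_cig, supp_cig, p2$cigar),
        rnext = rep("=", 3L * k),
        pnext = c(p2$pos, p2$pos, prim_pos),
        seq = c(stored, stored, s2),
        tag = c(prim_sa, supp_sa, rep(NA_character_, k))
      )
    }

    # --- contamination: organelle + rRNA (single-end) ---
    libr <- manifest$library[manifest$library$sample_id == sm$sample_id, ]
    if (libr$organelle > 0) {
      n_org <- libr$organelle
      st <- sample.int(org_len - L + 1L, n_org, replace = TRUE)
      acc[[length(acc) + 1L]] <- list(
        qname = sprintf("%s:O%05d", sm$sample_id, seq_len(n_org)),
        flag = sample(c(0L, 16L), n_org, replace = TRUE),
        chrom = rep(org_chrom, n_org), pos = st,
        cigar = rep(paste0(L, "M"), n_org),
        rnext = rep("*", n_org), pnext = rep(0L, n_org),
        seq = substring(chr_str[[org_chrom]], st, st + L - 1L),
        tag = rep(NA_character_, n_org)
      )
    }
    if (libr$rrna > 0) {
      n_rr <- libr$rrna
      pick <- sample.int(nrow(genome$rrna), n_rr, replace = TRUE)
      span <- genome$rrna$end[pick] - genome$rrna$start[pick] - L + 2L
      st <- genome$rrna$start[pick] +
        as.integer(floor(stats::runif(n_rr) * span))
      ch <- genome$rrna$chrom[pick]
      acc[[length(acc) + 1L]] <- list(
        qname = sprintf("%s:R%05d", sm$sample_id, seq_len(n_rr)),
        flag = sample(c(0L, 16L), n_rr, replace = TRUE),
        chrom = ch, pos = st,
        cigar = rep(paste0(L, "M"), n_rr),
        rnext = rep("*", n_rr), pnext = rep(0L, n_rr),
        seq = substring(chr_str[[ch[1]]], st, st + L - 1L),
        tag = rep(NA_character_, n_rr)
      )
    }

    fields <- purrr::map(
      c("qname", "flag", "chrom", "pos", "cigar", "rnext", "pnext", "seq", "tag"),
      function(fn) unlist(lapply(acc, `[[`, fn), use.names = FALSE)
    )
    names(fields) <- c("qname", "flag", "chrom", "pos", "cigar", "rnext", "pnext", "seq", "tag")
    lines <- sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
      fields$qname, fields$flag, fields$chrom, fields$pos, fields$cigar,
      fields$rnext, fields$pnext, fields$seq, qual
    )
    has_tag <- !is.na(fields$tag)
    lines[has_tag] <- paste0(lines[has_tag], "\t", fields$tag[has_tag])

    sam_path <- file.path(outdir, paste0(sm$sample_id, ".sam"))
    writeLines(c(header, lines), sam_path)

    fq_path <- NA_character_
    if (write_fastq) {
      fq_path <- file.path(outdir, paste0(sm$sample_id, ".fastq"))
      fq_keep <- bitwAnd(fields$flag, 2048L) == 0L & bitwAnd(fields$flag, 256L) == 0L
      fq_seq <- fields$seq[fq_keep]
      fq_flag <- fields$flag[fq_keep]
      rev <- bitwAnd(fq_flag, 16L) != 0L
      fq_seq[rev] <- revcomp(fq_seq[rev])
      mate_sfx <- dplyr::case_when(
        bitwAnd(fq_flag, 64L) != 0L ~ "/1",
        bitwAnd(fq_flag, 128L) != 0L ~ "/2",
        TRUE ~ ""
      )
      n <- sum(fq_keep)
      fq <- character(4L * n)
      fq[seq(1, 4L * n, 4)] <- paste0("@", fields$qname[fq_keep], mate_sfx)
      fq[seq(2, 4L * n, 4)] <- fq_seq
      fq[seq(3, 4L * n, 4)] <- "+"
      fq[seq(4, 4L * n, 4)] <- qual
      writeLines(fq, fq_path)
    }
    tibble::tibble(
      sample_id = sm$sample_id, sam = sam_path, fastq = fq_path,
      n_records = length(lines), n_templates = libr$total
    )
  })
  out
}
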