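#' Configuration for the synthetic circRNA study generator
#'
#' Encodes the design of the emulated experiment: a small multi-chromosome
#' plant-style genome (nuclear chromosomes, one organelle chromosome, annotated
#' rRNA loci), multi-exon genes with canonical GT-AG introns, per-genotype
#' circRNA pools in which most circRNAs appear sporadically in single
#' replicates and a minority reproducibly in all replicates, genotype-specific
#' fold changes in circRNA abundance with unchanged linear abundance, and
#' paired-end reads whose junction-spanning mates are emitted as chiastic
#' split alignments.
#'
#' The defaults describe the demonstration study used throughout the package:
#' a ~2 Mb nuclear genome with 200 genes, 40 true circRNAs, and 4 biological
#' replicates for each of 3 genotypes (the first genotype is the wild-type).
#'
#' @param seed Master seed; identical configurations with identical seeds
#'   produce byte-identical outputs.
#' @param n_nuclear_chroms,chrom_length Number and length (bases) of nuclear
#'   chromosomes.
#' @param n_genes Total number of multi-exon genes across nuclear chromosomes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length Base-pair ranges `c(min, max)`. The
#'   minimum exon length must be at least `read_length - anchor_len` so that
#'   both arms of a junction-spanning read stay within single exons (see the
#'   methods vignette).
#' @param organelle_length Length of the single organelle chromosome.
#' @param n_rrna_loci,rrna_length Number and length of annotated rRNA loci.
#' @param genotypes Genotype labels; the first is the wild-type reference.
#' @param n_replicates Biological replicates per genotype.
#' @param read_length,insert_size Read and insert length (bases) of the
#'   emulated paired-end library.
#' @param depth Mean linear templates (read pairs) per gene per sample.
#' @param n_circ Number of true circRNAs in the study.
#' @param frac_sporadic_circ Fraction of circRNAs drawn independently per
#'   replicate (Bernoulli inclusion, low counts).
#' @param frac_reproducible_circ Fraction of circRNAs present in every
#'   replicate of the genotypes that carry them.
#' @param frac_shared_reproducible Of the reproducible circRNAs, the fraction
#'   present in all genotypes; the remainder are private to single genotypes.
#' @param frac_offboundary_circ Fraction of circRNAs whose back-splice site is
#'   shifted into the exon body (mid-exon back-splicing) rather than sitting
#'   on annotated exon boundaries.
#' @param sporadic_inclusion Per-replicate inclusion probability of a sporadic
#'   circRNA.
#' @param sporadic_count_range Junction-read (template) count range of an
#'   included sporadic circRNA.
#' @param circ_mean_count Mean junction-template count of a reproducible
#'   circRNA at fold change 1 (per-circRNA means are drawn log-normally
#'   around this value).
#' @param circ_fold_changes Named list, one element per non-wild-type
#'   genotype. Each element is either a named numeric vector mapping circRNA
#'   ids to fold changes, or a list
#'   `list(n_up =, fold_up =, n_down =, fold_down =)` that spikes the first
#'   shared reproducible circRNAs deterministically. Fold changes multiply
#'   mean circRNA counts only; linear abundances never change. The default
#'   (`NULL`) spikes the first mutant with up to 4 increased (4-fold) and 2
#'   decreased (0.25-fold) circRNAs and the second mutant with up to 3 and
#'   2, capped by the number of shared reproducible circRNAs — the
#'   up/down imbalance seen in splicing-factor knockouts.
#' @param contamination Named fractions `c(organelle =, rrna =)` of total
#'   reads drawn from the organelle chromosome and rRNA loci.
#' @param noise_dispersion Negative-binomial dispersion of circRNA replicate
#'   counts (variance = mu + dispersion * mu^2).
#' @param linear_dispersion Negative-binomial dispersion of linear gene
#'   counts across biological replicates; much tighter than circRNA noise,
#'   so that linear replicate correlations reach the ~0.99 regime reported
#'   for mRNA.
#' @param gene_mean_sdlog Log-normal spread of per-gene expression means
#'   (about 1.5, a typical RNA-seq dynamic range of 2-3 orders of
#'   magnitude); the mean of the distribution stays at `depth`.
#' @return A validated `circleaf_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_nuclear_chroms = 2L,
                       chrom_length = 1000000L,
                       n_genes = 200L,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(80L, 300L),
                       intron_length = c(60L, 200L),
                       organelle_length = 100000L,
                       n_rrna_loci = 4L,
                       rrna_length = 2000L,
                       genotypes = c("col0", "cbp80", "c2h2"),
                       n_replicates = 4L,
                       read_length = 100L,
                       insert_size = 250L,
                       depth = 30,
                       n_circ = 40L,
                       frac_sporadic_circ = 0.6,
                       frac_reproducible_circ = 0.4,
                       frac_shared_reproducible = 0.5,
                       frac_offboundary_circ = 0.15,
                       sporadic_inclusion = 0.25,
                       sporadic_count_range = c(1L, 3L),
                       circ_mean_count = 20,
                       circ_fold_changes = NULL,
                       contamination = c(organelle = 0.05, rrna = 0.05),
                       noise_dispersion = 0.3,
                       linear_dispersion = 0.05,
                       gene_mean_sdlog = 1.5) {
  cfg <- list(
    seed = as.integer(seed),
    n_nuclear_chroms = as.integer(n_nuclear_chroms),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    organelle_length = as.integer(organelle_length),
    n_rrna_loci = as.integer(n_rrna_loci),
    rrna_length = as.integer(rrna_length),
    genotypes = genotypes,
    n_replicates = as.integer(n_replicates),
    read_length = as.integer(read_length),
    insert_size = as.integer(insert_size),
    depth = depth,
    n_circ = as.integer(n_circ),
    frac_sporadic_circ = frac_sporadic_circ,
    frac_reproducible_circ = frac_reproducible_circ,
    frac_shared_reproducible = frac_shared_reproducible,
    frac_offboundary_circ = frac_offboundary_circ,
    sporadic_inclusion = sporadic_inclusion,
    sporadic_count_range = as.integer(sporadic_count_range),
    circ_mean_count = circ_mean_count,
    circ_fold_changes = circ_fold_changes,
    contamination = contamination,
    noise_dispersion = noise_dispersion,
    linear_dispersion = linear_dispersion,
    gene_mean_sdlog = gene_mean_sdlog
  )
  if (is.null(circ_fold_changes)) {
    budget <- round(frac_shared_reproducible * round(frac_reproducible_circ * cfg$n_circ))
    mutants <- cfg$genotypes[-1]
    want_up <- c(4L, 3L)
    auto <- list()
    for (i in seq_len(min(2L, length(mutants)))) {
      up <- min(want_up[i], max(budget - 2L, 0L))
      down <- min(2L, budget - up)
      if (up + down > 0) {
        auto[[mutants[i]]] <- list(n_up = up, fold_up = 4, n_down = down, fold_down = 0.25)
      }
    }
    cfg$circ_fold_changes <- auto
  }
  class(cfg) <- "circleaf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c(
    "frac_sporadic_circ", "frac_reproducible_circ",
    "frac_shared_reproducible", "frac_offboundary_circ", "sporadic_inclusion"
  )
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (any(cfg$contamination < 0) || sum(cfg$contamination) >= 1) {
    stop("contamination fractions must be non-negative and sum to < 1")
  }
  if (cfg$frac_sporadic_circ + cfg$frac_reproducible_circ > 1 + 1e-12) {
    stop("frac_sporadic_circ + frac_reproducible_circ must be <= 1")
  }
  for (f in c("exons_per_gene", "exon_length", "intron_length", "sporadic_count_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop(f, " must be a positive c(min, max) range")
    }
  }
  if (length(cfg$genotypes) < 1 || anyDuplicated(cfg$genotypes)) {
    stop("genotypes must be a non-empty set of unique labels")
  }
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2")
  if (cfg$read_length >= 2 * cfg$exon_length[1] + 40) {
    # circle circumference must exceed the read; shortest circle spans one exon
    stop(
      "read_length too long relative to the shortest exon: junction reads ",
      "could not be placed with both arms inside a single-exon circle"
    )
  }
  unknown <- setdiff(names(cfg$circ_fold_changes), cfg$genotypes)
  if (length(unknown) > 0) {
    stop("circ_fold_changes references unknown genotype(s): ", paste(unknown, collapse = ", "))
  }
  if (cfg$genotypes[1] %in% names(cfg$circ_fold_changes)) {
    stop("fold changes cannot target the wild-type genotype ", cfg$genotypes[1])
  }
  invisible(cfg)
}

#' @export
print.circleaf_sim_config <- function(x, ...) {
  cat("<circleaf simulation config>\n")
  cat(sprintf(
    "  genome: %d nuclear chrom(s) x %s bp + organelle (%s bp), %d genes, %d rRNA loci\n",
    x$n_nuclear_chroms, format(x$chrom_length, big.mark = ","),
    format(x$organelle_length, big.mark = ","), x$n_genes, x$n_rrna_loci
  ))
  cat(sprintf(
    "  design: %s; %d replicates; %d circRNAs (%.0f%% sporadic / %.0f%% reproducible)\n",
    paste(x$genotypes, collapse = ", "), x$n_replicates, x$n_circ,
    100 * x$frac_sporadic_circ, 100 * x$frac_reproducible_circ
  ))
  cat(sprintf("  reads: %d bp paired-end, seed %d\n", x$read_length, x$seed))
  invisible(x)
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `sample_id`, `genotype`, `replicate`.
#' @export
sim_samples <- function(config) {
  tidyr::expand_grid(
    genotype = config$genotypes,
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", genotype, replicate)) |>
    dplyr::select(sample_id, genotype, replicate)
}
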