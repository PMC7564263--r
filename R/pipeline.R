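#' Run the full synthetic circRNA study end to end
#'
#' Orchestrates simulate -> detect -> quantify -> consensus -> differential
#' -> annotate as one reproducible run: generates the genome, ground truth
#' and per-sample alignments, calls circRNAs per sample (split-read
#' detector), accounts libraries and builds circular and linear matrices,
#' derives per-genotype consensus/uniqueness sets and replicate
#' correlations, tests mutants against the wild-type, annotates consensus
#' junctions against the gene models, and (optionally) cross-validates calls
#' with the anchor detector.
#'
#' All study outputs are written under `outdir` as plain-text tables plus a
#' summary JSON and an md5 manifest of every written file; the function also
#' returns everything in memory.
#'
#' @param config A [sim_config()]; its seed drives the whole run.
#' @param outdir Output directory.
#' @param min_reads,require_signal Detection thresholds (defaults 2, TRUE).
#' @param k Consensus threshold (default: all replicates).
#' @param pseudocount,p_cutoff,fold_cutoff Differential-test parameters
#'   (defaults 0.5, 0.05, 2).
#' @param anchor_len Anchor length for the cross-validation detector.
#' @param boundary_tolerance Boundary-match tolerance for annotation.
#' @param concordance One of `"first_replicate"` (anchor detector on each
#'   genotype's first replicate), `"all"`, or `"none"`.
#' @return A `circleaf_run` list: `genome`, `manifest`, `files`, `calls`,
#'   `libraries`, `matrices`, `consensus`, `uniqueness`, `correlations`,
#'   `differential`, `global_tests`, `structures`, `distributions`,
#'   `concordance`, `summary` (the written JSON as a list).
#' @export
run_circleaf <- function(config = sim_config(), outdir,
                         min_reads = 2L, require_signal = TRUE, k = NULL,
                         pseudocount = 0.5, p_cutoff = 0.05, fold_cutoff = 2,
                         anchor_len = 20L, boundary_tolerance = 0L,
                         concordance = c("first_replicate", "all", "none")) {
  concordance <- match.arg(concordance)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  genome <- simulate_genome(config)
  write_genome(genome, file.path(outdir, "genome.fa"), file.path(outdir, "genome.gff3"))
  manifest <- simulate_truth(config, genome)
  write_manifest(manifest, file.path(outdir, "truth_manifest.json"))
  readr::write_tsv(manifest$samples, file.path(outdir, "samples.tsv"))
  files <- simulate_reads(manifest, genome, config, file.path(outdir, "alignments"),
                          write_fastq = concordance != "none")
  samples <- manifest$samples
  wt <- config$genotypes[1]
  mutants <- setdiff(config$genotypes, wt)

  # detection + library accounting
  segs_by_sample <- stats::setNames(lapply(files$sam, read_sam), files$sample_id)
  calls_by_sample <- purrr::imap(segs_by_sample, function(segs, sid) {
    call_circrnas(segs, genome, min_reads = min_reads, require_signal = require_signal) |>
      dplyr::mutate(sample_id = sid)
  })
  calls <- dplyr::bind_rows(calls_by_sample)
  readr::write_tsv(
    dplyr::select(calls, sample_id, circ_id, chrom, start, end, strand,
                  n_junction_reads, canonical_signal),
    file.path(outdir, "circ_calls.tsv")
  )
  libraries <- purrr::imap_dfr(segs_by_sample, function(segs, sid) {
    dplyr::mutate(count_library_components(segs, genome), sample_id = sid)
  }) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::select(sample_id, genotype, replicate, dplyr::everything())
  readr::write_tsv(libraries, file.path(outdir, "library_accounting.tsv"))

  # matrices
  circ_mat <- build_circ_matrix(calls, libraries)
  junctions <- dplyr::distinct(calls, circ_id, chrom, start, end, strand)
  linear <- quantify_linear(segs_by_sample, junctions, genome, libraries)
  readr::write_tsv(circ_mat, file.path(outdir, "circ_matrix.tsv"))
  readr::write_tsv(linear$boundary, file.path(outdir, "linear_boundary_matrix.tsv"))
  readr::write_tsv(linear$gene, file.path(outdir, "linear_gene_matrix.tsv"))

  # consensus, uniqueness, correlations
  consensus <- purrr::map(
    stats::setNames(config$genotypes, config$genotypes),
    function(gt) consensus_records(calls, samples, gt, k = k)
  )
  readr::write_tsv(dplyr::bind_rows(consensus), file.path(outdir, "consensus_records.tsv"))
  cons_sets <- purrr::map(consensus, ~ sort(.x$circ_id[.x$in_consensus]))
  wt_calls <- dplyr::filter(calls, sample_id %in% samples$sample_id[samples$genotype == wt])
  uniqueness <- purrr::map(stats::setNames(mutants, mutants), function(gt) {
    list(
      strict = unique_to_variant(cons_sets[[gt]], wt_calls, "strict"),
      consensus = unique_to_variant(cons_sets[[gt]], wt_calls, "consensus",
                                    reference_consensus = cons_sets[[wt]])
    )
  })
  spectra <- purrr::map(
    stats::setNames(config$genotypes, config$genotypes),
    function(gt) reproducibility_spectrum(calls, samples, gt)
  )
  correlations <- purrr::map(
    stats::setNames(config$genotypes, config$genotypes),
    function(gt) {
      list(
        circ = replicate_correlation(circ_mat, samples, gt),
        gene = replicate_correlation(linear$gene, samples, gt)
      )
    }
  )

  # differential analyses per mutant
  differential <- list(); global_tests <- list()
  for (gt in mutants) {
    universe <- union(cons_sets[[gt]], cons_sets[[wt]])
    if (length(universe) > 0) {
      differential[[gt]] <- circ_fold_change_test(
        circ_mat, samples, gt, reference = wt, universe = universe,
        pseudocount = pseudocount, p_cutoff = p_cutoff, fold_cutoff = fold_cutoff
      )
      readr::write_tsv(differential[[gt]], file.path(outdir, paste0("differential_", gt, ".tsv")))
    }
    global_tests[[gt]] <- list(
      consensus = global_accumulation_test(circ_mat, samples, gt, reference = wt,
                                           universe = universe),
      all_detected = global_accumulation_test(circ_mat, samples, gt, reference = wt),
      linear = linear_abundance_test(linear$boundary, samples, gt, reference = wt,
                                     universe = cons_sets[[gt]])
    )
  }

  # circ-linear coupling over the union of consensus circRNAs
  all_cons <- sort(unique(unlist(cons_sets)))
  circ_linear <- NULL
  if (length(all_cons) >= 3) {
    pairs <- tibble::tibble(circ_id = all_cons, linear_id = all_cons)
    circ_linear <- tryCatch(
      circ_linear_correlation(circ_mat, linear$boundary, pairs, samples, wt),
      error = function(e) NULL
    )
  }

  # structural annotation of all consensus junctions
  structures <- NULL; distributions <- list()
  if (length(all_cons) > 0) {
    jx <- dplyr::filter(junctions, circ_id %in% all_cons)
    structures <- annotate_junctions(jx, genome, tolerance = boundary_tolerance)
    readr::write_tsv(structures, file.path(outdir, "junction_structures.tsv"))
    distributions <- purrr::map(
      stats::setNames(config$genotypes, config$genotypes),
      function(gt) exon_start_distribution(
        dplyr::filter(structures, circ_id %in% cons_sets[[gt]])
      )
    )
  }

  # detector cross-validation
  conc <- NULL
  if (concordance != "none") {
    pick <- if (concordance == "all") files$sample_id else {
      samples |>
        dplyr::group_by(genotype) |>
        dplyr::slice_min(replicate, n = 1) |>
        dplyr::pull(sample_id)
    }
    conc <- purrr::map_dfr(pick, function(sid) {
      anchor <- call_circrnas_anchor(files$fastq[files$sample_id == sid], genome,
                                     anchor_len = anchor_len, min_reads = min_reads)
      dplyr::mutate(concordance(calls_by_sample[[sid]], anchor), sample_id = sid)
    })
    readr::write_tsv(conc, file.path(outdir, "detector_concordance.tsv"))
  }

  summary <- list(
    seed = config$seed,
    genotypes = config$genotypes,
    n_samples = nrow(samples),
    n_circ_detected_union = length(unique(calls$circ_id)),
    consensus_counts = purrr::map_int(cons_sets, length),
    uniqueness_counts = purrr::map(uniqueness, ~ purrr::map_int(.x, length)),
    spectrum_single_replicate = purrr::map_dbl(spectra, ~ .x$fraction[1]),
    mean_replicate_r = purrr::map(correlations, ~ list(
      circ = attr(.x$circ, "mean_r"), gene = attr(.x$gene, "mean_r")
    )),
    global_tests = purrr::map(global_tests, function(g) {
      purrr::map(g, ~ list(p_value = .x$p_value, stars = .x$stars))
    }),
    differential_counts = purrr::map(differential, ~ list(
      up = sum(.x$significant & .x$log2_fc > 0),
      down = sum(.x$significant & .x$log2_fc < 0)
    )),
    circ_linear_r = if (!is.null(circ_linear)) circ_linear$r else NA,
    first_exon_fraction = purrr::map_dbl(distributions, ~ .x$frac_first_exon %||% NA_real_),
    concordance = if (!is.null(conc)) mean(conc$frac_a_in_b, na.rm = TRUE) else NA
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  written <- setdiff(written, file.path(outdir, "file_hashes.tsv"))
  hashes <- tibble::tibble(
    file = sub(paste0("^", outdir, "/?"), "", written),
    md5 = unname(tools::md5sum(written))
  ) |> dplyr::arrange(file)
  readr::write_tsv(hashes, file.path(outdir, "file_hashes.tsv"))

  structure(
    list(
      config = config, genome = genome, manifest = manifest, files = files,
      calls = calls, libraries = libraries,
      matrices = c(list(circ = circ_mat), linear),
      consensus = consensus, consensus_sets = cons_sets,
      uniqueness = uniqueness, spectra = spectra, correlations = correlations,
      differential = differential, global_tests = global_tests,
      circ_linear = circ_linear, structures = structures,
      distributions = distributions, concordance = conc,
      summary = summary, hashes = hashes, outdir = outdir
    ),
    class = "circleaf_run"
  )
}

#' @export
print.circleaf_run <- function(x, ...) {
  cat("<circleaf run>\n")
  cat("  outdir:", x$outdir, "\n")
  cat("  detected circRNAs (union):", x$summary$n_circ_detected_union, "\n")
  cat("  consensus counts:", paste(names(x$consensus_sets),
                                   purrr::map_int(x$consensus_sets, length),
                                   sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate a study input bundle
#'
#' Cross-checks genome FASTA, GFF3 annotation, SAM files and the sample
#' sheet: chromosome-name agreement between the SAM headers and the FASTA,
#' exon coordinates within chromosome bounds, legal strand values, and at
#' least 2 replicates per genotype. Fatal inconsistencies and mere warnings
#' are distinguished in the returned diagnostics.
#'
#' @param fasta,gff Genome/annotation paths.
#' @param sam_paths SAM file paths.
#' @param samples Sample sheet tibble.
#' @return Tibble with columns `level` (`"fatal"`/`"warning"`), `check`,
#'   `message`. Zero fatal rows means the bundle is runnable.
#' @export
validate_inputs <- function(fasta, gff, sam_paths, samples) {
  diags <- list()
  note <- function(level, check, msg) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(level = level, check = check, message = msg)
  }
  genome <- tryCatch(read_genome(fasta, gff), error = function(e) {
    note("fatal", "annotation", conditionMessage(e))
    NULL
  })
  if (!is.null(genome)) {
    bad_strand <- setdiff(unique(genome$genes$strand), c("+", "-"))
    if (length(bad_strand) > 0) {
      note("fatal", "strand", paste("illegal strand value(s):", paste(bad_strand, collapse = ",")))
    }
    lens <- stats::setNames(genome$chroms$length, genome$chroms$chrom)
    out_of_bounds <- genome$exons |>
      dplyr::filter(start < 1 | end > lens[chrom])
    if (nrow(out_of_bounds) > 0) {
      note("fatal", "exon_bounds", sprintf(
        "%d exon(s) outside chromosome bounds; first: %s:%d-%d",
        nrow(out_of_bounds), out_of_bounds$chrom[1],
        out_of_bounds$start[1], out_of_bounds$end[1]
      ))
    }
    for (p in sam_paths) {
      hdr <- readr::read_lines(p, n_max = 200)
      sq <- stringr::str_match(hdr[startsWith(hdr, "@SQ")], "SN:(\\S+)")[, 2]
      missing <- setdiff(sq, genome$chroms$chrom)
      if (length(missing) > 0) {
        note("fatal", "chrom_names", sprintf(
          "%s: SAM chromosome(s) %s absent from FASTA", basename(p),
          paste(missing, collapse = ",")
        ))
      }
    }
  }
  reps <- dplyr::count(samples, genotype)
  for (i in seq_len(nrow(reps))) {
    if (reps$n[i] < 2) {
      note("fatal", "replicates", sprintf(
        "genotype %s has %d replicate(s); at least 2 are required",
        reps$genotype[i], reps$n[i]
      ))
    }
  }
  if (length(diags) == 0) {
    return(tibble::tibble(level = character(), check = character(), message = character()))
  }
  dplyr::bind_rows(diags)
}
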