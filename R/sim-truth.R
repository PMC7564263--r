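#' Assign per-genotype transcript pools and a ground-truth manifest
#'
#' Draws the circRNA pool (reproducible circRNAs present in every replicate of
#' their carrier genotypes, sporadic circRNAs included independently per
#' replicate with low counts), realizes per-sample junction-template and
#' linear gene counts from a negative-binomial model, applies genotype fold
#' changes to circRNA means only (linear abundances are identical across
#' genotypes), and computes per-sample library composition including
#' organelle and rRNA contamination.
#'
#' Most circRNA back-splice sites sit exactly on annotated exon boundaries; a
#' configurable minority is shifted into the exon body, emulating mid-exon
#' back-splicing. Shifted sites are placed only where the genome already
#' carries canonical AG/GT flanks, so every manifest circRNA is
#' canonical-signal positive.
#'
#' @param config A [sim_config()] object.
#' @param genome The matching [simulate_genome()] bundle.
#' @return A `circleaf_manifest`: tibbles `samples`, `circ_ref`,
#'   `circ_counts` (circ_id x sample true junction-template counts),
#'   `gene_counts`, `fold_map`, and `library` (per-sample template totals by
#'   category).
#' @export
simulate_truth <- function(config, genome) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))
  samples <- sim_samples(config)
  L <- config$read_length
  min_circ_len <- L + 20L

  n_rep <- round(config$frac_reproducible_circ * config$n_circ)
  n_spor <- round(config$frac_sporadic_circ * config$n_circ)
  n_used <- n_rep + n_spor
  n_shared <- round(config$frac_shared_reproducible * n_rep)

  host <- sample(genome$genes$gene_id, n_used)
  classes <- c(rep("reproducible", n_rep), rep("sporadic", n_spor))

  # genotype presence: shared reproducible in all genotypes; private ones
  # round-robin with mutants first; sporadic circRNAs sit in every pool
  presence <- vector("list", n_used)
  priv_order <- c(config$genotypes[-1], config$genotypes[1])
  pi <- 0L
  for (i in seq_len(n_used)) {
    if (classes[i] == "sporadic" || i <= n_shared) {
      presence[[i]] <- config$genotypes
    } else {
      pi <- pi + 1L
      presence[[i]] <- priv_order[(pi - 1L) %% length(priv_order) + 1L]
    }
  }

  empty_ref <- tibble::tibble(
    circ_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), host_gene = character(),
    exon_from = integer(), exon_to = integer(),
    at_start_boundary = logical(), at_end_boundary = logical(),
    spliced_length = integer(), class = character(), genotypes = character()
  )
  circ_ref <- if (n_used == 0) empty_ref else purrr::map_dfr(seq_len(n_used), function(i) {
    g <- genome$genes[genome$genes$gene_id == host[i], ]
    ex <- genome$exons[genome$exons$gene_id == host[i], ]
    ex <- ex[order(ex$start), ]
    n_ex <- nrow(ex)
    elen <- ex$end - ex$start + 1L

    pairs <- tidyr::expand_grid(a = seq_len(n_ex), b = seq_len(n_ex)) |>
      dplyr::filter(b >= a) |>
      dplyr::mutate(splen = purrr::map2_int(a, b, ~ sum(elen[.x:.y]))) |>
      dplyr::filter(splen >= min_circ_len)
    # first-exon preference for circRNAs private to the second genotype,
    # emulating the cap-binding-complex mutant phenotype
    has_first <- if (g$strand == "+") pairs$a == 1L else pairs$b == n_ex
    private_to_mut1 <- length(config$genotypes) >= 2 &&
      identical(presence[[i]], config$genotypes[2])
    pool <- if (private_to_mut1 && stats::runif(1) < 0.7 && any(has_first)) {
      pairs[has_first, ]
    } else if (!private_to_mut1 && any(!has_first)) {
      pairs[!has_first, ]
    } else {
      pairs
    }
    pick <- pool[sample(nrow(pool), 1L), ]
    a <- pick$a; b <- pick$b
    s <- ex$start[a]; e <- ex$end[b]

    at_start <- TRUE; at_end <- TRUE
    if (stats::runif(1) < config$frac_offboundary_circ) {
      side <- sample(c("start", "end", "both"), 1L)
      slack <- pick$splen - min_circ_len
      budget <- if (side == "both") slack %/% 2L else slack
      if (side %in% c("start", "both") && budget > 4L) {
        s2 <- shift_into_exon(
          genome, g$chrom, g$strand, "start",
          lo = ex$start[a] + 3L, hi = min(ex$start[a] + budget, ex$end[a] - 20L)
        )
        if (!is.na(s2)) { s <- s2; at_start <- FALSE }
      }
      if (side %in% c("end", "both") && budget > 4L) {
        e2 <- shift_into_exon(
          genome, g$chrom, g$strand, "end",
          lo = max(ex$end[b] - budget, ex$start[b] + 20L), hi = ex$end[b] - 3L
        )
        if (!is.na(e2)) { e <- e2; at_end <- FALSE }
      }
    }

    cmap <- circle_exon_map(genome, host[i], s, e)
    tibble::tibble(
      circ_id = circ_id(g$chrom, s, e),
      chrom = g$chrom, strand = g$strand, start = s, end = e,
      host_gene = host[i],
      exon_from = cmap$exon_rank[1], exon_to = cmap$exon_rank[nrow(cmap)],
      at_start_boundary = at_start, at_end_boundary = at_end,
      spliced_length = sum(cmap$len),
      class = classes[i],
      genotypes = paste(presence[[i]], collapse = ",")
    )
  })
  circ_ref$canonical_signal <- logical(nrow(circ_ref))
  circ_ref$canonical_signal <- has_splice_signal(
    genome, circ_ref$chrom, circ_ref$strand, circ_ref$start, circ_ref$end
  )
  circ_ref$base_mean <- if (n_used == 0) numeric(0) else ifelse(
    circ_ref$class == "reproducible",
    stats::rlnorm(n_used, log(config$circ_mean_count), 0.35),
    NA_real_
  )

  # realize the fold-change map (genotype -> circ_id -> fold)
  shared_rep <- circ_ref$circ_id[circ_ref$class == "reproducible"][seq_len(n_shared)]
  fold_map <- purrr::imap_dfr(config$circ_fold_changes, function(spec, gt) {
    if (is.numeric(spec)) {
      bad <- setdiff(names(spec), circ_ref$circ_id)
      if (length(bad) > 0) stop("fold-change map references unknown circRNA(s): ",
                                paste(bad, collapse = ", "))
      tibble::tibble(genotype = gt, circ_id = names(spec), fold = unname(spec))
    } else {
      n_up <- spec$n_up %||% 0; n_down <- spec$n_down %||% 0
      if (n_up + n_down > length(shared_rep)) {
        stop("fold-change spec for ", gt, " asks for more spikes than there are shared reproducible circRNAs")
      }
      tibble::tibble(
        genotype = gt,
        circ_id = shared_rep[seq_len(n_up + n_down)],
        fold = c(rep(spec$fold_up %||% 1, n_up), rep(spec$fold_down %||% 1, n_down))
      )
    }
  })
  if (nrow(fold_map) == 0) {
    fold_map <- tibble::tibble(genotype = character(), circ_id = character(),
                               fold = numeric())
  }

  # per-sample junction-template counts
  grid <- tidyr::expand_grid(circ_id = circ_ref$circ_id, sample_id = samples$sample_id) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(
      dplyr::select(circ_ref, circ_id, class, base_mean, genotypes),
      by = "circ_id"
    ) |>
    dplyr::left_join(fold_map, by = c("circ_id", "genotype")) |>
    dplyr::mutate(
      fold = dplyr::coalesce(fold, 1),
      carried = purrr::map2_lgl(genotypes, genotype, ~ .y %in% strsplit(.x, ",")[[1]])
    ) |>
    dplyr::arrange(circ_id, sample_id)

  size <- 1 / config$noise_dispersion
  is_rep <- grid$class == "reproducible" & grid$carried
  is_spor <- grid$class == "sporadic"
  count <- integer(nrow(grid))
  count[is_rep] <- stats::rnbinom(sum(is_rep),
    mu = grid$base_mean[is_rep] * grid$fold[is_rep], size = size
  )
  incl <- stats::rbinom(sum(is_spor), 1, config$sporadic_inclusion) == 1
  spor_counts <- integer(sum(is_spor))
  spor_counts[incl] <- sample_range(
    config$sporadic_count_range[1], config$sporadic_count_range[2], sum(incl)
  )
  count[is_spor] <- spor_counts
  circ_counts <- dplyr::select(grid, circ_id, sample_id) |>
    dplyr::mutate(count = count)

  # linear gene counts: identical means across genotypes; wide log-normal
  # expression spread with tight replicate noise, the mRNA regime
  sdl <- config$gene_mean_sdlog
  gene_mean <- tibble::tibble(
    gene_id = genome$genes$gene_id,
    mean = stats::rlnorm(nrow(genome$genes), log(config$depth) - sdl^2 / 2, sdl)
  )
  gene_grid <- tidyr::expand_grid(gene_id = gene_mean$gene_id, sample_id = samples$sample_id) |>
    dplyr::left_join(gene_mean, by = "gene_id") |>
    dplyr::arrange(gene_id, sample_id)
  gene_counts <- gene_grid |>
    dplyr::mutate(count = stats::rnbinom(dplyr::n(), mu = mean,
                                         size = 1 / config$linear_dispersion)) |>
    dplyr::select(gene_id, sample_id, count)

  # per-sample library accounting (template level)
  f_org <- config$contamination[["organelle"]]
  f_rrna <- config$contamination[["rrna"]]
  lib <- dplyr::full_join(
    dplyr::summarise(dplyr::group_by(circ_counts, sample_id), junction = sum(count)),
    dplyr::summarise(dplyr::group_by(gene_counts, sample_id), linear = sum(count)),
    by = "sample_id"
  ) |>
    dplyr::mutate(junction = dplyr::coalesce(junction, 0L)) |>
    dplyr::mutate(
      organelle = round(f_org / (1 - f_org - f_rrna) * (junction + linear)),
      rrna = round(f_rrna / (1 - f_org - f_rrna) * (junction + linear)),
      total = junction + linear + organelle + rrna
    ) |>
    dplyr::ungroup()

  structure(
    list(
      samples = samples,
      circ_ref = circ_ref,
      circ_counts = circ_counts,
      gene_means = gene_mean,
      gene_counts = gene_counts,
      fold_map = fold_map,
      library = lib,
      config = config
    ),
    class = "circleaf_manifest"
  )
}

# find a shifted back-splice coordinate inside an exon whose flanks already
# carry the canonical signal; returns NA when the window has none
shift_into_exon <- function(genome, chrom, strand, side, lo, hi) {
  if (hi < lo) return(NA_integer_)
  if (side == "start") {
    pat <- if (strand == "+") "AG" else "AC"
    seq <- genome_seq(genome, chrom, lo - 2L, hi - 1L)
    at <- stringr::str_locate_all(seq, paste0("(?=", pat, ")"))[[1]][, 1]
    cand <- lo - 2L + at - 1L + 2L # coordinate after the flank dinucleotide
  } else {
    pat <- if (strand == "+") "GT" else "CT"
    seq <- genome_seq(genome, chrom, lo + 1L, hi + 2L)
    at <- stringr::str_locate_all(seq, paste0("(?=", pat, ")"))[[1]][, 1]
    cand <- lo + 1L + at - 1L - 1L # coordinate before the flank dinucleotide
  }
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) == 0) return(NA_integer_)
  as.integer(sample_one(cand))
}

#' @export
print.circleaf_manifest <- function(x, ...) {
  cat("<circleaf ground-truth manifest>\n")
  cat(sprintf(
    "  %d circRNAs (%d reproducible / %d sporadic) across %d samples; %d genes\n",
    nrow(x$circ_ref), sum(x$circ_ref$class == "reproducible"),
    sum(x$circ_ref$class == "sporadic"), nrow(x$samples), nrow(x$gene_means)
  ))
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest A `circleaf_manifest`.
#' @param path Output (input) JSON path.
#' @return `write_manifest()` returns the path invisibly; `read_manifest()`
#'   the manifest (without the originating config).
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[c("samples", "circ_ref", "circ_counts", "gene_means",
                    "gene_counts", "fold_map", "library")]
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::map(raw, tibble::as_tibble)
  structure(out, class = "circleaf_manifest")
}

#' True detectability of manifest circRNAs at a read threshold
#'
#' A circRNA counts as detectable in a sample when its true junction-template
#' count reaches `min_reads` — the same threshold the detector applies. This
#' is the oracle used to compare detector output with the manifest.
#'
#' @param manifest A `circleaf_manifest`.
#' @param min_reads Detection threshold (default 2, the standard rule).
#' @return Tibble `circ_id`, `sample_id`, `detectable`.
#' @export
truth_detectable <- function(manifest, min_reads = 2L) {
  dplyr::mutate(manifest$circ_counts, detectable = count >= min_reads) |>
    dplyr::select(circ_id, sample_id, detectable)
}
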