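#' Simulate count matrices for differential-test calibration
#'
#' Draws a two-group negative-binomial count matrix with per-feature means
#' sampled log-normally, optionally spiking a subset of features with a true
#' fold change in group B. Counts are returned in the long matrix layout the
#' differential tests consume; all samples share the same effective library
#' size, so normalized values equal raw counts.
#'
#' @param n_features Number of features.
#' @param n_per_group Replicates per group.
#' @param dispersion Negative-binomial dispersion (variance = mu + d mu^2).
#' @param mean_log,mean_sdlog Log-normal parameters of per-feature baseline
#'   means.
#' @param n_spiked Number of features given a true fold change in group B.
#' @param fold The spiked fold change.
#' @param spike_min_mean Minimum baseline mean of spiked features.
#' @param seed Seed.
#' @return List: `matrix` (long tibble `circ_id`, `sample_id`, `raw`,
#'   `norm`), `samples` (genotypes `A` reference, `B`), `truth` (`circ_id`,
#'   `fold`).
#' @export
simulate_null_matrix <- function(n_features = 2000L, n_per_group = 4L,
                                 dispersion = 0.3, mean_log = log(50),
                                 mean_sdlog = 0.8, n_spiked = 0L, fold = 4,
                                 spike_min_mean = 20, seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  ids <- sprintf("F%05d", seq_len(n_features))
  mu <- stats::rlnorm(n_features, mean_log, mean_sdlog)
  foldvec <- rep(1, n_features)
  if (n_spiked > 0) {
    eligible <- which(mu >= spike_min_mean)
    if (length(eligible) < n_spiked) {
      mu[seq_len(n_spiked)] <- pmax(mu[seq_len(n_spiked)], spike_min_mean)
      eligible <- seq_len(n_features)
    }
    spiked <- eligible[seq_len(n_spiked)]
    foldvec[spiked] <- fold
  }
  samples <- tibble::tibble(
    sample_id = c(sprintf("A_r%d", seq_len(n_per_group)), sprintf("B_r%d", seq_len(n_per_group))),
    genotype = rep(c("A", "B"), each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2)
  )
  size <- 1 / dispersion
  draw <- function(mu_vec) {
    matrix(
      stats::rnbinom(length(mu_vec) * n_per_group, mu = rep(mu_vec, n_per_group), size = size),
      ncol = n_per_group
    )
  }
  a <- draw(mu)
  b <- draw(mu * foldvec)
  long <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_per_group), function(j) {
      tibble::tibble(circ_id = ids, sample_id = sprintf("A_r%d", j), raw = a[, j])
    }),
    purrr::map_dfr(seq_len(n_per_group), function(j) {
      tibble::tibble(circ_id = ids, sample_id = sprintf("B_r%d", j), raw = b[, j])
    })
  ) |>
    dplyr::mutate(norm = as.numeric(raw))
  list(
    matrix = long,
    samples = samples,
    truth = tibble::tibble(circ_id = ids, fold = foldvec, mean = mu)
  )
}

#' Truth-level circular and linear matrices from a manifest
#'
#' Builds the circular and linear-gene matrices directly from a manifest's
#' true counts, thresholded at `min_reads` for circRNA presence — the count
#' structure the alignment-level pipeline would recover, without the
#' read-emission round trip. Used for replicate-correlation properties where
#' only the count structure matters.
#'
#' @param manifest A [simulate_truth()] manifest.
#' @param min_reads Detection threshold applied to circRNA counts.
#' @return List of long tibbles `circ` and `gene` (normalized per million
#'   effective templates using the manifest's library table).
#' @export
truth_matrices <- function(manifest, min_reads = 2L) {
  lib <- manifest$library |>
    dplyr::mutate(effective_size = junction + linear) |>
    dplyr::select(sample_id, effective_size)
  circ_calls <- manifest$circ_counts |>
    dplyr::filter(count >= min_reads) |>
    dplyr::rename(n_junction_reads = count)
  circ <- build_circ_matrix(circ_calls, lib)
  gene <- manifest$gene_counts |>
    dplyr::left_join(lib, by = "sample_id") |>
    dplyr::mutate(raw = count, norm = normalize_counts(raw, effective_size)) |>
    dplyr::select(gene_id, sample_id, raw, norm)
  attr(gene, "kind") <- "linear_gene"
  list(circ = circ, gene = gene)
}
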