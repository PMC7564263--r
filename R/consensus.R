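#' Detection table: which circRNA was called in which sample
#'
#' @param calls Tibble binding per-sample call tables with a `sample_id`
#'   column (any tibble with `circ_id` + `sample_id` works).
#' @param samples Sample sheet (`sample_id`, `genotype`, `replicate`).
#' @return Tibble `circ_id`, `sample_id`, `genotype`, `replicate`,
#'   `detected` (complete over all circRNAs x samples).
#' @export
detection_table <- function(calls, samples) {
  tidyr::expand_grid(circ_id = sort(unique(calls$circ_id)), sample_id = samples$sample_id) |>
    dplyr::left_join(
      dplyr::mutate(dplyr::distinct(calls, circ_id, sample_id), detected = TRUE),
      by = c("circ_id", "sample_id")
    ) |>
    dplyr::mutate(detected = dplyr::coalesce(detected, FALSE)) |>
    dplyr::left_join(samples, by = "sample_id")
}

#' Replicate-reproducibility spectrum of circRNA detection
#'
#' Over the circRNAs detected in at least one replicate of a genotype, the
#' fraction detected in exactly 1, 2, ..., n replicates. In real libraries
#' the single-replicate class dominates (sporadic back-splicing); the
#' spectrum quantifies that structure.
#'
#' @param calls Calls with `circ_id`, `sample_id`.
#' @param samples Sample sheet.
#' @param genotype Genotype to profile.
#' @return Tibble `n_detected`, `n_circ`, `fraction` (fractions sum to 1).
#' @export
reproducibility_spectrum <- function(calls, samples, genotype) {
  gt <- genotype
  smp <- dplyr::filter(samples, .data$genotype == gt)
  if (nrow(smp) == 0) stop("genotype not present in sample sheet: ", gt)
  if (nrow(smp) < 2) stop("reproducibility needs >= 2 replicates for ", gt)
  det <- calls |>
    dplyr::filter(sample_id %in% smp$sample_id) |>
    dplyr::distinct(circ_id, sample_id) |>
    dplyr::count(circ_id, name = "n_detected")
  tibble::tibble(n_detected = seq_len(nrow(smp))) |>
    dplyr::left_join(dplyr::count(det, n_detected, name = "n_circ"), by = "n_detected") |>
    dplyr::mutate(
      n_circ = dplyr::coalesce(n_circ, 0L),
      fraction = if (nrow(det) > 0) n_circ / nrow(det) else 0
    )
}

#' Per-genotype consensus records and consensus set
#'
#' A circRNA enters the consensus when detected in at least `k` of the
#' genotype's replicates; the default `k` equals the number of replicates
#' (the all-replicates rule), and `k = n - 1`-style relaxations are a matter
#' of passing a smaller `k`.
#'
#' @param calls Calls with `circ_id`, `sample_id`.
#' @param samples Sample sheet.
#' @param genotype Genotype to summarise.
#' @param k Minimum replicates (default: all replicates of the genotype).
#' @return Tibble of consensus records for every circRNA seen at least once
#'   in the genotype: `circ_id`, `genotype`, `n_detected`, `n_replicates`,
#'   `detection_pattern` (e.g. `"1101"`, replicate order), `in_consensus`.
#' @export
consensus_records <- function(calls, samples, genotype, k = NULL) {
  gt <- genotype
  smp <- dplyr::filter(samples, .data$genotype == gt) |> dplyr::arrange(replicate)
  if (nrow(smp) == 0) stop("genotype not present in sample sheet: ", gt)
  n <- nrow(smp)
  k <- k %||% n
  stopifnot(k >= 1, k <= n)
  det <- detection_table(dplyr::filter(calls, sample_id %in% smp$sample_id), smp)
  det |>
    dplyr::group_by(circ_id) |>
    dplyr::summarise(
      n_detected = sum(detected),
      detection_pattern = paste0(as.integer(detected[order(replicate)]), collapse = ""),
      .groups = "drop"
    ) |>
    dplyr::filter(n_detected >= 1) |>
    dplyr::mutate(
      genotype = gt, n_replicates = n,
      in_consensus = n_detected >= k
    ) |>
    dplyr::select(circ_id, genotype, n_detected, n_replicates, detection_pattern, in_consensus)
}

#' @rdname consensus_records
#' @return `consensus_set()`: the character vector of consensus circRNA ids.
#' @export
consensus_set <- function(calls, samples, genotype, k = NULL) {
  rec <- consensus_records(calls, samples, genotype, k = k)
  sort(rec$circ_id[rec$in_consensus])
}

#' CircRNAs unique to a variant relative to a reference genotype
#'
#' Two readings of uniqueness: `strict` removes any circRNA detected in even
#' a single reference replicate; `consensus` removes only circRNAs in the
#' reference consensus set (so a circRNA sporadically present in the
#' reference still counts as variant-typical).
#'
#' @param variant_set Character vector of consensus ids for the variant.
#' @param reference_calls Calls of the reference genotype's replicates
#'   (`circ_id`, `sample_id`).
#' @param mode `"strict"` or `"consensus"`.
#' @param reference_consensus For `mode = "consensus"`, the reference
#'   consensus id set.
#' @return Character vector of unique circRNA ids.
#' @export
unique_to_variant <- function(variant_set, reference_calls,
                              mode = c("strict", "consensus"),
                              reference_consensus = NULL) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    seen <- unique(reference_calls$circ_id)
    sort(setdiff(variant_set, seen))
  } else {
    if (is.null(reference_consensus)) {
      stop("mode = 'consensus' needs the reference consensus set")
    }
    sort(setdiff(variant_set, reference_consensus))
  }
}

#' Pairwise replicate correlation of an abundance matrix
#'
#' Pearson correlation of normalized abundances between every pair of a
#' genotype's replicates, computed identically for circular and linear
#' matrices so the two are comparable like for like. For each pair, features
#' absent (zero) in both replicates are dropped; features present in only
#' one are kept as zeros — presence/absence variability is part of the
#' signal being measured.
#'
#' @param matrix Long matrix tibble (`sample_id`, `norm` and a feature
#'   column, the first non-sample column).
#' @param samples Sample sheet.
#' @param genotype Genotype whose replicates are compared.
#' @param log2 Correlate log2(norm + pseudocount) instead of raw normalized
#'   values.
#' @param pseudocount Pseudocount for the log option.
#' @return Tibble `sample_a`, `sample_b`, `r`, `n_features`; the mean over
#'   pairs is in attribute `mean_r`. Pairs with fewer than 2 shared
#'   non-degenerate features get `NA` (with a warning).
#' @export
replicate_correlation <- function(matrix, samples, genotype, log2 = FALSE,
                                  pseudocount = 0.5) {
  gt <- genotype
  smp <- dplyr::filter(samples, .data$genotype == gt)
  if (nrow(smp) < 2) stop("replicate correlation needs >= 2 replicates for ", gt)
  feat_col <- setdiff(names(matrix), c("sample_id", "raw", "norm"))[1]
  wide <- matrix |>
    dplyr::filter(sample_id %in% smp$sample_id) |>
    dplyr::select(dplyr::all_of(c(feat_col, "sample_id", "norm"))) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = norm, values_fill = 0)
  ids <- smp$sample_id
  for (id in setdiff(ids, names(wide))) wide[[id]] <- numeric(nrow(wide))
  pairs <- utils::combn(ids, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    x <- wide[[pairs[1, i]]]
    y <- wide[[pairs[2, i]]]
    keep <- !(x == 0 & y == 0)
    x <- x[keep]; y <- y[keep]
    if (log2) { x <- log2(x + pseudocount); y <- log2(y + pseudocount) }
    r <- if (sum(keep) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("degenerate replicate pair ", pairs[1, i], " vs ", pairs[2, i])
      NA_real_
    } else {
      stats::cor(x, y)
    }
    tibble::tibble(
      sample_a = pairs[1, i], sample_b = pairs[2, i],
      r = r, n_features = sum(keep)
    )
  })
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  out
}
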