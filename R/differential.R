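#' Per-circRNA fold-change test between a mutant and the wild-type
#'
#' Tests each circRNA's log2(normalized + pseudocount) abundance between the
#' two genotypes' replicates, with the field's significance rule: raw
#' p-value at most `p_cutoff` AND at least `fold_cutoff`-fold change (in
#' either direction). The default test is the variance-moderated t
#' (empirical-Bayes shrinkage of per-feature variances across the matrix,
#' via limma), the standard choice at 3-4 replicates per group where
#' per-feature variance estimates are too noisy for a plain t-test;
#' `method = "welch"` runs ordinary Welch t-tests instead.
#' Benjamini-Hochberg adjusted p-values are reported alongside but do not
#' gate the flag. Features that are zero in every replicate of both groups
#' are excluded from testing.
#'
#' @param matrix Long circular matrix (`circ_id`, `sample_id`, `norm`).
#' @param samples Sample sheet.
#' @param genotype Mutant genotype.
#' @param reference Reference genotype (default: first in the sample sheet).
#' @param universe Optional circ_id vector restricting the tested features
#'   (typically the union of the two genotypes' consensus sets).
#' @param pseudocount Pseudocount added before the log transform.
#' @param p_cutoff,fold_cutoff Significance rule (defaults 0.05 and 2).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Tibble: `circ_id`, `mean_ref`, `mean_mut` (normalized means),
#'   `log2_fc`, `p_value`, `p_adj`, `significant`.
#' @export
circ_fold_change_test <- function(matrix, samples, genotype, reference = NULL,
                                  universe = NULL, pseudocount = 0.5,
                                  p_cutoff = 0.05, fold_cutoff = 2,
                                  method = c("moderated", "welch")) {
  method <- match.arg(method)
  reference <- reference %||% samples$genotype[1]
  feat_col <- setdiff(names(matrix), c("sample_id", "raw", "norm"))[1]
  grp <- function(gt) {
    ids <- samples$sample_id[samples$genotype == gt]
    if (length(ids) < 2) stop("fewer than 2 replicates for group ", gt)
    ids
  }
  ids_ref <- grp(reference)
  ids_mut <- grp(genotype)

  m <- matrix
  if (!is.null(universe)) m <- m[m[[feat_col]] %in% universe, ]
  wide <- m |>
    dplyr::filter(sample_id %in% c(ids_ref, ids_mut)) |>
    dplyr::select(dplyr::all_of(c(feat_col, "sample_id", "norm"))) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = norm, values_fill = 0)
  x <- as.matrix(wide[, ids_ref, drop = FALSE])
  y <- as.matrix(wide[, ids_mut, drop = FALSE])
  nonzero <- rowSums(x) > 0 | rowSums(y) > 0
  if (any(!nonzero)) {
    message(sum(!nonzero), " feature(s) zero in both groups excluded from testing")
  }
  wide <- wide[nonzero, ]; x <- x[nonzero, , drop = FALSE]; y <- y[nonzero, , drop = FALSE]

  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  log2_fc <- rowMeans(ly) - rowMeans(lx)
  if (method == "moderated") {
    design <- stats::model.matrix(~ factor(rep(c("ref", "mut"), c(ncol(lx), ncol(ly))),
                                           levels = c("ref", "mut")))
    fit <- limma::eBayes(limma::lmFit(cbind(lx, ly), design))
    p <- fit$p.value[, 2]
  } else {
    p <- vapply(seq_len(nrow(wide)), function(i) {
      out <- tryCatch(stats::t.test(ly[i, ], lx[i, ])$p.value, error = function(e) NA_real_)
      if (is.na(out) && isTRUE(all.equal(mean(ly[i, ]), mean(lx[i, ])))) out <- 1
      out
    }, numeric(1))
  }

  tibble::tibble(
    circ_id = wide[[feat_col]],
    mean_ref = rowMeans(x),
    mean_mut = rowMeans(y),
    log2_fc = log2_fc,
    p_value = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    significant = !is.na(p) & p <= p_cutoff & abs(log2_fc) >= log2(fold_cutoff)
  ) |>
    dplyr::arrange(p_value)
}

#' Global circRNA accumulation test between genotypes
#'
#' Two-sided Mann-Whitney U test comparing the pooled distributions of
#' per-circRNA-per-replicate normalized back-splice counts between a mutant
#' and the reference genotype. The observation universe is either a supplied
#' consensus id set or all detected circRNAs.
#'
#' @inheritParams circ_fold_change_test
#' @param universe circ_id vector (e.g. a consensus set union) or `NULL` for
#'   all features in the matrix.
#' @return A `circleaf_global_test` object; see [tidy.circleaf_global_test()]
#'   and [glance.circleaf_global_test()].
#' @export
global_accumulation_test <- function(matrix, samples, genotype, reference = NULL,
                                     universe = NULL) {
  reference <- reference %||% samples$genotype[1]
  feat_col <- setdiff(names(matrix), c("sample_id", "raw", "norm"))[1]
  m <- matrix
  if (!is.null(universe)) m <- m[m[[feat_col]] %in% universe, ]
  if (nrow(m) == 0) {
    warning("empty universe: global accumulation test undefined")
    res <- list(
      p_value = NA_real_, stars = "", genotype = genotype, reference = reference,
      n_mut = 0L, n_ref = 0L, median_mut = NA_real_, median_ref = NA_real_,
      median_shift = NA_real_
    )
    class(res) <- "circleaf_global_test"
    return(res)
  }
  vals <- function(gt) {
    ids <- samples$sample_id[samples$genotype == gt]
    m$norm[m$sample_id %in% ids]
  }
  v_mut <- vals(genotype)
  v_ref <- vals(reference)
  if (length(v_mut) < 2 || length(v_ref) < 2) {
    stop("global accumulation test needs >= 2 observations per side")
  }
  wt <- suppressWarnings(stats::wilcox.test(v_mut, v_ref, alternative = "two.sided"))
  p <- wt$p.value
  stars <- if (is.na(p)) "" else if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  res <- list(
    p_value = p, stars = stars, genotype = genotype, reference = reference,
    n_mut = length(v_mut), n_ref = length(v_ref),
    median_mut = stats::median(v_mut), median_ref = stats::median(v_ref),
    median_shift = stats::median(v_mut) - stats::median(v_ref)
  )
  class(res) <- "circleaf_global_test"
  res
}

#' @export
print.circleaf_global_test <- function(x, ...) {
  cat(sprintf(
    "<global circRNA accumulation test> %s vs %s: p = %.4g %s (n = %d / %d, median shift = %.3g)\n",
    x$genotype, x$reference, x$p_value, x$stars, x$n_mut, x$n_ref, x$median_shift
  ))
  invisible(x)
}

#' Broom-style accessors for global accumulation tests
#'
#' @param x A `circleaf_global_test`.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble of the test result; `glance()`: the
#'   same with sample sizes only.
#' @export
tidy.circleaf_global_test <- function(x, ...) {
  tibble::tibble(
    genotype = x$genotype, reference = x$reference,
    p_value = x$p_value, stars = x$stars,
    median_mut = x$median_mut, median_ref = x$median_ref,
    median_shift = x$median_shift, n_mut = x$n_mut, n_ref = x$n_ref
  )
}

#' @rdname tidy.circleaf_global_test
#' @export
glance.circleaf_global_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, stars = x$stars, n_mut = x$n_mut, n_ref = x$n_ref)
}

#' Correlation between circular and linear abundances
#'
#' Pearson correlation over paired features (a circRNA and its linear
#' counterpart), each averaged across the replicates of the genotype under
#' study. Near-zero values indicate that circRNA production is uncoupled
#' from the production of the linear transcripts.
#'
#' @param circ_matrix,linear_matrix Long matrices (`norm` column; feature
#'   column first).
#' @param pairs Tibble mapping `circ_id` to `linear_id` (ids in the linear
#'   matrix's feature column).
#' @param samples Sample sheet.
#' @param genotype Genotype whose replicates are averaged.
#' @return One-row tibble `r`, `p_value`, `n_pairs`.
#' @export
circ_linear_correlation <- function(circ_matrix, linear_matrix, pairs, samples, genotype) {
  ids <- samples$sample_id[samples$genotype == genotype]
  feat_lin <- setdiff(names(linear_matrix), c("sample_id", "raw", "norm"))[1]
  cmeans <- circ_matrix |>
    dplyr::filter(sample_id %in% ids) |>
    dplyr::group_by(circ_id) |>
    dplyr::summarise(circ = mean(norm), .groups = "drop")
  lmeans <- linear_matrix |>
    dplyr::filter(sample_id %in% ids) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(feat_lin))) |>
    dplyr::summarise(linear = mean(norm), .groups = "drop")
  joined <- pairs |>
    dplyr::inner_join(cmeans, by = "circ_id") |>
    dplyr::inner_join(lmeans, by = stats::setNames(feat_lin, "linear_id"))
  if (nrow(joined) < 3) stop("circ-linear correlation needs >= 3 overlapping pairs")
  if (stats::sd(joined$circ) == 0 || stats::sd(joined$linear) == 0) {
    stop("circ-linear correlation undefined: zero variance in one member")
  }
  ct <- stats::cor.test(joined$circ, joined$linear)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(joined))
}

#' Global abundance test for linear counterparts
#'
#' The Mann-Whitney machinery of [global_accumulation_test()] applied to a
#' linear matrix, with the universe typically set to the linear counterparts
#' of the genotype's consensus circRNAs.
#'
#' @inheritParams global_accumulation_test
#' @export
linear_abundance_test <- function(matrix, samples, genotype, reference = NULL,
                                  universe = NULL) {
  global_accumulation_test(matrix, samples, genotype, reference = reference,
                           universe = universe)
}
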