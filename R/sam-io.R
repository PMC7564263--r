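#' Read SAM alignment records into a segment table
#'
#' Parses a SAM file into one row per alignment record, with coordinates
#' prepared for back-splice geometry checks: reference span (`ref_start`,
#' `ref_end`, 1-based closed) and the aligned interval of the *original* read
#' (`read_start`, `read_end`, clip-aware and orientation-corrected, so that
#' offsets always count from the read's first sequenced base). CIGAR
#' arithmetic is delegated to GenomicAlignments.
#'
#' Malformed records are skipped with a warning and counted in the
#' `malformed` attribute; a file without any header line is rejected.
#'
#' @param path Path to a SAM file.
#' @return A tibble with one row per record: `qname`, `flag`, `chrom`,
#'   `ref_start`, `ref_end`, `mapq`, `cigar`, `strand`, `mate` (1, 2, or 0
#'   for unpaired), `is_supplementary`, `is_secondary`, `is_unmapped`,
#'   `read_start`, `read_end`, `read_len`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "@")
  if (!any(is_header)) stop("SAM file has no header lines: ", path)
  body <- lines[!is_header]
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  bad <- nf < 11L
  flag <- suppressWarnings(as.integer(vapply(f, function(x) if (length(x) >= 2) x[2] else NA_character_, "")))
  pos <- suppressWarnings(as.integer(vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_, "")))
  bad <- bad | is.na(flag) | is.na(pos)
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    warning(n_malformed, " malformed SAM record(s) skipped in ", basename(path))
    f <- f[!bad]; flag <- flag[!bad]; pos <- pos[!bad]
  }
  if (length(f) == 0) {
    out <- tibble::tibble(
      qname = character(), flag = integer(), chrom = character(),
      ref_start = integer(), ref_end = integer(), mapq = integer(),
      cigar = character(), strand = character(), mate = integer(),
      is_supplementary = logical(), is_secondary = logical(),
      is_unmapped = logical(), read_start = integer(), read_end = integer(),
      read_len = integer(), seq = character()
    )
    attr(out, "malformed") <- n_malformed
    return(out)
  }
  qname <- vapply(f, `[[`, "", 1L)
  chrom <- vapply(f, `[[`, "", 3L)
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  cigar <- vapply(f, `[[`, "", 6L)
  seq <- vapply(f, `[[`, "", 10L)

  unmapped <- bitwAnd(flag, 4L) != 0L
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  mate <- dplyr::case_when(
    bitwAnd(flag, 64L) != 0L ~ 1L,
    bitwAnd(flag, 128L) != 0L ~ 2L,
    TRUE ~ 0L
  )

  ref_w <- rep(NA_integer_, length(cigar))
  aq <- rep(NA_integer_, length(cigar))
  clip_l <- rep(0L, length(cigar))
  clip_r <- rep(0L, length(cigar))
  has_cig <- cigar != "*" & !unmapped
  if (any(has_cig)) {
    cg <- cigar[has_cig]
    ref_w[has_cig] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cg)
    aq[has_cig] <- GenomicAlignments::cigarWidthAlongQuerySpace(cg, after.soft.clipping = TRUE)
    ops <- GenomicAlignments::explodeCigarOps(cg)
    lens <- GenomicAlignments::explodeCigarOpLengths(cg)
    clip_l[has_cig] <- mapply(function(o, l) {
      i <- which(!o %in% c("S", "H"))[1]
      if (is.na(i) || i == 1L) 0L else sum(l[seq_len(i - 1L)])
    }, ops, lens)
    clip_r[has_cig] <- mapply(function(o, l) {
      n <- length(o)
      i <- which(!o %in% c("S", "H"))
      i <- i[length(i)]
      if (i == n) 0L else sum(l[(i + 1L):n])
    }, ops, lens)
  }
  read_len <- clip_l + aq + clip_r
  read_start <- ifelse(strand == "+", clip_l + 1L, clip_r + 1L)
  read_end <- read_start + aq - 1L

  out <- tibble::tibble(
    qname = qname, flag = flag, chrom = chrom,
    ref_start = pos, ref_end = pos + ref_w - 1L,
    mapq = mapq, cigar = cigar, strand = strand, mate = mate,
    is_supplementary = bitwAnd(flag, 2048L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_unmapped = unmapped,
    read_start = as.integer(read_start), read_end = as.integer(read_end),
    read_len = as.integer(read_len), seq = seq
  )
  attr(out, "malformed") <- n_malformed
  out
}

#' Group alignment segments by read end
#'
#' Adds the grouping key used throughout detection: one group per sequenced
#' read end (`qname` x mate), never pooled across mates. Unmapped and
#' secondary records are retained but flagged; single-segment groups pass
#' through for linear counting.
#'
#' @param segments A [read_sam()] tibble.
#' @return The tibble with `group_id` and per-group `n_segments` columns.
#' @export
split_read_groups <- function(segments) {
  segments |>
    dplyr::mutate(group_id = paste0(qname, "/", mate)) |>
    dplyr::add_count(group_id, name = "n_segments")
}
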