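#' Count alignments per feature
#'
#' An alignment is counted for a feature when its footprint 5' end lies
#' within the feature span (1-based inclusive). For the stranded assays
#' (`rna`, `ribo`) the alignment strand must equal the feature strand;
#' metagenomic counting is unstranded. An alignment whose 5' end falls in
#' two same-strand overlapping features is counted for each.
#'
#' @param alignments Unique-perfect alignment tibble.
#' @param orfs Feature tibble (`orf_id` or `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`).
#' @param assay One of `"rna"`, `"ribo"` (stranded) or `"metagenomic"`.
#' @return A tibble with one row per feature: `feature_id`, `count`,
#'   plus attribute `library_size` (number of alignments supplied).
#' @export
count_features <- function(alignments, orfs, assay = c("ribo", "rna", "metagenomic")) {
  assay <- match.arg(assay)
  check_orfs_positions(orfs)
  id_col <- if ("orf_id" %in% names(orfs)) "orf_id" else "gene_id"
  if (!id_col %in% names(orfs)) {
    abort_metaribo("Feature table needs an `orf_id` or `gene_id` column.")
  }
  counts <- integer(nrow(orfs))
  if (nrow(alignments) > 0 && nrow(orfs) > 0) {
    five <- ifelse(alignments$strand == "+",
                   alignments$pos,
                   alignments$pos + alignments$length - 1L)
    stranded <- assay %in% c("rna", "ribo")
    reads_gr <- GenomicRanges::GRanges(
      seqnames = alignments$contig_id,
      ranges = IRanges::IRanges(start = five, width = 1L),
      strand = if (stranded) alignments$strand else "*"
    )
    feat_gr <- GenomicRanges::GRanges(
      seqnames = orfs$contig_id,
      ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
      strand = if (stranded) orfs$strand else "*"
    )
    counts <- GenomicRanges::countOverlaps(feat_gr, reads_gr,
                                           ignore.strand = !stranded)
  }
  out <- tibble::tibble(feature_id = orfs[[id_col]], count = as.integer(counts))
  attr(out, "library_size") <- nrow(alignments)
  out
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = count / ((length/1000) * (library_size/1e6))`; a zero count is
#' 0 RPKM. Doubling every count together with the library size leaves RPKM
#' unchanged.
#'
#' @param counts Nonnegative integer vector of feature counts.
#' @param lengths Feature lengths in nt (positive).
#' @param library_size Retained (unique-perfect) alignments in the sample.
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, library_size) {
  if (any(lengths <= 0)) abort_metaribo("Feature lengths must be positive.")
  if (length(library_size) != 1 || library_size <= 0) {
    abort_metaribo("`library_size` must be a single positive number.")
  }
  counts / ((lengths / 1000) * (library_size / 1e6))
}

#' Translation-evidence call from footprint RPKM
#'
#' Strictly-greater-than comparison: a footprint RPKM of exactly the
#' threshold is not called translated.
#'
#' @param rpkm_value Numeric vector of footprint RPKM values.
#' @param threshold Calling threshold (default 10).
#' @return Logical vector.
#' @export
call_translated <- function(rpkm_value, threshold = 10) {
  rpkm_value > threshold
}

#' Translational efficiency
#'
#' Footprint RPKM over RNA RPKM from the same sample. When the RNA RPKM is
#' zero the ratio is undefined and `NA` is returned.
#'
#' @param ribo_rpkm,rna_rpkm Numeric vectors of matched RPKM values.
#' @return Numeric vector; `NA` where `rna_rpkm == 0`.
#' @export
translation_efficiency <- function(ribo_rpkm, rna_rpkm) {
  if (length(ribo_rpkm) != length(rna_rpkm)) {
    abort_metaribo("`ribo_rpkm` and `rna_rpkm` must have equal length.")
  }
  ifelse(rna_rpkm == 0, NA_real_, ribo_rpkm / rna_rpkm)
}

log_with_pseudocount <- function(..., pseudocount = NULL) {
  vals <- c(...)
  if (is.null(pseudocount)) {
    pos <- vals[vals > 0]
    pseudocount <- if (length(pos) > 0) 0.5 * min(pos) else 0.5
  }
  list(pseudocount = pseudocount)
}

#' Compare two (or three) signal vectors
#'
#' Computes the statistics used to compare assay signal distributions:
#' Pearson correlation on log10-scaled values with a pseudocount of half
#' the smallest positive value, a two-sample Kolmogorov-Smirnov test, and
#' -- when a third vector is supplied -- Zou's 95% confidence interval for
#' the difference of the two overlapping dependent correlations
#' cor(x, y) - cor(x, z), flagged significant when the interval excludes 0.
#'
#' @param x,y Paired numeric vectors (e.g. RPKM per gene in two assays).
#' @param z Optional third vector sharing `x`, for the correlation
#'   comparison cor(x,y) vs cor(x,z).
#' @param conf_level Confidence level for Zou's interval (default 0.95).
#' @return A one-row tibble: `pearson_r`, `ks_D`, `ks_p` and, with `z`,
#'   `pearson_r_xz`, `zou_lower`, `zou_upper`, `zou_significant`.
#' @export
compare_signal_stats <- function(x, y, z = NULL, conf_level = 0.95) {
  if (length(x) != length(y)) abort_metaribo("`x` and `y` must have equal length.")
  pc <- log_with_pseudocount(x, y, if (is.null(z)) NULL else z)$pseudocount
  lx <- log10(x + pc)
  ly <- log10(y + pc)
  r12 <- stats::cor(lx, ly)
  ks <- suppressWarnings(stats::ks.test(x, y))
  out <- tibble::tibble(
    pearson_r = r12,
    ks_D = unname(ks$statistic),
    ks_p = ks$p.value
  )
  if (!is.null(z)) {
    if (length(z) != length(x)) abort_metaribo("`z` must have the same length as `x`.")
    n <- length(x)
    if (n < 4) abort_metaribo("Zou's interval needs at least 4 observations.")
    lz <- log10(z + pc)
    r13 <- stats::cor(lx, lz)
    r23 <- stats::cor(ly, lz)
    ci <- zou_difference_ci(r12, r13, r23, n, conf_level)
    out$pearson_r_xz <- r13
    out$zou_lower <- ci[1]
    out$zou_upper <- ci[2]
    out$zou_significant <- ci[1] > 0 || ci[2] < 0
  }
  out
}

# Zou (2007) confidence interval for the difference of two overlapping
# dependent correlations r12 - r13 (variable 1 shared), via Fisher-z
# individual intervals and the correlation between the two estimates.
zou_difference_ci <- function(r12, r13, r23, n, conf_level = 0.95) {
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  fisher <- function(r) atanh(r)
  inv <- function(z) tanh(z)
  se <- 1 / sqrt(n - 3)
  l1 <- inv(fisher(r12) - zcrit * se); u1 <- inv(fisher(r12) + zcrit * se)
  l2 <- inv(fisher(r13) - zcrit * se); u2 <- inv(fisher(r13) + zcrit * se)
  corr_r12_r13 <-
    ((r23 - 0.5 * r12 * r13) * (1 - r12^2 - r13^2 - r23^2) + r23^3) /
    ((1 - r12^2) * (1 - r13^2))
  d <- r12 - r13
  lower <- d - sqrt((r12 - l1)^2 + (u2 - r13)^2 -
                      2 * corr_r12_r13 * (r12 - l1) * (u2 - r13))
  upper <- d + sqrt((u1 - r12)^2 + (r13 - l2)^2 -
                      2 * corr_r12_r13 * (u1 - r12) * (r13 - l2))
  c(lower, upper)
}

#' Assemble a counts/RPKM table across samples
#'
#' Convenience wrapper stacking per-sample [count_features()] outputs into
#' a long tibble with RPKM and translation calls.
#'
#' @param counts_list Named list of [count_features()] results (names are
#'   sample/assay labels).
#' @param lengths Named vector of feature lengths (nt), names matching
#'   `feature_id`.
#' @param rpkm_threshold Translation-evidence threshold (default 10).
#' @return A long tibble: `feature_id`, `sample`, `count`, `library_size`,
#'   `rpkm`, `translated`.
#' @export
quantify_samples <- function(counts_list, lengths, rpkm_threshold = 10) {
  purrr::imap_dfr(counts_list, function(ct, label) {
    ls <- attr(ct, "library_size")
    tibble::tibble(
      feature_id = ct$feature_id,
      sample = label,
      count = ct$count,
      library_size = ls,
      rpkm = rpkm(ct$count, unname(lengths[ct$feature_id]), ls),
      translated = call_translated(
        rpkm(ct$count, unname(lengths[ct$feature_id]), ls), rpkm_threshold
      )
    )
  })
}
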