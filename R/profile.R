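#' Build per-contig, per-strand 5'-end signal tracks
#'
#' Each unique-perfect alignment contributes one count at its footprint
#' 5' position: the leftmost base for plus-strand alignments, the rightmost
#' for minus-strand. Total track mass equals the number of alignments. No
#' P-site offset is applied; downstream diagnostics work on raw 5'-end
#' signal.
#'
#' @param alignments Alignment tibble (already unique-perfect filtered).
#' @param genomes Contig tibble defining track lengths.
#' @return An `mrs_track` object: per contig, integer count vectors for the
#'   `+` and `-` strands.
#' @export
signal_track <- function(alignments, genomes) {
  check_genomes(genomes)
  lens <- stats::setNames(nchar(genomes$sequence), genomes$id)
  track <- lapply(lens, function(L) {
    list("+" = integer(L), "-" = integer(L))
  })
  if (nrow(alignments) > 0) {
    five <- ifelse(alignments$strand == "+",
                   alignments$pos,
                   alignments$pos + alignments$length - 1L)
    bad <- five < 1L | five > lens[alignments$contig_id] |
      alignments$pos < 1L |
      (alignments$pos + alignments$length - 1L) > lens[alignments$contig_id]
    if (any(bad | is.na(bad))) {
      abort_metaribo("Alignment extends beyond contig bounds.")
    }
    key <- split(seq_len(nrow(alignments)),
                 list(alignments$contig_id, alignments$strand), drop = TRUE)
    for (k in names(key)) {
      rows <- key[[k]]
      contig <- alignments$contig_id[rows[1]]
      strand <- alignments$strand[rows[1]]
      tab <- tabulate(five[rows], nbins = lens[contig])
      track[[contig]][[strand]] <- track[[contig]][[strand]] + tab
    }
  }
  structure(list(track = track, n_alignments = nrow(alignments)),
            class = "mrs_track")
}

#' @export
print.mrs_track <- function(x, ...) {
  cat(sprintf("<mrs_track> %d contig(s), %d alignment(s)\n",
              length(x$track), x$n_alignments))
  invisible(x)
}

track_mass <- function(track) {
  sum(vapply(track$track, function(tt) sum(tt[["+"]]) + sum(tt[["-"]]), numeric(1)))
}

# 5'-end counts at gene offsets 0..(nt_length-1) in reading direction.
gene_body_counts <- function(track, contig_id, start, end, strand) {
  tt <- track$track[[contig_id]]
  if (is.null(tt)) abort_metaribo(sprintf("Contig `%s` absent from track.", contig_id))
  if (strand == "+") tt[["+"]][start:end] else rev(tt[["-"]][start:end])
}

# Strand-oriented window of counts at `offsets` relative to genomic anchor
# position, out-of-contig offsets as 0.
window_counts <- function(track, contig_id, anchor_pos, strand, offsets) {
  tt <- track$track[[contig_id]]
  L <- length(tt[["+"]])
  pos <- if (strand == "+") anchor_pos + offsets else anchor_pos - offsets
  out <- numeric(length(offsets))
  ok <- pos >= 1L & pos <= L
  out[ok] <- tt[[strand]][pos[ok]]
  out
}

#' Metagene profile around start or stop codons
#'
#' For every gene with at least `min_reads` footprint 5' ends inside its
#' ORF, extracts the strand-oriented window of 5'-end counts around the
#' anchor (offset 0 is the first nucleotide of the start codon, or the
#' first nucleotide of the stop codon), normalizes each gene's window to
#' sum to one, and averages across genes. Per-gene normalization makes the
#' profile invariant to rescaling any single gene's coverage.
#'
#' @param track An `mrs_track` from [signal_track()].
#' @param orfs ORF or truth-gene tibble (columns `contig_id`, `start`,
#'   `end`, `strand`).
#' @param flank_nt Half-window width; offsets run from `-flank_nt` to
#'   `flank_nt - 1` (default 50).
#' @param min_reads Minimum in-ORF 5' ends for a gene to qualify (default 10).
#' @param anchor `"start"` or `"stop"`.
#' @return A tibble of class `mrs_metagene` with columns `offset` and
#'   `mean_signal`, and attributes `n_genes_used` and `anchor`. With no
#'   qualifying genes the profile is all zero and `n_genes_used` is 0.
#' @export
metagene_profile <- function(track, orfs, flank_nt = 50L, min_reads = 10L,
                             anchor = c("start", "stop")) {
  anchor <- match.arg(anchor)
  check_orfs_positions(orfs)
  offsets <- seq.int(-flank_nt, flank_nt - 1L)
  acc <- numeric(length(offsets))
  n_used <- 0L
  for (i in seq_len(nrow(orfs))) {
    body <- gene_body_counts(track, orfs$contig_id[i], orfs$start[i],
                             orfs$end[i], orfs$strand[i])
    if (sum(body) < min_reads) next
    anchor_pos <- if (anchor == "start") {
      if (orfs$strand[i] == "+") orfs$start[i] else orfs$end[i]
    } else {
      if (orfs$strand[i] == "+") orfs$end[i] - 2L else orfs$start[i] + 2L
    }
    win <- window_counts(track, orfs$contig_id[i], anchor_pos, orfs$strand[i], offsets)
    s <- sum(win)
    if (s > 0) win <- win / s
    acc <- acc + win
    n_used <- n_used + 1L
  }
  mean_signal <- if (n_used > 0) acc / n_used else acc
  tibble::new_tibble(
    list(offset = offsets, mean_signal = mean_signal),
    nrow = length(offsets),
    class = "mrs_metagene",
    n_genes_used = n_used,
    anchor = anchor
  )
}

check_orfs_positions <- function(orfs) {
  needed <- c("contig_id", "start", "end", "strand")
  if (!is.data.frame(orfs) || !all(needed %in% names(orfs))) {
    abort_metaribo(sprintf("Gene table must contain columns %s.",
                           paste(needed, collapse = ", ")))
  }
  invisible(orfs)
}

#' Triplet periodicity of in-ORF footprint signal
#'
#' Classifies every in-ORF 5' end by its offset from the gene start modulo
#' 3 (in the reading direction) and tests the three frame counts against
#' uniformity with a Pearson chi-square statistic (2 df). The statistic is
#' invariant to gene order and unaffected by off-ORF signal. With zero
#' in-ORF signal the counts are (0,0,0), fractions are undefined (NA) and
#' p is 1.
#'
#' @inheritParams metagene_profile
#' @return A one-row tibble: `frame0`, `frame1`, `frame2` counts,
#'   `frac0`, `frac1`, `frac2`, `chi2`, `p_value`.
#' @export
frame_periodicity <- function(track, orfs) {
  check_orfs_positions(orfs)
  frames <- numeric(3)
  for (i in seq_len(nrow(orfs))) {
    body <- gene_body_counts(track, orfs$contig_id[i], orfs$start[i],
                             orfs$end[i], orfs$strand[i])
    if (length(body) == 0) next
    f <- (seq_along(body) - 1L) %% 3L
    frames <- frames + vapply(0:2, function(k) sum(body[f == k]), numeric(1))
  }
  total <- sum(frames)
  if (total == 0) {
    return(tibble::tibble(
      frame0 = 0L, frame1 = 0L, frame2 = 0L,
      frac0 = NA_real_, frac1 = NA_real_, frac2 = NA_real_,
      chi2 = 0, p_value = 1
    ))
  }
  expected <- total / 3
  chi2 <- sum((frames - expected)^2 / expected)
  tibble::tibble(
    frame0 = as.integer(frames[1]), frame1 = as.integer(frames[2]),
    frame2 = as.integer(frames[3]),
    frac0 = frames[1] / total, frac1 = frames[2] / total, frac2 = frames[3] / total,
    chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  )
}

#' Start-codon enrichment ratio
#'
#' Mean metagene signal over the start window (offsets `[0, start_window)`)
#' divided by the mean over the body range (default: from the end of the
#' start window to the end of the profiled window). A flat profile gives
#' 1; a zero body mean returns `Inf` with a warning.
#'
#' @param profile An `mrs_metagene` from [metagene_profile()] anchored at
#'   the start codon.
#' @param start_window_nt Width of the start window (default 12).
#' @param body_range Optional integer pair of offsets (inclusive lower,
#'   exclusive upper) for the body.
#' @return The enrichment ratio (a single number).
#' @export
start_enrichment <- function(profile, start_window_nt = 12L, body_range = NULL) {
  stopifnot(inherits(profile, "mrs_metagene"))
  offsets <- profile$offset
  if (is.null(body_range)) {
    body_range <- c(start_window_nt, max(offsets) + 1L)
  }
  in_start <- offsets >= 0 & offsets < start_window_nt
  in_body <- offsets >= body_range[1] & offsets < body_range[2]
  if (!any(in_start) || !any(in_body)) {
    abort_metaribo("Profile window does not cover the requested ranges.")
  }
  start_mean <- mean(profile$mean_signal[in_start])
  body_mean <- mean(profile$mean_signal[in_body])
  if (body_mean == 0) {
    rlang::warn("Zero body signal; start enrichment reported as Inf.")
    return(Inf)
  }
  start_mean / body_mean
}
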