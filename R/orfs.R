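#' Translate an ORF nucleotide sequence
#'
#' Standard bacterial (translation table 11) codon semantics: the sequence
#' must be a whole number of codons and end with a stop codon, internal stop
#' codons are an error, and a permitted non-ATG initiator (GTG, TTG) is
#' rendered as methionine at position 1. The returned protein excludes the
#' stop codon.
#'
#' @param nt_sequence DNA string, length divisible by 3, ending in a stop codon.
#' @param start_codons Permitted initiator codons rendered as M.
#' @return The protein string.
#' @examples
#' translate_orf("ATGGCTTAA")  # "MA"
#' translate_orf("GTGGCTTAA")  # "MA", initiator rule
#' @export
translate_orf <- function(nt_sequence, start_codons = DEFAULT_START_CODONS) {
  nt_sequence <- toupper(nt_sequence)
  n <- nchar(nt_sequence)
  if (n == 0 || n %% 3 != 0) {
    abort_metaribo("ORF length must be a positive multiple of 3.")
  }
  codons <- substring(nt_sequence, seq(1, n, 3), seq(3, n, 3))
  k <- length(codons)
  if (!codons[k] %in% STOP_CODONS) {
    abort_metaribo("ORF must end with a stop codon.")
  }
  body <- codons[-k]
  if (any(body %in% STOP_CODONS)) {
    abort_metaribo(sprintf(
      "Internal stop codon at codon %d.", which(body %in% STOP_CODONS)[1]
    ))
  }
  aa <- unname(Biostrings::GENETIC_CODE[body])
  if (anyNA(aa)) abort_metaribo("Sequence contains an untranslatable codon.")
  if (length(aa) > 0 && body[1] %in% start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}

# ORFs in the three forward frames of one sequence. Returns start/end in
# coordinates of `seq`; the caller maps minus-strand results back.
scan_forward_frames <- function(seq, min_orf_nt, start_codons) {
  L <- nchar(seq)
  out <- vector("list", 3)
  for (f in 0:2) {
    pos <- seq.int(f + 1, by = 3, length.out = (L - f) %/% 3)
    if (length(pos) == 0) next
    codons <- substring(seq, pos, pos + 2)
    stop_i <- which(codons %in% STOP_CODONS)
    start_i <- which(codons %in% start_codons)
    if (length(stop_i) == 0 || length(start_i) == 0) next
    # Outermost start for each stop: first start codon after the previous
    # in-frame stop (no intervening in-frame stop by construction).
    prev_stop <- c(0L, stop_i[-length(stop_i)])
    first_after <- findInterval(prev_stop, start_i) + 1L
    ok <- first_after <= length(start_i) & start_i[pmin(first_after, length(start_i))] < stop_i
    if (!any(ok)) next
    a <- start_i[first_after[ok]]
    s <- stop_i[ok]
    nt_len <- 3L * (s - a + 1L)
    keep <- nt_len >= min_orf_nt
    if (!any(keep)) next
    out[[f + 1]] <- tibble::tibble(
      start = pos[a[keep]],
      end = pos[s[keep]] + 2L,
      nt_length = nt_len[keep]
    )
  }
  dplyr::bind_rows(out)
}

#' Find open reading frames by six-frame scanning
#'
#' Scans all six frames of every contig. For each in-frame stop codon the
#' ORF runs from the outermost upstream in-frame start codon (with no
#' intervening in-frame stop) to that stop, mirroring the maximal-ORF
#' convention of Prodigal-family gene callers; ORFs shorter than
#' `min_orf_nt` (stop codon included) are dropped. Coordinates are 1-based
#' inclusive on the contig with `start < end` regardless of strand.
#'
#' @param genomes Contig tibble (`id`, `sequence`), e.g. from [read_fasta()].
#' @param min_orf_nt Minimum ORF length in bp including the stop codon
#'   (default 15).
#' @param start_codons Permitted start codons (default ATG, GTG, TTG).
#' @return A tibble with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand`, `protein` (initiator included, stop excluded) and
#'   `nt_length`, sorted by contig, start and strand.
#' @examples
#' contig <- tibble::tibble(id = "c1", sequence = "ATGAAAAAAAAAAAATAA")
#' find_orfs(contig)
#' @export
find_orfs <- function(genomes, min_orf_nt = 15L, start_codons = DEFAULT_START_CODONS) {
  check_genomes(genomes)
  if (length(start_codons) == 0 || !all(start_codons %in% c("ATG", "GTG", "TTG"))) {
    abort_metaribo("`start_codons` must be a nonempty subset of ATG, GTG, TTG.")
  }
  per_contig <- purrr::map(seq_len(nrow(genomes)), function(i) {
    seq <- genomes$sequence[i]
    L <- nchar(seq)
    fwd <- scan_forward_frames(seq, min_orf_nt, start_codons)
    if (nrow(fwd) > 0) fwd$strand <- "+"
    rc <- scan_forward_frames(revcomp(seq), min_orf_nt, start_codons)
    if (nrow(rc) > 0) {
      rc <- dplyr::mutate(rc,
        new_start = L - .data$end + 1L,
        end = L - .data$start + 1L,
        start = .data$new_start,
        strand = "-"
      )
      rc$new_start <- NULL
    }
    orfs <- dplyr::bind_rows(fwd, rc)
    if (nrow(orfs) == 0) return(orfs)
    orfs$contig_id <- genomes$id[i]
    nt <- ifelse(
      orfs$strand == "+",
      substring(seq, orfs$start, orfs$end),
      revcomp(substring(seq, orfs$start, orfs$end))
    )
    orfs$protein <- vapply(nt, translate_orf, character(1),
                           start_codons = start_codons, USE.NAMES = FALSE)
    orfs
  })
  orfs <- dplyr::bind_rows(per_contig)
  if (nrow(orfs) == 0) {
    return(tibble::tibble(
      orf_id = character(), contig_id = character(), start = integer(),
      end = integer(), strand = character(), protein = character(),
      nt_length = integer()
    ))
  }
  orfs <- dplyr::arrange(orfs, .data$contig_id, .data$start, .data$strand)
  orfs$orf_id <- sprintf("%s:%d-%d:%s", orfs$contig_id, orfs$start, orfs$end, orfs$strand)
  dplyr::select(orfs, "orf_id", "contig_id", "start", "end", "strand",
                "protein", "nt_length")
}

#' Select small ORFs by protein length
#'
#' Keeps ORFs whose protein length (initiator methionine included, stop codon
#' excluded) lies within the inclusive amino-acid window; order is preserved.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param smorf_aa_range Inclusive protein-length window (default c(5, 50)).
#' @return The filtered ORF tibble.
#' @export
select_smorfs <- function(orfs, smorf_aa_range = c(5L, 50L)) {
  check_orfs(orfs)
  if (nrow(orfs) == 0) return(orfs)
  len <- nchar(orfs$protein)
  orfs[len >= smorf_aa_range[1] & len <= smorf_aa_range[2], , drop = FALSE]
}
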