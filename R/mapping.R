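#' Build an exact-match seed index
#'
#' Indexes every forward-strand k-mer position of every contig. Reads are
#' later placed by looking up their first k-mer (and the first k-mer of
#' their reverse complement) and verifying the full read, which yields the
#' complete set of 0-mismatch locations on both strands.
#'
#' @param genomes Contig tibble (`id`, `sequence`).
#' @param k Seed length (default 21); must be at least 8 and no longer than
#'   the reads to be mapped.
#' @return An `mrs_index` object.
#' @export
build_index <- function(genomes, k = 21L) {
  check_genomes(genomes)
  k <- as.integer(k)
  if (k < 8) abort_metaribo("Seed length `k` must be at least 8.")
  if (any(nchar(genomes$sequence) < k)) {
    abort_metaribo("Every contig must be at least `k` bases long.")
  }
  tabs <- purrr::map(seq_len(nrow(genomes)), function(i) {
    L <- nchar(genomes$sequence[i])
    pos <- seq_len(L - k + 1L)
    tibble::tibble(
      kmer = substring(genomes$sequence[i], pos, pos + k - 1L),
      contig = i,
      pos = pos
    )
  })
  tab <- dplyr::bind_rows(tabs)
  lookup <- split(seq_len(nrow(tab)), tab$kmer)
  structure(
    list(genomes = genomes, k = k, tab = tab, lookup = lookup),
    class = "mrs_index"
  )
}

#' @export
print.mrs_index <- function(x, ...) {
  cat(sprintf("<mrs_index> %d contig(s), k = %d, %d indexed k-mers\n",
              nrow(x$genomes), x$k, nrow(x$tab)))
  invisible(x)
}

# Candidate leftmost positions where `queries` (exact strings) may start,
# found by seeding on the first k-mer. Returns tibble(query_idx, contig, pos).
seed_candidates <- function(index, queries) {
  seeds <- substr(queries, 1L, index$k)
  hit_rows <- index$lookup[seeds]
  n_each <- lengths(hit_rows)
  if (sum(n_each) == 0) {
    return(tibble::tibble(query_idx = integer(), contig = integer(), pos = integer()))
  }
  rows <- unlist(hit_rows, use.names = FALSE)
  tibble::tibble(
    query_idx = rep.int(seq_along(queries), n_each),
    contig = index$tab$contig[rows],
    pos = index$tab$pos[rows]
  )
}

#' Map reads by exact matching
#'
#' Reports, for every read, all genomic locations (either strand) where the
#' read matches with zero mismatches. Matching is seed-and-verify: candidate
#' loci come from the first k-mer of the read (forward hits) and of its
#' reverse complement (reverse hits), and the full read is verified against
#' the contig. `n_hits` on every record of a read equals the total number of
#' perfect locations for that read; reads with no perfect location produce
#' no records, and reads shorter than the seed are dropped with a message.
#'
#' @param index An `mrs_index` from [build_index()].
#' @param reads Tibble with columns `read_id` and `sequence`, e.g. from
#'   [read_fastq()].
#' @return An alignment tibble with columns `read_id`, `contig_id`, `pos`
#'   (1-based leftmost), `strand`, `length`, `n_mismatch` (always 0) and
#'   `n_hits`.
#' @seealso [filter_unique_perfect()]
#' @export
map_reads <- function(index, reads) {
  stopifnot(inherits(index, "mrs_index"))
  if (!all(c("read_id", "sequence") %in% names(reads))) {
    abort_metaribo("`reads` must have columns `read_id` and `sequence`.")
  }
  empty <- tibble::tibble(
    read_id = character(), contig_id = character(), pos = integer(),
    strand = character(), length = integer(), n_mismatch = integer(),
    n_hits = integer()
  )
  if (nrow(reads) == 0) return(empty)
  short <- nchar(reads$sequence) < index$k
  if (any(short)) {
    rlang::inform(sprintf("Dropping %d read(s) shorter than the %d bp seed.",
                          sum(short), index$k))
    reads <- reads[!short, , drop = FALSE]
  }
  if (nrow(reads) == 0) return(empty)
  seqs <- toupper(reads$sequence)
  rc <- revcomp(seqs)
  lens <- nchar(seqs)
  contig_seqs <- index$genomes$sequence
  contig_lens <- nchar(contig_seqs)

  verify <- function(cand, expected, strand) {
    if (nrow(cand) == 0) {
      return(tibble::tibble(query_idx = integer(), contig = integer(),
                            pos = integer(), strand = character()))
    }
    end <- cand$pos + lens[cand$query_idx] - 1L
    inb <- end <= contig_lens[cand$contig]
    cand <- cand[inb, , drop = FALSE]
    end <- end[inb]
    if (nrow(cand) == 0) {
      return(tibble::tibble(query_idx = integer(), contig = integer(),
                            pos = integer(), strand = character()))
    }
    obs <- substring(contig_seqs[cand$contig], cand$pos, end)
    ok <- obs == expected[cand$query_idx]
    tibble::tibble(
      query_idx = cand$query_idx[ok],
      contig = cand$contig[ok],
      pos = cand$pos[ok],
      strand = strand
    )
  }

  fwd <- verify(seed_candidates(index, seqs), seqs, "+")
  rev <- verify(seed_candidates(index, rc), rc, "-")
  hits <- dplyr::bind_rows(fwd, rev)
  if (nrow(hits) == 0) return(empty)
  hits <- dplyr::distinct(hits)
  counts <- table(hits$query_idx)
  hits$n_hits <- as.integer(counts[as.character(hits$query_idx)])
  out <- tibble::tibble(
    read_id = reads$read_id[hits$query_idx],
    contig_id = index$genomes$id[hits$contig],
    pos = hits$pos,
    strand = hits$strand,
    length = lens[hits$query_idx],
    n_mismatch = 0L,
    n_hits = hits$n_hits
  )
  dplyr::arrange(out, .data$read_id, .data$contig_id, .data$pos)
}

#' Keep only perfect, unique alignments
#'
#' Retains exactly the records with `n_mismatch == 0` and `n_hits == 1`:
#' any second 0-mismatch location disqualifies the whole read. The filter
#' is idempotent.
#'
#' @param alignments Alignment tibble carrying `n_mismatch` and `n_hits`.
#' @return The filtered alignment tibble.
#' @export
filter_unique_perfect <- function(alignments) {
  if (!all(c("n_mismatch", "n_hits") %in% names(alignments))) {
    abort_metaribo("`alignments` must carry `n_mismatch` and `n_hits` columns.")
  }
  dplyr::filter(alignments, .data$n_mismatch == 0, .data$n_hits == 1)
}

#' Read alignments from a SAM file
#'
#' Translates SAM records into the package's alignment tibble. The `NM` tag
#' is mandatory (its absence is an error naming the line); `n_hits` is the
#' number of equal-best records (minimal `NM`) per read. Unmapped records
#' (FLAG 0x4) are skipped.
#'
#' @param path Path to a SAM file.
#' @return An alignment tibble (see [map_reads()]).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) abort_metaribo(sprintf("SAM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!stringr::str_starts(lines, "@"))
  empty <- tibble::tibble(
    read_id = character(), contig_id = character(), pos = integer(),
    strand = character(), length = integer(), n_mismatch = integer(),
    n_hits = integer()
  )
  if (length(body_idx) == 0) return(empty)
  fields <- stringr::str_split(lines[body_idx], "\t")
  recs <- purrr::map2(fields, body_idx, function(f, line_no) {
    if (length(f) < 11) {
      abort_metaribo(sprintf("Malformed SAM record at line %d.", line_no))
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(nm_tag) == 0) {
      abort_metaribo(sprintf("Missing NM tag in SAM record at line %d.", line_no))
    }
    len <- if (f[10] != "*") {
      nchar(f[10])
    } else {
      ops <- stringr::str_match_all(f[6], "(\\d+)([MIDNSHP=X])")[[1]]
      sum(as.integer(ops[ops[, 3] %in% c("M", "I", "S", "=", "X"), 2]))
    }
    tibble::tibble(
      read_id = f[1],
      contig_id = f[3],
      pos = as.integer(f[4]),
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      length = as.integer(len),
      n_mismatch = as.integer(sub("^NM:i:", "", nm_tag[1]))
    )
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::group_by(out, .data$read_id)
  out <- dplyr::mutate(out,
    n_hits = sum(.data$n_mismatch == min(.data$n_mismatch))
  )
  dplyr::ungroup(out)
}

#' Write alignments to a SAM file
#'
#' Emits minimal valid SAM: `@SQ` headers for every contig, the strand bit
#' in FLAG, MAPQ 255, a full-length match CIGAR and a mandatory `NM` tag.
#' If the alignment tibble carries a `sequence` column it is written in the
#' SEQ field, otherwise `*`.
#'
#' @param alignments Alignment tibble.
#' @param genomes Contig tibble used for `@SQ` headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genomes, path) {
  check_genomes(genomes)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", genomes$id, nchar(genomes$sequence))
  )
  if (nrow(alignments) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  nm <- if ("n_mismatch" %in% names(alignments)) alignments$n_mismatch else 0L
  seq_field <- if ("sequence" %in% names(alignments)) {
    # SAM stores SEQ in reference-forward orientation.
    ifelse(alignments$strand == "-", revcomp(alignments$sequence), alignments$sequence)
  } else {
    "*"
  }
  qual_field <- if ("sequence" %in% names(alignments)) {
    strrep("I", nchar(alignments$sequence))
  } else {
    "*"
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
    alignments$read_id,
    ifelse(alignments$strand == "-", 16L, 0L),
    alignments$contig_id,
    alignments$pos,
    alignments$length,
    seq_field,
    qual_field,
    nm
  )
  writeLines(c(header, body), path)
  invisible(path)
}
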