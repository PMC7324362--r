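#' Read a FASTA file of contigs
#'
#' Reads DNA sequences into a tibble with one row per contig. Lowercase
#' bases are normalized to uppercase; any symbol outside A/C/G/T is a hard
#' error reporting the offending position, and duplicate record ids are
#' rejected. An optional `taxon=<label>` tag in the description line is
#' parsed into the `taxon` column.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence` and `taxon` (NA when no
#'   taxon tag is present).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_metaribo(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- stringr::str_split_fixed(headers, "\\s+", 2)[, 1]
  taxon <- stringr::str_match(headers, "taxon=(\\S+)")[, 2]
  genomes <- tibble::tibble(
    id = ids,
    sequence = unname(toupper(as.character(set))),
    taxon = unname(taxon)
  )
  check_genomes(genomes)
  genomes
}

#' Write contigs to a FASTA file
#'
#' Sequences are wrapped at 80 columns. A non-missing `taxon` column is
#' written as a `taxon=<label>` tag on the header so that
#' `read_fasta(write_fasta(x))` round-trips id, sequence and taxon.
#'
#' @param genomes Tibble with columns `id`, `sequence`, optionally `taxon`.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 80) {
  if (!all(c("id", "sequence") %in% names(genomes))) {
    abort_metaribo("`genomes` must have columns `id` and `sequence`.")
  }
  dup <- genomes$id[duplicated(genomes$id)]
  if (length(dup) > 0) {
    abort_metaribo(sprintf("Duplicate contig id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    header <- genomes$id[i]
    if ("taxon" %in% names(genomes) && !is.na(genomes$taxon[i])) {
      header <- paste0(header, " taxon=", genomes$taxon[i])
    }
    writeLines(paste0(">", header), con)
    seq <- genomes$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort_metaribo(sprintf("FASTQ file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(
    read_id = stringr::str_split_fixed(names(set), "\\s+", 2)[, 1],
    sequence = unname(as.character(set))
  )
}

#' Write reads to a FASTQ file
#'
#' Simulated reads are error-free, so a constant quality string ("I") is
#' emitted for every base.
#'
#' @param reads Tibble with columns `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$sequence))
  out <- character(4L * n)
  out[seq(1, 4 * n, 4)] <- paste0("@", reads$read_id)
  out[seq(2, 4 * n, 4)] <- reads$sequence
  out[seq(3, 4 * n, 4)] <- "+"
  out[seq(4, 4 * n, 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Write ORFs as GFF3
#'
#' Emits one CDS feature per ORF with 1-based inclusive coordinates and
#' `ID` plus `protein_length` attributes.
#'
#' @param orfs ORF tibble (see [find_orfs()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(orfs, path, source = "metaribo") {
  check_orfs(orfs)
  lines <- "##gff-version 3"
  if (nrow(orfs) > 0) {
    attrs <- sprintf("ID=%s;protein_length=%d", orfs$orf_id, nchar(orfs$protein))
    lines <- c(lines, sprintf(
      "%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
      orfs$contig_id, source, orfs$start, orfs$end, orfs$strand, attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports CDS/gene features into the package's feature-tibble layout so
#' externally produced gene models can replace the built-in ORF scan.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types GFF3 `type` values to keep (default CDS and gene).
#' @return A tibble with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_gff3 <- function(path, feature_types = c("CDS", "gene")) {
  if (!file.exists(path)) abort_metaribo(sprintf("GFF3 file not found: %s", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort_metaribo("Reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  fallback <- sprintf("%s:%d-%d:%s",
                      as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr), GenomicRanges::end(gr),
                      as.character(GenomicRanges::strand(gr)))
  tibble::tibble(
    orf_id = ifelse(is.na(ids), fallback, ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write ORFs as BED6
#'
#' BED uses 0-based half-open coordinates; all other package I/O is 1-based
#' inclusive.
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(orfs, path) {
  check_orfs(orfs)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    orfs$contig_id, orfs$start - 1L, orfs$end, orfs$orf_id, orfs$strand
  )
  writeLines(lines, path)
  invisible(path)
}
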