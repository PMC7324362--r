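# Feature assignment for one read 5' end; same-strand overlapping genes are
# resolved toward the gene whose start codon is closest (ambiguities tallied).
assign_reads_to_features <- function(alignments, orfs, assay) {
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
  ov <- GenomicRanges::findOverlaps(reads_gr, feat_gr, ignore.strand = !stranded)
  hits <- tibble::tibble(
    read_row = S4Vectors::queryHits(ov),
    feat_row = S4Vectors::subjectHits(ov)
  )
  n_ambiguous <- 0L
  if (nrow(hits) > 0) {
    # distance from the read 5' end to each candidate gene's start codon
    gene_start <- ifelse(orfs$strand[hits$feat_row] == "+",
                         orfs$start[hits$feat_row], orfs$end[hits$feat_row])
    hits$dist <- abs(five[hits$read_row] - gene_start)
    dup <- duplicated(hits$read_row) | duplicated(hits$read_row, fromLast = TRUE)
    n_ambiguous <- length(unique(hits$read_row[dup]))
    hits <- dplyr::slice_min(dplyr::group_by(hits, .data$read_row),
                             .data$dist, n = 1, with_ties = FALSE)
    hits <- dplyr::ungroup(hits)
  }
  list(hits = hits, n_ambiguous = n_ambiguous)
}

#' Propagate gene taxonomy to reads
#'
#' Classifies each read by the taxon of the gene containing its 5' end
#' (strand-enforced for the rna/ribo assays), enabling like-for-like
#' taxonomic comparison between technologies whose reads are too short to
#' classify directly. Reads hitting no gene, or a gene absent from the
#' taxon table, are unclassified (the latter with a logged tally).
#'
#' @param alignments Unique-perfect alignment tibble.
#' @param orfs Feature tibble (`orf_id`/`gene_id`, coordinates, strand).
#' @param gene_taxa Tibble mapping feature ids to taxa: columns `id`,
#'   `taxon`.
#' @param assay Assay of the alignments (controls strand enforcement).
#' @return A list of class `mrs_taxonomy`: `read_taxa` (tibble `read_id`,
#'   `taxon`, NA when unclassified), `abundance` (tibble `taxon`,
#'   `fraction` of classified reads), `unclassified_fraction`,
#'   `n_ambiguous`, `n_missing_taxon`.
#' @export
propagate_taxonomy <- function(alignments, orfs, gene_taxa,
                               assay = c("ribo", "rna", "metagenomic")) {
  assay <- match.arg(assay)
  check_orfs_positions(orfs)
  id_col <- if ("orf_id" %in% names(orfs)) "orf_id" else "gene_id"
  if (!all(c("id", "taxon") %in% names(gene_taxa))) {
    abort_metaribo("`gene_taxa` must have columns `id` and `taxon`.")
  }
  read_taxa <- tibble::tibble(read_id = alignments$read_id, taxon = NA_character_)
  n_ambiguous <- 0L
  n_missing <- 0L
  if (nrow(alignments) > 0 && nrow(orfs) > 0) {
    asg <- assign_reads_to_features(alignments, orfs, assay)
    n_ambiguous <- asg$n_ambiguous
    if (nrow(asg$hits) > 0) {
      feat_ids <- orfs[[id_col]][asg$hits$feat_row]
      taxa <- gene_taxa$taxon[match(feat_ids, gene_taxa$id)]
      n_missing <- sum(is.na(taxa))
      read_taxa$taxon[asg$hits$read_row] <- taxa
    }
  }
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "%d read(s) hit genes without a taxon label; counted unclassified.", n_missing
    ))
  }
  classified <- read_taxa$taxon[!is.na(read_taxa$taxon)]
  abundance <- if (length(classified) > 0) {
    tab <- table(classified)
    tibble::tibble(
      taxon = names(tab),
      fraction = as.numeric(tab) / length(classified)
    )
  } else {
    tibble::tibble(taxon = character(), fraction = numeric())
  }
  structure(
    list(
      read_taxa = read_taxa,
      abundance = dplyr::arrange(abundance, dplyr::desc(.data$fraction)),
      unclassified_fraction = if (nrow(read_taxa) > 0) {
        mean(is.na(read_taxa$taxon))
      } else {
        NA_real_
      },
      n_ambiguous = n_ambiguous,
      n_missing_taxon = n_missing
    ),
    class = "mrs_taxonomy"
  )
}

#' @export
print.mrs_taxonomy <- function(x, ...) {
  cat(sprintf("<mrs_taxonomy> %d read(s), %.1f%% unclassified\n",
              nrow(x$read_taxa), 100 * (x$unclassified_fraction %||% NA)))
  print(x$abundance)
  invisible(x)
}

#' Group rare taxa into "Other"
#'
#' Taxa with relative abundance strictly below the threshold are merged
#' into a single "Other" entry; the total is preserved.
#'
#' @param abundance Tibble with columns `taxon` and `fraction`.
#' @param threshold Strict lower bound for keeping a taxon (default 0.03).
#' @return The grouped abundance tibble (no "Other" row when nothing is
#'   grouped).
#' @export
group_other <- function(abundance, threshold = 0.03) {
  if (!all(c("taxon", "fraction") %in% names(abundance))) {
    abort_metaribo("`abundance` must have columns `taxon` and `fraction`.")
  }
  rare <- abundance$fraction < threshold
  if (!any(rare)) return(abundance)
  kept <- abundance[!rare, , drop = FALSE]
  dplyr::bind_rows(
    kept,
    tibble::tibble(taxon = "Other", fraction = sum(abundance$fraction[rare]))
  )
}

#' Scan the genomic neighborhood of a smORF
#'
#' Neighbors are the genes at rank distance 1..`max_genes` on either side
#' of the smORF along its contig (rank in start-coordinate order,
#' strand-independent). Their domain annotations are filtered by the hit
#' rule: e-value at most `evalue_max` and PSSM coverage at least
#' `coverage_min`.
#'
#' @param orfs Feature tibble for one or more contigs.
#' @param smorf_id Feature id of the anchor smORF.
#' @param domain_table Tibble `(orf_id, domain_id, e_value, pssm_coverage)`
#'   standing in for an external domain search.
#' @param max_genes Maximum rank distance (default 10).
#' @param evalue_max,coverage_min Domain hit filter (defaults 0.05, 0.80).
#' @return A tibble of neighbor domain hits: `orf_id`, `rank_distance`,
#'   `domain_id`, `e_value`, `pssm_coverage` (zero rows when the smORF has
#'   no annotated neighbors).
#' @export
neighborhood_scan <- function(orfs, smorf_id, domain_table, max_genes = 10L,
                              evalue_max = 0.05, coverage_min = 0.80) {
  check_orfs_positions(orfs)
  id_col <- if ("orf_id" %in% names(orfs)) "orf_id" else "gene_id"
  if (!smorf_id %in% orfs[[id_col]]) {
    abort_metaribo(sprintf("smORF `%s` not found in the feature table.", smorf_id))
  }
  anchor <- orfs[orfs[[id_col]] == smorf_id, , drop = FALSE]
  same_contig <- orfs[orfs$contig_id == anchor$contig_id[1], , drop = FALSE]
  same_contig <- same_contig[order(same_contig$start, same_contig[[id_col]]), ,
                             drop = FALSE]
  pos <- which(same_contig[[id_col]] == smorf_id)
  rank_dist <- abs(seq_len(nrow(same_contig)) - pos)
  neighbors <- same_contig[rank_dist >= 1 & rank_dist <= max_genes, , drop = FALSE]
  nd <- rank_dist[rank_dist >= 1 & rank_dist <= max_genes]
  if (nrow(neighbors) == 0) {
    return(tibble::tibble(
      orf_id = character(), rank_distance = integer(), domain_id = character(),
      e_value = numeric(), pssm_coverage = numeric()
    ))
  }
  hits <- dplyr::inner_join(
    tibble::tibble(orf_id = neighbors[[id_col]], rank_distance = nd),
    domain_table,
    by = "orf_id"
  )
  dplyr::filter(hits, .data$e_value <= evalue_max,
                .data$pssm_coverage >= coverage_min)
}

#' Domain co-occurrence across smORF neighborhoods
#'
#' Runs [neighborhood_scan()] for every smORF and counts, per domain, the
#' number of smORFs with that domain among their neighbors (the
#' "n of m smORFs near a two-component system"-style summary).
#'
#' @inheritParams neighborhood_scan
#' @param smorf_ids Feature ids of the anchor smORFs.
#' @return A tibble: `domain_id`, `n_smorfs`, sorted by decreasing count.
#' @export
neighborhood_cooccurrence <- function(orfs, smorf_ids, domain_table,
                                      max_genes = 10L, evalue_max = 0.05,
                                      coverage_min = 0.80) {
  per <- purrr::map_dfr(smorf_ids, function(s) {
    hits <- neighborhood_scan(orfs, s, domain_table, max_genes, evalue_max,
                              coverage_min)
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(smorf_id = s, domain_id = unique(hits$domain_id))
  })
  if (nrow(per) == 0) {
    return(tibble::tibble(domain_id = character(), n_smorfs = integer()))
  }
  out <- dplyr::count(per, .data$domain_id, name = "n_smorfs")
  dplyr::arrange(out, dplyr::desc(.data$n_smorfs), .data$domain_id)
}

#' Call family cellular localization
#'
#' A family is labelled secreted (resp. transmembrane) when at least
#' `member_fraction` of its members carry the corresponding per-protein
#' flag (inclusive bound); both labels can be reported together, and
#' families qualifying for neither are `"none"`.
#'
#' @param families `mrs_families` tibble with `member_ids` list-column.
#' @param per_protein_flags Tibble `(id, secreted, transmembrane)` covering
#'   every member (logical flags).
#' @param member_fraction Inclusive qualifying fraction (default 0.80).
#' @return `families` with a `localization` character column (`"none"`,
#'   `"secreted"`, `"transmembrane"` or `"secreted+transmembrane"`).
#' @export
localization_call <- function(families, per_protein_flags, member_fraction = 0.80) {
  if (!all(c("id", "secreted", "transmembrane") %in% names(per_protein_flags))) {
    abort_metaribo("`per_protein_flags` needs columns `id`, `secreted`, `transmembrane`.")
  }
  families$localization <- vapply(families$member_ids, function(ids) {
    rows <- match(ids, per_protein_flags$id)
    if (anyNA(rows)) {
      abort_metaribo(sprintf(
        "Missing localization flag(s) for member(s): %s",
        paste(utils::head(ids[is.na(rows)], 5), collapse = ", ")
      ))
    }
    sec <- mean(per_protein_flags$secreted[rows]) >= member_fraction
    tm <- mean(per_protein_flags$transmembrane[rows]) >= member_fraction
    if (sec && tm) "secreted+transmembrane" else if (sec) "secreted" else if (tm) "transmembrane" else "none"
  }, character(1))
  families
}
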