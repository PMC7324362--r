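# Karlin-Altschul parameters for gapped BLOSUM62, gap open 11 / extend 1
# (standard protein-search values).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Pairwise protein alignment with search statistics
#'
#' BLOSUM62 alignment with gap open 11 and gap extend 1. The default
#' `"local"` mode is Smith-Waterman, used for homology search; `"global"`
#' mode is Needleman-Wunsch over the full sequences, the semantics used for
#' CD-Hit-style clustering where the alignment must span the sequences. Identity is
#' identical residues divided by alignment columns (internal gaps included,
#' end gaps excluded), and the bit score and e-value follow Karlin-Altschul
#' statistics with search space `nchar(a) * nchar(b) * n_subjects`
#' (meaningful for the local mode).
#'
#' @param a_protein Query protein string.
#' @param b_protein Subject protein string.
#' @param n_subjects Number of subject sequences in the notional database
#'   (scales the e-value; default 1).
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @return A one-row tibble: `score`, `bit_score`, `e_value`, `identity`,
#'   `alignment_length`, `aligned_query_fraction` (alignment columns over
#'   query length) and `subject_coverage` (aligned subject span over
#'   subject length).
#' @export
pairwise_align <- function(a_protein, b_protein, n_subjects = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (nchar(a_protein) == 0 || nchar(b_protein) == 0) {
    abort_metaribo("Protein sequences must be nonempty.")
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a_protein),
    subject = Biostrings::AAString(b_protein),
    type = mode,
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11,
    gapExtension = 1
  )
  s <- Biostrings::score(aln)
  aligned_p <- as.character(Biostrings::alignedPattern(aln))
  n_cols <- nchar(aligned_p)
  n_ident <- Biostrings::nmatch(aln)
  bit <- (KA_LAMBDA * s - log(KA_K)) / log(2)
  evalue <- nchar(a_protein) * nchar(b_protein) * n_subjects * 2^(-bit)
  subj_span <- IRanges::width(Biostrings::subject(aln))
  tibble::tibble(
    score = s,
    bit_score = bit,
    e_value = evalue,
    identity = if (n_cols > 0) n_ident / n_cols else 0,
    alignment_length = n_cols,
    aligned_query_fraction = n_cols / nchar(a_protein),
    subject_coverage = subj_span / nchar(b_protein)
  )
}

#' Greedy incremental identity clustering of proteins
#'
#' CD-Hit-style greedy clustering: sequences are sorted by length
#' (descending, ties by id) and processed in order. The first sequence
#' founds cluster 1; each subsequent sequence joins the best-matching
#' qualifying cluster -- highest identity to the cluster representative
#' among clusters where identity is at least `identity_c`, the
#' shorter/longer length ratio is at least `length_diff_cutoff`, and the
#' alignment covers at least `long_coverage` of the longer sequence -- or
#' founds a new cluster. Representatives are therefore the longest members
#' (ties broken lexicographically by id). Identity and coverage come from
#' global alignment ([pairwise_align()] `"global"` mode), the appropriate
#' semantics when the alignment must span nearly the whole longer sequence.
#'
#' @param proteins Tibble with columns `id` and `protein` (optionally
#'   `nt_sequence`, carried through for members).
#' @param identity_c Identity threshold (default 0.50).
#' @param length_diff_cutoff Minimum shorter/longer length ratio
#'   (default 0.95).
#' @param long_coverage Minimum aligned fraction of the longer sequence
#'   (default 0.95).
#' @return A tibble of class `mrs_families`: one row per family with
#'   `family_id`, `representative_id`, `n_members` and list-columns
#'   `member_ids`, `member_proteins` (and `member_nt_sequences` when
#'   nucleotide sequences were supplied).
#' @export
greedy_cluster <- function(proteins, identity_c = 0.50,
                           length_diff_cutoff = 0.95, long_coverage = 0.95) {
  if (!all(c("id", "protein") %in% names(proteins)) || nrow(proteins) == 0) {
    abort_metaribo("`proteins` must be a nonempty tibble with `id` and `protein`.")
  }
  if (anyDuplicated(proteins$id)) abort_metaribo("Protein ids must be unique.")
  ord <- order(-nchar(proteins$protein), proteins$id)
  proteins <- proteins[ord, , drop = FALSE]
  reps <- integer(0)          # row index of each cluster representative
  members <- list()
  for (i in seq_len(nrow(proteins))) {
    best_cluster <- NA_integer_
    best_identity <- -Inf
    for (cl in seq_along(reps)) {
      rep_row <- reps[cl]
      len_ratio <- nchar(proteins$protein[i]) / nchar(proteins$protein[rep_row])
      if (len_ratio < length_diff_cutoff) next
      hit <- pairwise_align(proteins$protein[i], proteins$protein[rep_row],
                            mode = "global")
      if (hit$identity >= identity_c && hit$subject_coverage >= long_coverage &&
          hit$identity > best_identity) {
        best_identity <- hit$identity
        best_cluster <- cl
      }
    }
    if (is.na(best_cluster)) {
      reps <- c(reps, i)
      members[[length(members) + 1]] <- i
    } else {
      members[[best_cluster]] <- c(members[[best_cluster]], i)
    }
  }
  out <- tibble::tibble(
    family_id = sprintf("fam%04d", seq_along(reps)),
    representative_id = proteins$id[reps],
    n_members = lengths(members),
    member_ids = lapply(members, function(m) proteins$id[m]),
    member_proteins = lapply(members, function(m) proteins$protein[m])
  )
  if ("nt_sequence" %in% names(proteins)) {
    out$member_nt_sequences <- lapply(members, function(m) proteins$nt_sequence[m])
  }
  class(out) <- c("mrs_families", class(out))
  out
}

#' Assign small-protein homologs to reference families
#'
#' Queries each smORF protein against family representatives and keeps the
#' best (lowest e-value) hit satisfying the significance filter: e-value at
#' most `evalue_max` and hit length between the bounds of `length_window`
#' (fractions of the query protein length; alignment-column convention, see
#' `length_basis`).
#'
#' @param smorf_proteins Tibble with `id` and `protein` columns.
#' @param family_representatives Tibble with `family_id` and `protein`.
#' @param evalue_max Significance cap on the e-value (default 0.05).
#' @param length_window Allowed hit length as a fraction of the query
#'   length (default c(0.90, 1.10)).
#' @param length_basis `"alignment"` (alignment columns, default) or
#'   `"subject"` (subject length) as the hit-length definition.
#' @return A tibble of links: `id`, `family_id`, `identity`, `e_value`,
#'   `hit_length_fraction`.
#' @export
assign_family_homologs <- function(smorf_proteins, family_representatives,
                                   evalue_max = 0.05,
                                   length_window = c(0.90, 1.10),
                                   length_basis = c("alignment", "subject")) {
  length_basis <- match.arg(length_basis)
  n_subj <- nrow(family_representatives)
  links <- purrr::map_dfr(seq_len(nrow(smorf_proteins)), function(i) {
    q <- smorf_proteins$protein[i]
    hits <- purrr::map_dfr(seq_len(n_subj), function(j) {
      h <- pairwise_align(q, family_representatives$protein[j], n_subjects = n_subj)
      h$family_id <- family_representatives$family_id[j]
      h
    })
    hits$hit_length_fraction <- if (length_basis == "alignment") {
      hits$alignment_length / nchar(q)
    } else {
      nchar(family_representatives$protein) / nchar(q)
    }
    hits <- hits[hits$e_value <= evalue_max &
                   hits$hit_length_fraction >= length_window[1] &
                   hits$hit_length_fraction <= length_window[2], , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    best <- hits[which.min(hits$e_value), , drop = FALSE]
    tibble::tibble(
      id = smorf_proteins$id[i],
      family_id = best$family_id,
      identity = best$identity,
      e_value = best$e_value,
      hit_length_fraction = best$hit_length_fraction
    )
  })
  if (nrow(links) == 0) {
    links <- tibble::tibble(
      id = character(), family_id = character(), identity = numeric(),
      e_value = numeric(), hit_length_fraction = numeric()
    )
  }
  links
}

#' Flag families with protein-synthesis evidence
#'
#' A family is considered synthesized when at least one linked smORF is
#' called translated (footprint RPKM strictly above the threshold).
#' Evidence is monotone: adding translated links never unsets the flag.
#'
#' @param families `mrs_families` tibble (or any tibble with `family_id`).
#' @param homolog_links Links from [assign_family_homologs()].
#' @param translated_calls Tibble with `id` and logical `translated`
#'   covering every linked smORF id.
#' @return `families` with a logical `synthesized` column.
#' @export
family_synthesis_evidence <- function(families, homolog_links, translated_calls) {
  dangling <- setdiff(homolog_links$id, translated_calls$id)
  if (length(dangling) > 0) {
    abort_metaribo(sprintf(
      "Homolog link(s) refer to smORF id(s) without translation calls: %s",
      paste(utils::head(dangling, 5), collapse = ", ")
    ))
  }
  linked <- dplyr::left_join(homolog_links, translated_calls, by = "id")
  synth <- dplyr::summarise(
    dplyr::group_by(linked, .data$family_id),
    synthesized = any(.data$translated)
  )
  families$synthesized <- families$family_id %in%
    synth$family_id[synth$synthesized]
  families
}

#' Collapse family members to unique DNA sequences
#'
#' Exact-string deduplication of member nucleotide sequences, reported in
#' descending occurrence order; occurrence counts sum to the member count.
#'
#' @param members Tibble with columns `member_id` and `nt_sequence`.
#' @return A tibble: `nt_sequence`, `n_occurrences`, sorted by decreasing
#'   occurrence (ties by sequence).
#' @export
collapse_unique_dna <- function(members) {
  if (!all(c("member_id", "nt_sequence") %in% names(members))) {
    abort_metaribo("`members` must have columns `member_id` and `nt_sequence`.")
  }
  if (anyNA(members$nt_sequence)) {
    bad <- members$member_id[is.na(members$nt_sequence)][1]
    abort_metaribo(sprintf("Missing nucleotide sequence for member `%s`.", bad))
  }
  out <- dplyr::count(members, .data$nt_sequence, name = "n_occurrences")
  dplyr::arrange(out, dplyr::desc(.data$n_occurrences), .data$nt_sequence)
}

#' Hypergeometric domain-enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least
#' `k_sample_with_domain` domain-bearing members in a sample of size
#' `n_sample` drawn from a population of `n_population` containing
#' `k_population_with_domain` domain-bearing members.
#'
#' @param n_population Population size.
#' @param k_population_with_domain Domain-bearing members in the population.
#' @param n_sample Sample size.
#' @param k_sample_with_domain Observed domain-bearing members in the sample.
#' @return The p-value P(X >= k_sample_with_domain).
#' @examples
#' domain_enrichment(10, 5, 5, 5)  # 1/252
#' @export
domain_enrichment <- function(n_population, k_population_with_domain,
                              n_sample, k_sample_with_domain) {
  if (k_population_with_domain > n_population || n_sample > n_population ||
      k_sample_with_domain > n_sample ||
      k_sample_with_domain > k_population_with_domain) {
    abort_metaribo("Inconsistent hypergeometric counts.")
  }
  stats::phyper(k_sample_with_domain - 1, k_population_with_domain,
                n_population - k_population_with_domain, n_sample,
                lower.tail = FALSE)
}
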