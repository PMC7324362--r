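#' Footprint signal model
#'
#' Describes the positional distribution of ribosome-footprint 5' ends used
#' by the read simulator: a body density modulated by reading-frame weights
#' (triplet periodicity), multiplicative peaks over windows at the start and
#' stop codons, and a uniform off-ORF background. Start/stop windows default
#' to 12 nt (a whole number of codons, so peaks do not distort the overall
#' frame mix) and the background defaults to a per-bp rate that makes
#' off-ORF footprints a negligible (<0.1%) contamination, consistent with an
#' error-free footprint model.
#'
#' @param start_peak_weight Multiplier over body density within the start
#'   window (default 10).
#' @param stop_peak_weight Multiplier within the stop window (default 5).
#' @param start_window_nt,stop_window_nt Window widths in nt (default 12).
#' @param frame_weights Probabilities of the three codon frames for a body
#'   5' end; must sum to 1 (default c(0.6, 0.2, 0.2)).
#' @param background_rate Off-ORF 5' ends per bp per strand, on the scale of
#'   unit mean gene mass (default 1e-7).
#' @return A `signal_model` list.
#' @export
signal_model <- function(start_peak_weight = 10, stop_peak_weight = 5,
                         start_window_nt = 12L, stop_window_nt = 12L,
                         frame_weights = c(0.6, 0.2, 0.2),
                         background_rate = 1e-7) {
  if (length(frame_weights) != 3 || any(frame_weights < 0) ||
      abs(sum(frame_weights) - 1) > 1e-12) {
    abort_metaribo("`frame_weights` must be 3 nonnegative values summing to 1.")
  }
  if (start_peak_weight < 0 || stop_peak_weight < 0 || background_rate < 0) {
    abort_metaribo("Peak weights and background rate must be nonnegative.")
  }
  structure(
    list(
      start_peak_weight = start_peak_weight,
      stop_peak_weight = stop_peak_weight,
      start_window_nt = as.integer(start_window_nt),
      stop_window_nt = as.integer(stop_window_nt),
      frame_weights = frame_weights,
      background_rate = background_rate
    ),
    class = "signal_model"
  )
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# aa -> synonymous codons, standard code, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

random_protein <- function(len_aa) {
  aas <- setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")
  paste0("M", paste(sample(aas, len_aa - 1, replace = TRUE), collapse = ""))
}

# Reverse-translate: ATG initiator, random synonymous codons, random stop.
protein_to_nt <- function(protein, codons = codon_table()) {
  aa <- strsplit(protein, "")[[1]]
  body <- vapply(aa[-1], function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# Substitute the residues at `sites` (never position 1) to different amino
# acids. Family members share one set of variable sites, as in a protein
# family with hypervariable positions: any member-to-member identity then
# equals roughly 1 - divergence, not 1 - 2*divergence.
mutate_protein <- function(protein, sites) {
  aa <- strsplit(protein, "")[[1]]
  aas <- setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")
  for (i in sites) {
    aa[i] <- sample(setdiff(aas, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

#' Simulate a mixed-community genome set with planted genes
#'
#' Generates random genomes for several taxa and plants non-overlapping
#' protein-coding genes on random strands: regular genes, small ORFs
#' (smORFs), untranslated decoy ORFs, and optional planted protein
#' families. Every planted gene starts with ATG, ends with a stop codon,
#' contains no internal in-frame stop, and carries an in-frame stop codon
#' immediately upstream of its start so that a maximal-ORF six-frame scan
#' recovers exactly the planted coordinates. Family members are generated
#' from an unmutated ancestor (member 1) by substituting exactly
#' `round(divergence * length)` residues, so member-versus-ancestor identity
#' is `1 - divergence` by construction.
#'
#' @param n_taxa Number of taxa (one contig each).
#' @param genome_length_nt Length of each contig in bp.
#' @param n_genes Total number of translated genes to plant (regular +
#'   smORFs), spread across taxa.
#' @param smorf_fraction Fraction of `n_genes` planted as smORFs.
#' @param decoy_fraction Untranslated decoy smORFs, as a fraction of
#'   `n_genes`, planted in addition.
#' @param family_spec Optional list with elements `n_families`, `members`,
#'   `divergence` and optionally `length_aa` (default 40): plants
#'   smORF-length protein families across taxa.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param regular_aa_range Protein-length range for regular genes.
#' @param smorf_aa_range Protein-length range for planted smORFs.
#' @param edge_margin Gene-free margin at contig ends (bp), sized so reads
#'   and metagene flanks never leave the contig.
#' @param gap_range Intergenic gap range (bp).
#' @return A list with `genomes` (contig tibble with `taxon`) and `truth`
#'   (one row per planted gene: coordinates, strand, protein, nucleotide
#'   sequence, smORF/decoy flags, family id, taxon, and empty abundance
#'   columns to be filled by [simulate_abundances()]).
#' @export
simulate_community <- function(n_taxa = 3, genome_length_nt = 20000L,
                               n_genes = 60, smorf_fraction = 0.2,
                               decoy_fraction = 0.1, family_spec = NULL,
                               seed = 1L,
                               regular_aa_range = c(80L, 200L),
                               smorf_aa_range = c(5L, 50L),
                               edge_margin = 100L, gap_range = c(20L, 150L)) {
  with_seed(seed, {
    codons <- codon_table()
    n_smorf <- round(smorf_fraction * n_genes)
    n_regular <- n_genes - n_smorf
    n_decoy <- round(decoy_fraction * n_genes)

    genes <- list()
    add_gene <- function(protein, is_decoy, family_id) {
      genes[[length(genes) + 1]] <<- list(
        protein = protein,
        nt = protein_to_nt(protein, codons),
        is_decoy = is_decoy,
        family_id = family_id
      )
    }
    for (i in seq_len(n_regular)) {
      add_gene(random_protein(sample(regular_aa_range[1]:regular_aa_range[2], 1)),
               FALSE, NA_character_)
    }
    for (i in seq_len(n_smorf)) {
      add_gene(random_protein(sample(smorf_aa_range[1]:smorf_aa_range[2], 1)),
               FALSE, NA_character_)
    }
    for (i in seq_len(n_decoy)) {
      add_gene(random_protein(sample(smorf_aa_range[1]:smorf_aa_range[2], 1)),
               TRUE, NA_character_)
    }
    if (!is.null(family_spec)) {
      len_aa <- family_spec$length_aa %||% 40L
      for (f in seq_len(family_spec$n_families)) {
        ancestor <- random_protein(len_aa)
        fid <- sprintf("fam%03d", f)
        add_gene(ancestor, FALSE, fid)
        n_sub <- round(family_spec$divergence * len_aa)
        sites <- if (n_sub > 0) sample(2:len_aa, n_sub) else integer(0)
        for (m in seq_len(family_spec$members - 1)) {
          add_gene(mutate_protein(ancestor, sites), FALSE, fid)
        }
      }
    }

    n_total <- length(genes)
    taxa <- sprintf("Taxon_%02d", seq_len(n_taxa))
    contig_ids <- sprintf("contig_%02d", seq_len(n_taxa))
    assignment <- if (n_total > 0) sample(rep_len(seq_len(n_taxa), n_total)) else integer(0)

    truth_rows <- list()
    sequences <- character(n_taxa)
    gene_counter <- 0L
    for (t in seq_len(n_taxa)) {
      mine <- which(assignment == t)
      mine <- mine[sample.int(length(mine))]
      parts <- list(random_dna(edge_margin))
      cursor <- edge_margin
      for (gi in mine) {
        g <- genes[[gi]]
        gap <- sample(gap_range[1]:gap_range[2], 1)
        strand <- sample(c("+", "-"), 1)
        # In-frame guard stop adjacent to the start codon in reading
        # direction, so the maximal ORF begins exactly at the planted start.
        cassette <- if (strand == "+") paste0("TAA", g$nt) else paste0(revcomp(g$nt), "TTA")
        gene_len <- nchar(g$nt)
        gene_start <- cursor + gap + (if (strand == "+") 3L else 0L) + 1L
        parts[[length(parts) + 1]] <- random_dna(gap)
        parts[[length(parts) + 1]] <- cassette
        cursor <- cursor + gap + nchar(cassette)
        if (cursor + edge_margin > genome_length_nt) {
          abort_metaribo(paste0(
            "Cannot pack the requested genes into ", genome_length_nt,
            " bp contigs; increase `genome_length_nt`."
          ))
        }
        gene_counter <- gene_counter + 1L
        truth_rows[[gene_counter]] <- tibble::tibble(
          gene_id = sprintf("g%04d", gene_counter),
          contig_id = contig_ids[t],
          start = gene_start,
          end = gene_start + gene_len - 1L,
          strand = strand,
          nt_length = gene_len,
          protein = g$protein,
          nt_sequence = g$nt,
          is_smorf = nchar(g$protein) >= smorf_aa_range[1] &
            nchar(g$protein) <= smorf_aa_range[2],
          is_decoy = g$is_decoy,
          family_id = g$family_id,
          taxon = taxa[t]
        )
      }
      parts[[length(parts) + 1]] <- random_dna(genome_length_nt - cursor)
      sequences[t] <- paste(unlist(parts), collapse = "")
    }

    genomes <- tibble::tibble(id = contig_ids, sequence = sequences, taxon = taxa)
    truth <- if (gene_counter > 0) {
      dplyr::arrange(dplyr::bind_rows(truth_rows), .data$contig_id, .data$start)
    } else {
      tibble::tibble(
        gene_id = character(), contig_id = character(), start = integer(),
        end = integer(), strand = character(), nt_length = integer(),
        protein = character(), nt_sequence = character(), is_smorf = logical(),
        is_decoy = logical(), family_id = character(), taxon = character()
      )
    }
    truth$transcription_level <- NA_real_
    truth$translational_efficiency <- NA_real_
    truth$regulated_class <- rep("none", nrow(truth))
    truth$planted_lfc_rna <- rep(0, nrow(truth))
    truth$planted_lfc_ribo <- rep(0, nrow(truth))
    list(genomes = genomes, truth = truth)
  })
}

#' Plant abundances and regulated gene classes
#'
#' Draws per-gene transcription levels from a lognormal distribution and
#' translational efficiencies (footprint density per transcript) from a
#' second lognormal; decoy ORFs get efficiency exactly 0 (transcribed but
#' untranslated). A chosen number of genes per class receive planted log2
#' shifts between condition 1 and condition 2: `transcriptional` genes shift
#' RNA and footprints together, `translational` genes shift footprints only
#' (RNA log2FC 0), `both` genes shift each independently.
#'
#' @param truth Truth tibble from [simulate_community()].
#' @param lognormal_mu,lognormal_sigma Transcription-level lognormal
#'   parameters (log scale; defaults 0 and 1).
#' @param sigma_te Lognormal sigma of translational efficiency (default 0.75).
#' @param te_mu Lognormal mean (log scale) of translational efficiency
#'   (default 0).
#' @param n_regulated Counts of regulated genes, in the order
#'   (transcriptional, translational, both); default none.
#' @param lfc_magnitude Absolute planted log2 fold change (default 2).
#' @param seed RNG seed.
#' @return The truth tibble with abundance columns filled.
#' @export
simulate_abundances <- function(truth, lognormal_mu = 0, lognormal_sigma = 1,
                                sigma_te = 0.75, te_mu = 0,
                                n_regulated = c(0L, 0L, 0L),
                                lfc_magnitude = 2, seed = 1L) {
  if (nrow(truth) == 0) return(truth)
  n_regulated <- rep_len(as.integer(n_regulated), 3)
  eligible <- which(!truth$is_decoy)
  if (sum(n_regulated) > length(eligible)) {
    abort_metaribo("More regulated genes requested than translated genes available.")
  }
  with_seed(seed, {
    n <- nrow(truth)
    truth$transcription_level <- stats::rlnorm(n, lognormal_mu, lognormal_sigma)
    truth$translational_efficiency <-
      ifelse(truth$is_decoy, 0, stats::rlnorm(n, te_mu, sigma_te))
    truth$regulated_class <- "none"
    truth$planted_lfc_rna <- 0
    truth$planted_lfc_ribo <- 0
    chosen <- sample(eligible, sum(n_regulated))
    classes <- rep(c("transcriptional", "translational", "both"), times = n_regulated)
    for (j in seq_along(chosen)) {
      i <- chosen[j]
      cls <- classes[j]
      s1 <- sample(c(-1, 1), 1)
      truth$regulated_class[i] <- cls
      if (cls == "transcriptional") {
        truth$planted_lfc_rna[i] <- s1 * lfc_magnitude
        truth$planted_lfc_ribo[i] <- s1 * lfc_magnitude
      } else if (cls == "translational") {
        truth$planted_lfc_rna[i] <- 0
        truth$planted_lfc_ribo[i] <- s1 * lfc_magnitude
      } else {
        s2 <- sample(c(-1, 1), 1)
        truth$planted_lfc_rna[i] <- s1 * lfc_magnitude
        truth$planted_lfc_ribo[i] <- s1 * lfc_magnitude + s2 * lfc_magnitude
      }
    }
    truth
  })
}

# Effective per-condition rates from planted log2 fold changes.
effective_rates <- function(truth, condition) {
  shift <- as.numeric(condition == 2)
  rna <- truth$transcription_level * 2^(truth$planted_lfc_rna * shift)
  ribo <- truth$transcription_level * truth$translational_efficiency *
    2^(truth$planted_lfc_ribo * shift)
  list(rna = rna, ribo = ribo)
}

#' Simulate error-free sequencing reads with ground truth
#'
#' Draws reads for one assay. Metagenomic reads are uniform over both
#' strands of the genome; RNA reads place their 5' ends uniformly over the
#' coding strand of gene spans, at a rate proportional to each gene's
#' transcription level; footprint (ribo) reads place 5' ends per gene at a
#' rate proportional to transcription times translational efficiency, with
#' within-gene positions mixing frame-weighted body density with start- and
#' stop-window peaks, plus a uniform both-strand background. Every read is
#' an exact substring (or reverse complement) of its source contig, and the
#' returned truth table records each read's source.
#'
#' @param genomes Contig tibble from [simulate_community()].
#' @param truth Truth tibble with abundances (see [simulate_abundances()]).
#' @param signal_model A [signal_model()] (used by the ribo assay).
#' @param assay One of "metagenomic", "rna", "ribo".
#' @param read_length_nt Read length (single fixed length per run).
#' @param n_reads Number of reads to draw.
#' @param seed RNG seed; independent of the genome seed (two-stream design).
#' @param condition Condition 1 or 2; condition 2 applies the planted
#'   log2 fold changes.
#' @return A list with `reads` (tibble `read_id`, `sequence`) and
#'   `truth_alignments` (tibble `read_id`, `contig_id`, `pos`, `strand`,
#'   `length`, `sequence`, `gene_id`; `gene_id` is NA for background and
#'   metagenomic reads).
#' @export
simulate_reads <- function(genomes, truth, signal_model = metaribo::signal_model(),
                           assay = c("ribo", "rna", "metagenomic"),
                           read_length_nt = 30L, n_reads = 10000L, seed = 1L,
                           condition = 1L) {
  assay <- match.arg(assay)
  check_genomes(genomes)
  if (n_reads < 0) abort_metaribo("`n_reads` must be nonnegative.")
  rl <- as.integer(read_length_nt)
  if (rl > min(nchar(genomes$sequence))) {
    abort_metaribo("`read_length_nt` exceeds the shortest contig.")
  }
  empty <- list(
    reads = tibble::tibble(read_id = character(), sequence = character()),
    truth_alignments = tibble::tibble(
      read_id = character(), contig_id = character(), pos = integer(),
      strand = character(), length = integer(), sequence = character(),
      gene_id = character()
    )
  )
  if (n_reads == 0) return(empty)

  with_seed(seed, {
    contig_len <- stats::setNames(nchar(genomes$sequence), genomes$id)
    total_bp <- sum(contig_len)

    draw_background <- function(n) {
      if (n == 0) {
        return(tibble::tibble(contig_id = character(), pos = integer(),
                              strand = character(), gene_id = character()))
      }
      slots <- contig_len - rl + 1L
      ci <- sample.int(nrow(genomes), n, replace = TRUE, prob = slots)
      tibble::tibble(
        contig_id = genomes$id[ci],
        pos = 1L + floor(stats::runif(n) * slots[ci]),
        strand = sample(c("+", "-"), n, replace = TRUE),
        gene_id = NA_character_
      )
    }

    if (assay == "metagenomic") {
      placed <- draw_background(n_reads)
    } else {
      if (anyNA(truth$transcription_level)) {
        abort_metaribo("Run `simulate_abundances()` before simulating rna/ribo reads.")
      }
      rates <- effective_rates(truth, condition)
      if (assay == "rna") {
        w <- rates$rna
        active <- which(w > 0)
        gi <- active[sample.int(length(active), n_reads, replace = TRUE,
                                prob = w[active])]
        off <- floor(stats::runif(n_reads) * truth$nt_length[gi])
        five <- ifelse(truth$strand[gi] == "+",
                       truth$start[gi] + off, truth$end[gi] - off)
        placed <- tibble::tibble(
          contig_id = truth$contig_id[gi],
          pos = as.integer(ifelse(truth$strand[gi] == "+", five, five - rl + 1L)),
          strand = truth$strand[gi],
          gene_id = truth$gene_id[gi]
        )
      } else {
        w <- rates$ribo
        active <- which(w > 0)
        gene_mass <- sum(w[active])
        bg_mass <- signal_model$background_rate * 2 * total_bp
        p_bg <- if (gene_mass + bg_mass > 0) bg_mass / (gene_mass + bg_mass) else 1
        n_bg <- stats::rbinom(1, n_reads, p_bg)
        n_gene <- n_reads - n_bg
        gene_part <- NULL
        if (n_gene > 0) {
          if (length(active) == 0) abort_metaribo("No translated genes to draw footprints from.")
          gi <- active[sample.int(length(active), n_gene, replace = TRUE,
                                  prob = w[active])]
          # per-gene 5'-end position distribution
          off <- integer(n_gene)
          for (g in unique(gi)) {
            rows <- which(gi == g)
            glen <- truth$nt_length[g]
            pw <- signal_model$frame_weights[(seq_len(glen) - 1L) %% 3L + 1L]
            sw <- min(signal_model$start_window_nt, glen)
            if (sw > 0) pw[seq_len(sw)] <- pw[seq_len(sw)] * signal_model$start_peak_weight
            tw <- min(signal_model$stop_window_nt, glen)
            if (tw > 0) {
              tail_idx <- (glen - tw + 1L):glen
              pw[tail_idx] <- pw[tail_idx] * signal_model$stop_peak_weight
            }
            off[rows] <- sample.int(glen, length(rows), replace = TRUE, prob = pw) - 1L
          }
          five <- ifelse(truth$strand[gi] == "+",
                         truth$start[gi] + off, truth$end[gi] - off)
          gene_part <- tibble::tibble(
            contig_id = truth$contig_id[gi],
            pos = as.integer(ifelse(truth$strand[gi] == "+", five, five - rl + 1L)),
            strand = truth$strand[gi],
            gene_id = truth$gene_id[gi]
          )
        }
        placed <- dplyr::bind_rows(gene_part, draw_background(n_bg))
      }
    }

    contig_seq <- stats::setNames(genomes$sequence, genomes$id)
    fwd <- substring(contig_seq[placed$contig_id], placed$pos, placed$pos + rl - 1L)
    seqs <- ifelse(placed$strand == "+", fwd, revcomp(fwd))
    ids <- sprintf("%s_c%d_r%07d", assay, condition, seq_len(nrow(placed)))
    list(
      reads = tibble::tibble(read_id = ids, sequence = unname(seqs)),
      truth_alignments = tibble::tibble(
        read_id = ids,
        contig_id = placed$contig_id,
        pos = placed$pos,
        strand = placed$strand,
        length = rl,
        sequence = unname(seqs),
        gene_id = placed$gene_id
      )
    )
  })
}

#' Simulate replicate count matrices for differential testing
#'
#' Draws per-gene counts for a two-condition, multi-assay, replicated
#' design directly from the planted abundance model: expected counts are
#' proportional to transcription (RNA) or transcription times translational
#' efficiency (footprints), scaled to a target mean depth per gene;
#' biological variability enters as lognormal replicate noise and counts
#' are Poisson within a library, giving negative-binomial-like dispersion
#' across replicates.
#'
#' @param truth Truth tibble with abundances.
#' @param n_replicates Replicates per condition and assay (default 3).
#' @param depth_per_gene Target mean count per gene per library (default 50).
#' @param sigma_rep Lognormal sigma of replicate noise (default 0.25,
#'   dispersion about 0.065).
#' @param assays Assays to simulate columns for.
#' @param seed RNG seed.
#' @return A list with `counts` (integer matrix, genes x columns) and
#'   `design` (tibble `column`, `samplegroup`, `type`, `replicate`).
#' @export
simulate_counts <- function(truth, n_replicates = 3L, depth_per_gene = 50,
                            sigma_rep = 0.25, assays = c("rna", "ribo"),
                            seed = 1L) {
  if (anyNA(truth$transcription_level)) {
    abort_metaribo("Run `simulate_abundances()` before simulating counts.")
  }
  with_seed(seed, {
    design <- tidyr::expand_grid(
      samplegroup = c("c1", "c2"),
      type = assays,
      replicate = seq_len(n_replicates)
    )
    design$column <- sprintf("%s_%s_r%d", design$type, design$samplegroup,
                             design$replicate)
    design <- design[, c("column", "samplegroup", "type", "replicate")]
    n <- nrow(truth)
    counts <- matrix(0L, nrow = n, ncol = nrow(design),
                     dimnames = list(truth$gene_id, design$column))
    for (j in seq_len(nrow(design))) {
      cond <- if (design$samplegroup[j] == "c2") 2L else 1L
      rates <- effective_rates(truth, cond)
      rate <- if (design$type[j] == "rna") rates$rna else rates$ribo
      mu <- rate / mean(rate) * depth_per_gene
      noise <- stats::rlnorm(n, -sigma_rep^2 / 2, sigma_rep)
      counts[, j] <- stats::rpois(n, mu * noise)
    }
    list(counts = counts, design = design)
  })
}
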