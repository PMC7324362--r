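#' Run the full community translation-profiling pipeline on simulated data
#'
#' Orchestrates the end-to-end demonstration workflow: simulate a
#' ground-truth community (genomes, abundances, three read assays), predict
#' ORFs, map and filter reads, compute footprint diagnostics (metagene
#' profiles, start enrichment, triplet periodicity), quantify features and
#' call translation evidence, cluster translated small proteins into
#' families with synthesis evidence, run the three differential contrasts
#' on simulated replicate counts, and propagate taxonomy. All stage seeds
#' derive from `seed`, and a rerun with the same seed and parameters is
#' byte-identical in every output file.
#'
#' @param outdir Output directory (created if absent).
#' @param config An [mrs_config()].
#' @param seed Master seed (default `config$rng_seed`).
#' @param n_taxa,genome_length_nt,n_genes,smorf_fraction,decoy_fraction,family_spec
#'   Community parameters passed to [simulate_community()].
#' @param n_reads Named vector of read counts per assay.
#' @param read_length_nt Read length.
#' @param model A [signal_model()].
#' @param n_regulated Regulated gene counts for [simulate_abundances()].
#' @param n_replicates,depth_per_gene Count-simulation parameters for the
#'   differential stage.
#' @param taxon Optional taxon label: restrict the differential stage to
#'   genes of that taxon.
#' @return An `mrs_run_report` (list) with config snapshot, stage timings,
#'   output file digests and headline metrics. Output files are written
#'   under `outdir`.
#' @export
run_pipeline <- function(outdir,
                         config = mrs_config(),
                         seed = config$rng_seed,
                         n_taxa = 3,
                         genome_length_nt = 20000L,
                         n_genes = 45,
                         smorf_fraction = 0.25,
                         decoy_fraction = 0.1,
                         family_spec = list(n_families = 4, members = 5,
                                            divergence = 0.2),
                         n_reads = c(metagenomic = 15000, rna = 25000,
                                     ribo = 25000),
                         read_length_nt = 30L,
                         model = signal_model(),
                         n_regulated = c(8L, 8L, 4L),
                         n_replicates = 3L,
                         depth_per_gene = 50,
                         taxon = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  path <- function(...) file.path(outdir, paste0(...))

  # -- simulate ---------------------------------------------------------
  comm <- tick("simulate_community",
               simulate_community(
                 n_taxa = n_taxa, genome_length_nt = genome_length_nt,
                 n_genes = n_genes, smorf_fraction = smorf_fraction,
                 decoy_fraction = decoy_fraction, family_spec = family_spec,
                 seed = seed
               ))
  truth <- simulate_abundances(comm$truth, n_regulated = n_regulated,
                               seed = seed + 101L)
  write_fasta(comm$genomes, path("genomes.fasta"))
  write_tsv_plain(truth, path("truth_genes.tsv"))
  truth_as_orfs <- dplyr::rename(truth, orf_id = "gene_id")
  write_gff3(truth_as_orfs, path("truth_genes.gff3"))

  assays <- c("metagenomic", "rna", "ribo")
  sim_reads <- list()
  for (a in assays) {
    sim_reads[[a]] <- tick(paste0("simulate_reads_", a),
                           simulate_reads(
                             comm$genomes, truth, model, assay = a,
                             read_length_nt = read_length_nt,
                             n_reads = n_reads[[a]],
                             seed = seed + 200L + match(a, assays)
                           ))
    write_fastq(sim_reads[[a]]$reads, path("reads_", a, ".fastq"))
  }

  # -- ORF prediction ---------------------------------------------------
  orfs <- tick("find_orfs", find_orfs(comm$genomes, config$min_orf_nt))
  smorfs <- select_smorfs(orfs, config$smorf_aa_range)
  write_gff3(orfs, path("orfs.gff3"))
  write_fasta(
    tibble::tibble(id = smorfs$orf_id, sequence = smorfs$protein),
    path("smorf_proteins.fasta")
  )

  # -- mapping ----------------------------------------------------------
  index <- tick("build_index", build_index(comm$genomes, k = 21L))
  aligned <- list()
  for (a in assays) {
    aligned[[a]] <- tick(paste0("map_", a), {
      hits <- map_reads(index, sim_reads[[a]]$reads)
      filter_unique_perfect(hits)
    })
    write_sam(aligned[[a]], comm$genomes, path("alignments_", a, ".sam"))
  }

  # -- footprint diagnostics (on planted genes) -------------------------
  diagnostics <- tick("riboprofile", {
    track <- signal_track(aligned$ribo, comm$genomes)
    regular <- truth[!truth$is_smorf & !truth$is_decoy, , drop = FALSE]
    prof_start <- metagene_profile(track, regular,
                                   flank_nt = config$metagene_flank_nt,
                                   min_reads = config$min_reads_metagene,
                                   anchor = "start")
    prof_stop <- metagene_profile(track, regular,
                                  flank_nt = config$metagene_flank_nt,
                                  min_reads = config$min_reads_metagene,
                                  anchor = "stop")
    list(
      track = track,
      start = prof_start,
      stop = prof_stop,
      enrichment = start_enrichment(prof_start, model$start_window_nt),
      periodicity = frame_periodicity(track, truth)
    )
  })
  write_tsv_plain(tibble::as_tibble(diagnostics$start), path("metagene_start.tsv"))
  write_tsv_plain(tibble::as_tibble(diagnostics$stop), path("metagene_stop.tsv"))
  write_tsv_plain(diagnostics$periodicity, path("periodicity.tsv"))

  # -- quantification ---------------------------------------------------
  quant <- tick("quantify", {
    lens <- stats::setNames(orfs$nt_length, orfs$orf_id)
    per_assay <- list(
      rna = count_features(aligned$rna, orfs, "rna"),
      ribo = count_features(aligned$ribo, orfs, "ribo")
    )
    quantify_samples(per_assay, lens, config$translation_rpkm_threshold)
  })
  write_tsv_plain(quant, path("quantified_features.tsv"))
  ribo_q <- quant[quant$sample == "ribo", , drop = FALSE]
  translated_smorfs <- smorfs[smorfs$orf_id %in%
                                ribo_q$feature_id[ribo_q$translated], , drop = FALSE]

  # -- families ---------------------------------------------------------
  fam <- tick("families", {
    if (nrow(translated_smorfs) >= 2) {
      prot <- tibble::tibble(
        id = translated_smorfs$orf_id,
        protein = translated_smorfs$protein
      )
      fams <- greedy_cluster(prot,
                             identity_c = config$family_identity_smorf,
                             length_diff_cutoff = config$cluster_length_diff_cutoff,
                             long_coverage = config$cluster_long_coverage)
      links <- tidyr::unnest(
        fams[, c("family_id", "member_ids")],
        cols = "member_ids"
      )
      names(links)[names(links) == "member_ids"] <- "id"
      calls <- tibble::tibble(
        id = ribo_q$feature_id,
        translated = ribo_q$translated
      )
      fams <- family_synthesis_evidence(fams, links, calls)
      fams
    } else {
      NULL
    }
  })
  if (!is.null(fam)) {
    flat <- fam
    flat$member_ids <- vapply(flat$member_ids, paste, character(1), collapse = ",")
    flat <- flat[, c("family_id", "representative_id", "n_members",
                     "member_ids", "synthesized")]
    write_tsv_plain(flat, path("families.tsv"))
  }

  # -- differential -----------------------------------------------------
  diff_truth <- truth
  if (!is.null(taxon)) {
    diff_truth <- diff_truth[diff_truth$taxon == taxon, , drop = FALSE]
  }
  diffs <- tick("differential", {
    sim_counts <- simulate_counts(diff_truth, n_replicates = n_replicates,
                                  depth_per_gene = depth_per_gene,
                                  seed = seed + 301L)
    lapply(stats::setNames(c("rna", "ribo", "interaction"),
                           c("rna", "ribo", "interaction")), function(ct) {
      nb_fit_test(sim_counts$counts, sim_counts$design, contrast = ct,
                  lfc_threshold = config$lfc_threshold,
                  fdr_threshold = config$fdr_threshold)
    })
  })
  write_tsv_plain(dplyr::bind_rows(lapply(diffs, tidy)), path("differential.tsv"))

  # -- taxonomy ---------------------------------------------------------
  taxonomy <- tick("taxonomy", {
    gene_taxa <- tibble::tibble(id = truth$gene_id, taxon = truth$taxon)
    lapply(stats::setNames(assays, assays), function(a) {
      tx <- propagate_taxonomy(aligned[[a]], truth_as_orfs, gene_taxa, assay = a)
      grouped <- group_other(tx$abundance, config$other_abundance_threshold)
      write_tsv_plain(grouped, path("taxonomy_", a, ".tsv"))
      tx
    })
  })

  # -- report -----------------------------------------------------------
  out_files <- sort(list.files(outdir, full.names = TRUE))
  out_files <- out_files[!grepl("report\\.json$", out_files)]
  digests <- tools::md5sum(out_files)
  metrics <- list(
    n_orfs = nrow(orfs),
    n_smorfs = nrow(smorfs),
    n_translated_smorfs = nrow(translated_smorfs),
    n_families = if (is.null(fam)) 0L else nrow(fam),
    n_synthesized_families = if (is.null(fam)) 0L else sum(fam$synthesized),
    n_differential = vapply(diffs, function(d) sum(d$call != "ns"), integer(1)),
    start_enrichment = diagnostics$enrichment,
    metagene_genes_used = attr(diagnostics$start, "n_genes_used"),
    frame_fractions = c(diagnostics$periodicity$frac0,
                        diagnostics$periodicity$frac1,
                        diagnostics$periodicity$frac2),
    periodicity_p = diagnostics$periodicity$p_value,
    unclassified_fraction = vapply(taxonomy, function(t) t$unclassified_fraction,
                                   numeric(1))
  )
  report <- structure(
    list(
      outdir = outdir,
      seed = seed,
      config = unclass(config),
      timings = timings,
      file_digests = as.list(digests),
      metrics = metrics
    ),
    class = "mrs_run_report"
  )
  jsonlite::write_json(
    report[c("seed", "config", "file_digests", "metrics")],
    path("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}

#' @export
print.mrs_run_report <- function(x, ...) {
  cat("<mrs_run_report>\n")
  cat(sprintf("  outdir: %s (seed %s)\n", x$outdir, x$seed))
  cat(sprintf("  ORFs: %d (%d smORFs, %d translated)\n",
              x$metrics$n_orfs, x$metrics$n_smorfs, x$metrics$n_translated_smorfs))
  cat(sprintf("  families: %d (%d synthesized)\n",
              x$metrics$n_families, x$metrics$n_synthesized_families))
  cat(sprintf("  start enrichment: %.2f over %d genes; frame fractions %s\n",
              x$metrics$start_enrichment, x$metrics$metagene_genes_used,
              paste(sprintf("%.3f", x$metrics$frame_fractions), collapse = "/")))
  cat(sprintf("  differential calls: %s\n",
              paste(names(x$metrics$n_differential),
                    x$metrics$n_differential, sep = "=", collapse = ", ")))
  invisible(x)
}

# Deterministic TSV writer (no quoting, no row names).
write_tsv_plain <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], paste, character(1), collapse = ",")
    }
    if (is.numeric(x[[j]])) x[[j]] <- format(x[[j]], digits = 15, trim = TRUE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
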