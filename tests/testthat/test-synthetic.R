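test_that("simulator output is deterministic and structurally valid", {
  a <- simulate_community(n_taxa = 2, genome_length_nt = 8000, n_genes = 10, seed = 5)
  b <- simulate_community(n_taxa = 2, genome_length_nt = 8000, n_genes = 10, seed = 5)
  expect_identical(a, b)
  # genes non-overlapping, inside the margins, correct sequence content
  tr <- a$truth
  expect_true(all(tr$start > 50 & tr$end < 8000 - 50))
  for (cid in unique(tr$contig_id)) {
    g <- tr[tr$contig_id == cid, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  seqs <- stats::setNames(a$genomes$sequence, a$genomes$id)
  planted <- substr(seqs[tr$contig_id], tr$start, tr$end)
  oriented <- ifelse(tr$strand == "+", planted,
                     vapply(planted, oracle_revcomp, character(1)))
  expect_equal(unname(oriented), tr$nt_sequence)
})

test_that("empty and infeasible communities behave as specified", {
  empty <- simulate_community(n_taxa = 1, genome_length_nt = 2000, n_genes = 0,
                              decoy_fraction = 0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(nchar(empty$genomes$sequence), 2000)
  expect_error(
    simulate_community(n_taxa = 1, genome_length_nt = 900, n_genes = 20, seed = 1),
    "increase `genome_length_nt`"
  )
})

test_that("abundance planting obeys the class contracts", {
  comm <- simulate_community(n_taxa = 2, genome_length_nt = 15000, n_genes = 30,
                             decoy_fraction = 0.2, seed = 6)
  # degenerate lognormal: all transcription levels equal exp(mu)
  tr0 <- simulate_abundances(comm$truth, lognormal_mu = 1, lognormal_sigma = 0,
                             seed = 7)
  expect_true(all(abs(tr0$transcription_level - exp(1)) < 1e-12))

  tr <- simulate_abundances(comm$truth, n_regulated = c(4, 5, 3), seed = 8)
  expect_equal(sum(tr$regulated_class == "transcriptional"), 4)
  expect_equal(sum(tr$regulated_class == "translational"), 5)
  expect_equal(sum(tr$regulated_class == "both"), 3)
  # decoys are transcribed but never translated, never regulated
  expect_true(all(tr$translational_efficiency[tr$is_decoy] == 0))
  expect_true(all(tr$translational_efficiency[!tr$is_decoy] > 0))
  expect_true(all(tr$regulated_class[tr$is_decoy] == "none"))
  # translational regulation leaves RNA untouched
  tl <- tr[tr$regulated_class == "translational", ]
  expect_true(all(tl$planted_lfc_rna == 0))
  expect_true(all(abs(tl$planted_lfc_ribo) >= 1))
  # a global null is a true null
  null <- simulate_abundances(comm$truth, n_regulated = c(0, 0, 0), seed = 9)
  expect_true(all(null$planted_lfc_rna == 0 & null$planted_lfc_ribo == 0))
  expect_error(simulate_abundances(comm$truth, n_regulated = c(100, 0, 0)),
               "More regulated genes")
})

test_that("reads are error-free substrings recorded at their truth positions", {
  comm <- simulate_community(n_taxa = 2, genome_length_nt = 8000, n_genes = 10,
                             seed = 10)
  truth <- simulate_abundances(comm$truth, seed = 11)
  seqs <- stats::setNames(comm$genomes$sequence, comm$genomes$id)
  for (assay in c("metagenomic", "rna", "ribo")) {
    sim <- simulate_reads(comm$genomes, truth, signal_model(), assay = assay,
                          n_reads = 500, seed = 12)
    expect_equal(nrow(sim$reads), 500)
    expect_equal(nrow(sim$truth_alignments), 500)
    ta <- sim$truth_alignments
    ref <- substr(seqs[ta$contig_id], ta$pos, ta$pos + ta$length - 1L)
    expected <- ifelse(ta$strand == "+", ref,
                       vapply(ref, oracle_revcomp, character(1)))
    expect_equal(unname(expected), sim$reads$sequence)
  }
  none <- simulate_reads(comm$genomes, truth, signal_model(), assay = "ribo",
                         n_reads = 0, seed = 13)
  expect_equal(nrow(none$reads), 0)
  expect_error(simulate_reads(comm$genomes, truth, signal_model(),
                              assay = "ribo", n_reads = -1), "nonnegative")
})

test_that("with zero background every footprint 5' end lies inside a gene", {
  comm <- simulate_community(n_taxa = 1, genome_length_nt = 6000, n_genes = 4,
                             decoy_fraction = 0, seed = 14)
  truth <- simulate_abundances(comm$truth, seed = 15)
  sm <- signal_model(background_rate = 0)
  sim <- simulate_reads(comm$genomes, truth, sm, assay = "ribo",
                        n_reads = 2000, seed = 16)
  ta <- sim$truth_alignments
  five <- ifelse(ta$strand == "+", ta$pos, ta$pos + ta$length - 1L)
  inside <- mapply(function(p, g) {
    row <- truth[truth$gene_id == g, ]
    p >= row$start && p <= row$end
  }, five, ta$gene_id)
  expect_true(all(ta$gene_id %in% truth$gene_id))
  expect_true(all(inside))
})

test_that("changing the read seed leaves genomes and truth untouched", {
  comm <- simulate_community(n_taxa = 1, genome_length_nt = 6000, n_genes = 6,
                             seed = 17)
  truth <- simulate_abundances(comm$truth, seed = 18)
  r1 <- simulate_reads(comm$genomes, truth, signal_model(), "ribo",
                       n_reads = 200, seed = 19)
  r2 <- simulate_reads(comm$genomes, truth, signal_model(), "ribo",
                       n_reads = 200, seed = 20)
  expect_false(identical(r1$reads$sequence, r2$reads$sequence))
  comm_again <- simulate_community(n_taxa = 1, genome_length_nt = 6000,
                                   n_genes = 6, seed = 17)
  expect_identical(comm, comm_again)
})

test_that("planted family members sit at the designed divergence", {
  comm <- simulate_community(
    n_taxa = 2, genome_length_nt = 12000, n_genes = 4,
    family_spec = list(n_families = 2, members = 4, divergence = 0.10,
                       length_aa = 40),
    seed = 22
  )
  fams <- comm$truth[!is.na(comm$truth$family_id), ]
  expect_equal(nrow(fams), 8)
  for (fid in unique(fams$family_id)) {
    members <- fams$protein[fams$family_id == fid]
    anc <- members[1]
    for (m in members[-1]) {
      hit <- pairwise_align(m, anc)
      expect_gte(hit$identity, 0.80)
    }
  }
})

test_that("simulated count matrices follow the planted design", {
  comm <- simulate_community(n_taxa = 2, genome_length_nt = 15000, n_genes = 30,
                             decoy_fraction = 0, seed = 23)
  truth <- simulate_abundances(comm$truth, n_regulated = c(0, 3, 0),
                               lfc_magnitude = 3, seed = 24)
  sim <- simulate_counts(truth, n_replicates = 3, depth_per_gene = 200,
                         sigma_rep = 0.1, seed = 25)
  expect_equal(dim(sim$counts), c(nrow(truth), 12))
  expect_equal(colnames(sim$counts), sim$design$column)
  # translational genes shift in ribo columns but not rna columns
  reg <- which(truth$regulated_class == "translational")
  rna1 <- rowMeans(sim$counts[, sim$design$type == "rna" & sim$design$samplegroup == "c1"])
  rna2 <- rowMeans(sim$counts[, sim$design$type == "rna" & sim$design$samplegroup == "c2"])
  ribo1 <- rowMeans(sim$counts[, sim$design$type == "ribo" & sim$design$samplegroup == "c1"])
  ribo2 <- rowMeans(sim$counts[, sim$design$type == "ribo" & sim$design$samplegroup == "c2"])
  lfc_ribo <- log2(ribo2[reg] / ribo1[reg])
  lfc_rna <- log2(rna2[reg] / rna1[reg])
  expect_true(all(abs(abs(lfc_ribo) - 3) < 1))
  expect_true(all(abs(lfc_rna) < 1))
})
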