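genes3 <- tibble::tibble(
  orf_id = c("gX", "gY", "gZ"),
  contig_id = "c1",
  start = c(11L, 101L, 201L),
  end = c(70L, 160L, 260L),
  strand = c("+", "+", "-")
)
taxa3 <- tibble::tibble(id = c("gX", "gY", "gZ"),
                        taxon = c("Bacteroides", "Bacteroides", "Prevotella"))

read_at <- function(pos, strand = "+", id = "r1") {
  tibble::tibble(read_id = id, contig_id = "c1", pos = as.integer(pos),
                 strand = strand, length = 20L, n_mismatch = 0L, n_hits = 1L)
}

test_that("reads inherit the taxon of the gene containing their 5' end", {
  reads <- dplyr::bind_rows(
    read_at(20, id = "a"),            # in gX
    read_at(110, id = "b"),           # in gY
    read_at(241, "-", id = "c"),      # 5' end at 260, in gZ
    read_at(500, id = "d")            # intergenic
  )
  tx <- propagate_taxonomy(reads, genes3, taxa3, assay = "ribo")
  expect_equal(tx$read_taxa$taxon,
               c("Bacteroides", "Bacteroides", "Prevotella", NA))
  expect_equal(tx$unclassified_fraction, 0.25)
  expect_equal(sum(tx$abundance$fraction), 1)
  expect_equal(tx$abundance$fraction[tx$abundance$taxon == "Bacteroides"], 2 / 3)

  # conservation: classified + unclassified = all alignments
  n_class <- sum(!is.na(tx$read_taxa$taxon))
  expect_equal(n_class + sum(is.na(tx$read_taxa$taxon)), nrow(reads))

  none <- propagate_taxonomy(reads[4, ], genes3, taxa3, assay = "ribo")
  expect_equal(nrow(none$abundance), 0)
  expect_equal(none$unclassified_fraction, 1)

  # a gene missing from the taxon table is tallied as unclassified
  expect_message(
    tx2 <- propagate_taxonomy(reads, genes3, taxa3[1:2, ], assay = "ribo"),
    "without a taxon label"
  )
  expect_true(is.na(tx2$read_taxa$taxon[3]))
})

test_that("simulator read taxonomy matches the truth table exactly", {
  comm <- simulate_community(n_taxa = 3, genome_length_nt = 9000, n_genes = 15,
                             decoy_fraction = 0, seed = 55)
  truth <- simulate_abundances(comm$truth, seed = 56)
  sim <- simulate_reads(comm$genomes, truth, signal_model(background_rate = 0),
                        assay = "ribo", n_reads = 2000, seed = 57)
  idx <- build_index(comm$genomes, 21)
  aln <- filter_unique_perfect(map_reads(idx, sim$reads))
  tx <- propagate_taxonomy(
    aln,
    dplyr::rename(truth, orf_id = "gene_id"),
    tibble::tibble(id = truth$gene_id, taxon = truth$taxon),
    assay = "ribo"
  )
  truth_taxon <- truth$taxon[match(sim$truth_alignments$gene_id, truth$gene_id)]
  want <- table(truth_taxon[sim$truth_alignments$read_id %in% aln$read_id])
  got <- tx$abundance
  expect_equal(
    got$fraction[match(names(want), got$taxon)],
    as.numeric(want) / sum(want)
  )
})

test_that("rare taxa group into Other with a strict threshold", {
  ab <- tibble::tibble(taxon = c("A", "B", "C"), fraction = c(0.5, 0.48, 0.02))
  out <- group_other(ab, 0.03)
  expect_equal(out$fraction[out$taxon == "Other"], 0.02)
  expect_equal(sum(out$fraction), 1, tolerance = 1e-9)

  keep <- tibble::tibble(taxon = c("A", "B"), fraction = c(0.9, 0.1))
  expect_identical(group_other(keep, 0.03), keep)

  # strictly below: 0.029 grouped, 0.03 kept
  edge <- tibble::tibble(taxon = c("A", "B", "C"),
                         fraction = c(0.941, 0.03, 0.029))
  out2 <- group_other(edge, 0.03)
  expect_true("B" %in% out2$taxon)
  expect_equal(out2$fraction[out2$taxon == "Other"], 0.029)
})

test_that("neighborhood scan respects rank distance and the domain filter", {
  orfs <- tibble::tibble(
    orf_id = sprintf("g%02d", 1:25),
    contig_id = "c1",
    start = seq(1L, by = 200L, length.out = 25),
    end = seq(100L, by = 200L, length.out = 25),
    strand = rep(c("+", "-"), length.out = 25)
  )
  domains <- tibble::tibble(
    orf_id = c("g02", "g03", "g22", "g23", "g13"),
    domain_id = c("HisKA", "HisKA", "Response_reg", "Response_reg", "Phage"),
    e_value = c(0.01, 0.06, 0.01, 0.01, 0.01),
    pssm_coverage = c(0.9, 0.9, 0.79, 0.95, 0.9)
  )
  hits <- neighborhood_scan(orfs, "g13", domains, max_genes = 10)
  # g02 is 11 ranks away -> excluded; g03 fails e-value; g22 fails coverage
  expect_equal(hits$orf_id, "g23")
  expect_equal(hits$rank_distance, 10L)
  expect_equal(hits$domain_id, "Response_reg")
  # the anchor's own domains are not neighbor hits
  expect_false("Phage" %in% hits$domain_id)
  expect_error(neighborhood_scan(orfs, "nope", domains), "not found")

  lone <- neighborhood_scan(orfs[13, ], "g13", domains)
  expect_equal(nrow(lone), 0)

  co <- neighborhood_cooccurrence(orfs, c("g13", "g14"), domains)
  # g14 additionally sees the anchor gene g13 and its Phage domain at rank 1
  expect_equal(co$domain_id, c("Response_reg", "Phage"))
  expect_equal(co$n_smorfs, c(2L, 1L))
})

test_that("localization calls use the inclusive 80% member rule", {
  fams <- tibble::tibble(
    family_id = c("f1", "f2", "f3"),
    member_ids = list(paste0("a", 1:5), paste0("b", 1:5), paste0("c", 1:5))
  )
  flags <- tibble::tibble(
    id = c(paste0("a", 1:5), paste0("b", 1:5), paste0("c", 1:5)),
    secreted = c(rep(TRUE, 4), FALSE, rep(FALSE, 10)),
    transmembrane = c(rep(FALSE, 5), rep(TRUE, 3), FALSE, FALSE, rep(TRUE, 5))
  )
  out <- localization_call(fams, flags, 0.80)
  expect_equal(out$localization, c("secreted", "none", "transmembrane"))
  expect_error(localization_call(fams, flags[-1, ], 0.80), "Missing localization")
})
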