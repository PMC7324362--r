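test_that("alignment of identical sequences is perfect", {
  h <- pairwise_align("MKVLYAWRT", "MKVLYAWRT")
  expect_equal(h$identity, 1)
  expect_equal(h$aligned_query_fraction, 1)
  expect_equal(h$subject_coverage, 1)
  expect_lt(h$e_value, 1e-3)
})

test_that("alignment scores match the exhaustive DP oracle on short peptides", {
  set.seed(71)
  for (trial in 1:12) {
    a <- paste(sample(AA20, sample(5:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA20, sample(5:12, 1), replace = TRUE), collapse = "")
    got <- pairwise_align(a, b)
    expect_equal(got$score, oracle_sw_score(a, b), info = paste(a, b))
  }
})

test_that("unrelated peptides are insignificant against a large database", {
  set.seed(72)
  evals <- replicate(20, {
    a <- paste(sample(AA20, 30, replace = TRUE), collapse = "")
    b <- paste(sample(AA20, 30, replace = TRUE), collapse = "")
    pairwise_align(a, b, n_subjects = 1e5)$e_value
  })
  expect_gte(mean(evals > 0.05), 0.95)
})

test_that("greedy clustering handles the elementary cases", {
  two_same <- tibble::tibble(id = c("a", "b"), protein = c("MKVLYAWRTQ", "MKVLYAWRTQ"))
  expect_equal(nrow(greedy_cluster(two_same)), 1)

  set.seed(73)
  p1 <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  p2 <- paste(sample(AA20, 40, replace = TRUE), collapse = "")  # unrelated
  far <- tibble::tibble(id = c("a", "b"), protein = c(p1, p2))
  expect_equal(nrow(greedy_cluster(far, identity_c = 0.5)), 2)

  # representative is the longest member, ties broken lexicographically
  fam <- greedy_cluster(tibble::tibble(
    id = c("zz", "aa"), protein = c("MKVLYAWRTQ", "MKVLYAWRTQ")
  ))
  expect_equal(fam$representative_id, "aa")
})

test_that("greedy partition equals the independent control-flow oracle", {
  set.seed(74)
  comm <- simulate_community(
    n_taxa = 2, genome_length_nt = 15000, n_genes = 6, smorf_fraction = 1,
    decoy_fraction = 0,
    family_spec = list(n_families = 3, members = 5, divergence = 0.2,
                       length_aa = 35),
    seed = 75
  )
  prot <- tibble::tibble(id = comm$truth$gene_id, protein = comm$truth$protein)
  expect_lte(nrow(prot), 25)
  fams <- greedy_cluster(prot, 0.5, 0.95, 0.95)
  got <- integer(0)
  for (i in seq_len(nrow(fams))) {
    got[fams$member_ids[[i]]] <- i
  }
  want <- oracle_greedy_partition(prot, 0.5, 0.95, 0.95)
  expect_equal(adjusted_rand_index(got, want), 1)
  # every member meets the identity threshold against its representative
  for (i in seq_len(nrow(fams))) {
    rep_prot <- prot$protein[prot$id == fams$representative_id[i]]
    for (m in fams$member_proteins[[i]]) {
      expect_gte(pairwise_align(m, rep_prot, mode = "global")$identity, 0.5)
    }
  }
})

test_that("clustering recovery depends on planted divergence as designed", {
  low <- simulate_community(
    n_taxa = 2, genome_length_nt = 20000, n_genes = 0, decoy_fraction = 0,
    family_spec = list(n_families = 4, members = 5, divergence = 0.30,
                       length_aa = 40),
    seed = 76
  )
  prot <- tibble::tibble(id = low$truth$gene_id, protein = low$truth$protein)
  fams <- greedy_cluster(prot, 0.5, 0.95, 0.95)
  got <- integer(0)
  for (i in seq_len(nrow(fams))) got[fams$member_ids[[i]]] <- i
  truth_lab <- stats::setNames(as.integer(factor(low$truth$family_id)),
                               low$truth$gene_id)
  expect_gte(adjusted_rand_index(got[names(truth_lab)], truth_lab), 0.95)

  high <- simulate_community(
    n_taxa = 2, genome_length_nt = 20000, n_genes = 0, decoy_fraction = 0,
    family_spec = list(n_families = 3, members = 5, divergence = 0.60,
                       length_aa = 40),
    seed = 77
  )
  prot_h <- tibble::tibble(id = high$truth$gene_id, protein = high$truth$protein)
  fams_h <- greedy_cluster(prot_h, 0.5, 0.95, 0.95)
  expect_gt(nrow(fams_h), 3)  # too divergent to hold together at 50%
})

test_that("homolog assignment applies the e-value and length-window filters", {
  set.seed(78)
  rep40 <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  reps <- tibble::tibble(family_id = "famA", protein = rep40)

  # identical smORF: accepted at identity 1
  q <- tibble::tibble(id = "s1", protein = rep40)
  links <- assign_family_homologs(q, reps)
  expect_equal(nrow(links), 1)
  expect_equal(links$identity, 1)

  # hit covering 85% of the query: rejected by the 90-110% window
  q_long <- tibble::tibble(
    id = "s2",
    protein = paste0(rep40, paste(rep("G", 7), collapse = ""))
  )
  links2 <- assign_family_homologs(q_long, reps)
  expect_equal(nrow(links2), 0)

  # insignificant e-value: rejected even with a window-compatible length
  unrelated <- paste(sample(AA20, 40, replace = TRUE), collapse = "")
  links3 <- assign_family_homologs(
    tibble::tibble(id = "s3", protein = unrelated),
    tibble::tibble(family_id = "famB",
                   protein = paste(sample(AA20, 40, replace = TRUE), collapse = ""))
  )
  expect_equal(nrow(links3), 0)
})

test_that("family synthesis evidence follows the strict RPKM rule", {
  fams <- tibble::tibble(
    family_id = c("f1", "f2", "f3"),
    representative_id = c("a", "b", "c"),
    n_members = 1L,
    member_ids = list("a", "b", "c"),
    member_proteins = list("M", "M", "M")
  )
  links <- tibble::tibble(id = c("a", "b"), family_id = c("f1", "f2"))
  calls <- tibble::tibble(id = c("a", "b"), translated = c(TRUE, FALSE))
  out <- family_synthesis_evidence(fams, links, calls)
  expect_equal(out$synthesized, c(TRUE, FALSE, FALSE))  # f3 has no links
  # adding a translated link never unsets the flag
  links2 <- dplyr::bind_rows(links, tibble::tibble(id = "a2", family_id = "f1"))
  calls2 <- dplyr::bind_rows(calls, tibble::tibble(id = "a2", translated = TRUE))
  expect_true(family_synthesis_evidence(fams, links2, calls2)$synthesized[1])
  expect_error(
    family_synthesis_evidence(fams, tibble::tibble(id = "ghost", family_id = "f1"), calls),
    "without translation calls"
  )
})

test_that("unique-DNA collapse counts exact sequence multiplicities", {
  members <- tibble::tibble(
    member_id = c("m1", "m2", "m3"),
    nt_sequence = c("ATGAAATAA", "ATGAAATAA", "ATGCCCTAA")
  )
  out <- collapse_unique_dna(members)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_occurrences, c(2L, 1L))
  expect_equal(sum(out$n_occurrences), 3L)
  expect_equal(nrow(collapse_unique_dna(members[c(1, 1, 1), ])), 1)
  members$nt_sequence[2] <- NA
  expect_error(collapse_unique_dna(members), "Missing nucleotide sequence.*m2")
})

test_that("planted nucleotide variants are recovered with their multiplicities", {
  comm <- simulate_community(
    n_taxa = 1, genome_length_nt = 15000, n_genes = 0, decoy_fraction = 0,
    family_spec = list(n_families = 1, members = 6, divergence = 0,
                       length_aa = 30),
    seed = 79
  )
  fam <- comm$truth[!is.na(comm$truth$family_id), ]
  out <- collapse_unique_dna(tibble::tibble(
    member_id = fam$gene_id, nt_sequence = fam$nt_sequence
  ))
  expect_equal(sum(out$n_occurrences), 6L)
  # multiplicities match a direct tabulation of the planted sequences
  expect_equal(out$n_occurrences, sort(as.integer(table(fam$nt_sequence)),
                                       decreasing = TRUE))
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  expect_equal(domain_enrichment(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(domain_enrichment(10, 5, 5, 0), 1)
  set.seed(80)
  for (trial in 1:20) {
    N <- sample(5:20, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(domain_enrichment(N, K, n, k), oracle_hyper_upper(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(domain_enrichment(10, 11, 5, 2), "Inconsistent")
})
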