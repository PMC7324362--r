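mk_genome <- function(L = 200, id = "c1") {
  tibble::tibble(id = id, sequence = strrep("A", L))
}

aln_row <- function(pos, strand = "+", len = 30L, id = "r") {
  tibble::tibble(read_id = id, contig_id = "c1", pos = as.integer(pos),
                 strand = strand, length = len, n_mismatch = 0L, n_hits = 1L)
}

test_that("signal track uses 5'-end conventions and conserves mass", {
  g <- mk_genome(100)
  tr <- signal_track(aln_row(5), g)
  expect_equal(tr$track$c1[["+"]][5], 1L)
  expect_equal(sum(tr$track$c1[["+"]]), 1L)

  tr2 <- signal_track(aln_row(5, strand = "-"), g)
  expect_equal(tr2$track$c1[["-"]][34], 1L)  # rightmost base of a 30 nt read

  many <- dplyr::bind_rows(lapply(1:50, function(i) aln_row(i, id = paste0("r", i))))
  tr3 <- signal_track(many, g)
  expect_equal(metaribo:::track_mass(tr3), 50)

  expect_error(signal_track(aln_row(95, len = 30L), g), "beyond contig bounds")
})

test_that("metagene profile filters by read count and is flat on uniform signal", {
  set.seed(51)
  g <- mk_genome(400)
  orf <- tibble::tibble(orf_id = "o1", contig_id = "c1", start = 101L,
                        end = 250L, strand = "+")
  nine <- dplyr::bind_rows(lapply(1:9, function(i) aln_row(100 + i, id = paste0("r", i))))
  prof9 <- metagene_profile(signal_track(nine, g), orf, flank_nt = 20,
                            min_reads = 10, anchor = "start")
  expect_equal(attr(prof9, "n_genes_used"), 0L)
  expect_true(all(prof9$mean_signal == 0))

  # uniform coverage across the whole window -> flat normalized profile
  uni <- dplyr::bind_rows(lapply(81:270, function(i) aln_row(i, len = 10L,
                                                             id = paste0("u", i))))
  prof <- metagene_profile(signal_track(uni, g), orf, flank_nt = 20,
                           min_reads = 10, anchor = "start")
  expect_equal(attr(prof, "n_genes_used"), 1L)
  expect_equal(prof$offset, -20:19)
  expect_lt(diff(range(prof$mean_signal)), 1e-12)
  expect_equal(sum(prof$mean_signal), 1)
})

test_that("per-gene normalization makes the profile scale-invariant per gene", {
  g <- mk_genome(600)
  orfs <- tibble::tibble(
    orf_id = c("a", "b"), contig_id = "c1",
    start = c(101L, 401L), end = c(250L, 550L), strand = "+"
  )
  reads_a <- dplyr::bind_rows(lapply(101:130, function(i) aln_row(i, id = paste0("a", i))))
  reads_b <- dplyr::bind_rows(lapply(401:430, function(i) aln_row(i, id = paste0("b", i))))
  base <- metagene_profile(signal_track(dplyr::bind_rows(reads_a, reads_b), g),
                           orfs, flank_nt = 20, min_reads = 10)
  # triple gene b's coverage: normalized profile unchanged
  reads_b3 <- dplyr::bind_rows(reads_b, reads_b, reads_b)
  reads_b3$read_id <- paste0(reads_b3$read_id, seq_len(nrow(reads_b3)))
  tripled <- metagene_profile(signal_track(dplyr::bind_rows(reads_a, reads_b3), g),
                              orfs, flank_nt = 20, min_reads = 10)
  expect_equal(base$mean_signal, tripled$mean_signal, tolerance = 1e-12)
})

test_that("minus-strand genes are profiled in reading orientation", {
  g <- mk_genome(300)
  orf <- tibble::tibble(orf_id = "m", contig_id = "c1", start = 101L,
                        end = 220L, strand = "-")
  # 12 reads whose 5' ends sit at the first codon of the minus-strand gene
  reads <- dplyr::bind_rows(lapply(1:12, function(i) {
    aln_row(220 - 29, strand = "-", id = paste0("m", i))  # 5' end at 220
  }))
  prof <- metagene_profile(signal_track(reads, g), orf, flank_nt = 10,
                           min_reads = 10, anchor = "start")
  expect_equal(attr(prof, "n_genes_used"), 1L)
  expect_equal(prof$mean_signal[prof$offset == 0], 1)
})

test_that("periodicity statistic matches closed forms", {
  g <- mk_genome(1000)
  orf <- tibble::tibble(orf_id = "o", contig_id = "c1", start = 101L,
                        end = 400L, strand = "+")
  # all 300 counts in frame 0
  f0 <- dplyr::bind_rows(lapply(1:300, function(i) {
    aln_row(101 + 3 * (i %% 100), id = paste0("f", i))
  }))
  stat <- frame_periodicity(signal_track(f0, g), orf)
  expect_equal(stat$frame0, 300L)
  expect_equal(c(stat$frac0, stat$frac1, stat$frac2), c(1, 0, 0))
  expect_equal(stat$chi2, 2 * 300)  # closed form 2n when all mass in one frame

  # perfectly balanced frames
  bal <- dplyr::bind_rows(lapply(0:29, function(i) {
    aln_row(101 + i, id = paste0("b", i))
  }))
  stat2 <- frame_periodicity(signal_track(bal, g), orf)
  expect_equal(stat2$chi2, 0)
  expect_equal(stat2$p_value, 1)

  # zero in-ORF signal
  stat3 <- frame_periodicity(signal_track(aln_row(500), g), orf)
  expect_equal(c(stat3$frame0, stat3$frame1, stat3$frame2), c(0L, 0L, 0L))
  expect_true(is.na(stat3$frac0))
  expect_equal(stat3$p_value, 1)

  # adding off-ORF signal changes nothing
  stat4 <- frame_periodicity(signal_track(dplyr::bind_rows(f0, aln_row(900)), g), orf)
  expect_equal(stat4$chi2, stat$chi2)
})

test_that("start enrichment is 1 for flat profiles and Inf when degenerate", {
  flat <- tibble::new_tibble(
    list(offset = -20:19, mean_signal = rep(1 / 40, 40)),
    nrow = 40, class = "mrs_metagene", n_genes_used = 1L, anchor = "start"
  )
  expect_equal(start_enrichment(flat, 12), 1)
  spike <- flat
  spike$mean_signal <- c(rep(0, 20), 1, rep(0, 19))
  expect_warning(r <- start_enrichment(spike, 12), "Inf")
  expect_true(is.infinite(r))
})
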