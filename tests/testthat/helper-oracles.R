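# Independent reference implementations used as test oracles. These are
# deliberately naive (enumeration / brute force) and share no code with the
# package internals they check.

STOPS <- c("TAA", "TAG", "TGA")

# The 20 standard amino acids, for random-peptide fixtures.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

random_contig <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force six-frame ORF enumeration: every (start codon, next in-frame
# stop) pair, outermost start per stop, both strands, length filter.
oracle_find_orfs <- function(seq, min_nt = 15, starts = c("ATG", "GTG", "TTG")) {
  scan_one <- function(s) {
    L <- nchar(s)
    out <- list()
    for (p in seq_len(max(L - 2, 0))) {
      codon <- substr(s, p, p + 2)
      if (!codon %in% starts) next
      # walk forward in frame to the next stop; the outermost-start rule is
      # applied afterwards by keeping the smallest start per stop
      q <- p
      hit <- NA
      while (q + 2 <= L) {
        cd <- substr(s, q, q + 2)
        if (cd %in% STOPS) {
          hit <- q
          break
        }
        q <- q + 3
      }
      if (!is.na(hit)) {
        out[[length(out) + 1]] <- data.frame(start = p, stop = hit)
      }
    }
    df <- do.call(rbind, out)
    if (is.null(df)) return(df)
    # outermost start per stop
    df <- df[order(df$stop, df$start), , drop = FALSE]
    df <- df[!duplicated(df$stop), , drop = FALSE]
    df$nt_length <- df$stop + 3 - df$start
    df[df$nt_length >= min_nt, , drop = FALSE]
  }
  fwd <- scan_one(seq)
  res <- list()
  if (!is.null(fwd) && nrow(fwd) > 0) {
    res[[1]] <- data.frame(start = fwd$start, end = fwd$stop + 2, strand = "+")
  }
  L <- nchar(seq)
  rc <- scan_one(oracle_revcomp(seq))
  if (!is.null(rc) && nrow(rc) > 0) {
    res[[2]] <- data.frame(
      start = L - (rc$stop + 2) + 1, end = L - rc$start + 1, strand = "-"
    )
  }
  df <- do.call(rbind, res)
  if (is.null(df)) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  df[order(df$start, df$strand), , drop = FALSE]
}

# Exhaustive exact-match locator: all 0-mismatch positions of `read` on
# both strands of each genome sequence.
oracle_match_read <- function(read, genomes) {
  out <- list()
  for (i in seq_len(nrow(genomes))) {
    s <- genomes$sequence[i]
    L <- nchar(s)
    w <- nchar(read)
    if (w > L) next
    rc <- oracle_revcomp(read)
    for (p in seq_len(L - w + 1)) {
      sub <- substr(s, p, p + w - 1)
      if (sub == read) {
        out[[length(out) + 1]] <- data.frame(
          contig_id = genomes$id[i], pos = p, strand = "+"
        )
      }
      if (sub == rc) {
        out[[length(out) + 1]] <- data.frame(
          contig_id = genomes$id[i], pos = p, strand = "-"
        )
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(contig_id = character(), pos = integer(), strand = character()))
  }
  df[order(df$contig_id, df$pos, df$strand), , drop = FALSE]
}

# Full dynamic-programming Smith-Waterman (affine gaps) for short peptides.
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  subst <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      sc <- subst[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sc, X[i, j], Y[i, j])
      best <- max(best, M[i, j])
    }
  }
  best
}

# Independent Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by enumeration of the density.
oracle_hyper_upper <- function(N, K, n, k) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# Independent greedy clustering using the same published rules but a
# separate control flow; identity/coverage come from pairwise_align.
oracle_greedy_partition <- function(proteins, c_id, s_ratio, aL) {
  ord <- order(-nchar(proteins$protein), proteins$id)
  proteins <- proteins[ord, , drop = FALSE]
  cluster_of <- integer(nrow(proteins))
  rep_rows <- integer(0)
  for (i in seq_len(nrow(proteins))) {
    best <- NA; best_id <- -Inf
    for (ci in seq_along(rep_rows)) {
      r <- rep_rows[ci]
      ratio <- nchar(proteins$protein[i]) / nchar(proteins$protein[r])
      if (ratio < s_ratio) next
      h <- metaribo::pairwise_align(proteins$protein[i], proteins$protein[r],
                                    mode = "global")
      if (h$identity >= c_id && h$subject_coverage >= aL && h$identity > best_id) {
        best <- ci; best_id <- h$identity
      }
    }
    if (is.na(best)) {
      rep_rows <- c(rep_rows, i)
      cluster_of[i] <- length(rep_rows)
    } else {
      cluster_of[i] <- best
    }
  }
  stats::setNames(cluster_of, proteins$id)
}

# Adjusted Rand index between two labelings given as named vectors.
adjusted_rand_index <- function(a, b) {
  b <- b[names(a)]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
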