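# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

#' @importFrom rlang abort warn inform %||%
NULL

abort_metaribo <- function(msg, class = "metaribo_error") {
  rlang::abort(msg, class = class)
}

# Reverse-complement a character vector of DNA strings.
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Validate a genome tibble (columns id, sequence, optional taxon).
check_genomes <- function(genomes, arg = "genomes") {
  if (!is.data.frame(genomes) || !all(c("id", "sequence") %in% names(genomes))) {
    abort_metaribo(sprintf("`%s` must be a data frame with columns `id` and `sequence`.", arg))
  }
  if (nrow(genomes) == 0) {
    abort_metaribo(sprintf("`%s` contains no sequences.", arg))
  }
  dup <- genomes$id[duplicated(genomes$id)]
  if (length(dup) > 0) {
    abort_metaribo(sprintf("Duplicate contig id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- stringr::str_locate(genomes$sequence, "[^ACGT]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort_metaribo(sprintf(
      "Non-ACGT symbol in sequence `%s` at position %d.", genomes$id[i], bad[i]
    ))
  }
  if (any(nchar(genomes$sequence) == 0)) {
    abort_metaribo("Empty sequence in genome set.")
  }
  invisible(genomes)
}

# Validate an ORF tibble.
check_orfs <- function(orfs, arg = "orfs") {
  needed <- c("orf_id", "contig_id", "start", "end", "strand")
  if (!is.data.frame(orfs) || !all(needed %in% names(orfs))) {
    abort_metaribo(sprintf(
      "`%s` must contain columns %s.", arg, paste(needed, collapse = ", ")
    ))
  }
  invisible(orfs)
}
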