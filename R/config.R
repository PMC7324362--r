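#' Pipeline configuration
#'
#' All tunable thresholds of the analysis live in a single configuration
#' object. Defaults are the values used throughout the workflow: a 15 bp
#' minimum ORF length for gene prediction, the 5--50 amino-acid small-protein
#' window, the MetaRibo-Seq RPKM > 10 translation-evidence rule, the ten-read
#' metagene gene filter, CD-Hit-style clustering parameters (50% identity for
#' small-protein families, 70% for differential-gene clustering, 0.95 length
#' ratio and long-sequence coverage), the homolog hit filter (e-value <= 0.05,
#' hit length within 90--110% of the query), the differential call rule
#' (|log2FC| > 1 and FDR < 0.05), the ten-gene neighborhood radius, the 80%
#' PSSM-coverage and 80%-of-members localization rules, and the 3% "Other"
#' abundance grouping.
#'
#' @param ... Named fields overriding the defaults (see Details).
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{min_orf_nt}{Minimum ORF length in bp, including the stop codon (15).}
#'   \item{smorf_aa_range}{Protein length window in amino acids defining a
#'     smORF, inclusive (c(5, 50)).}
#'   \item{translation_rpkm_threshold}{Strict RPKM threshold for calling a
#'     gene translated from footprint signal (10).}
#'   \item{min_reads_metagene}{Minimum in-ORF reads for a gene to enter the
#'     metagene average (10).}
#'   \item{family_identity_smorf, family_identity_diff}{Greedy clustering
#'     identity cutoffs for small-protein families (0.50) and for clustering
#'     differential genes (0.70).}
#'   \item{cluster_length_diff_cutoff, cluster_long_coverage}{Length-ratio and
#'     longer-sequence alignment-coverage requirements for joining a cluster
#'     (both 0.95).}
#'   \item{homolog_evalue_max, homolog_length_window}{Homolog hit filter:
#'     e-value cap (0.05) and allowed hit-length fraction of the query
#'     (c(0.90, 1.10)).}
#'   \item{lfc_threshold, fdr_threshold}{Differential call rule: strict
#'     |log2FC| > 1 and FDR < 0.05.}
#'   \item{neighborhood_max_genes}{Gene-rank radius for neighborhood scans (10).}
#'   \item{domain_coverage_min}{Minimum PSSM coverage for a domain hit (0.80).}
#'   \item{localization_member_fraction}{Fraction of members required to call
#'     a family secreted/transmembrane (0.80).}
#'   \item{other_abundance_threshold}{Taxa strictly below this relative
#'     abundance are grouped into "Other" (0.03).}
#'   \item{metagene_flank_nt}{Flank width around start/stop anchors (50).}
#'   \item{rng_seed}{Default seed for simulation stages (1).}
#' }
#'
#' @return A named list of class `mrs_config`.
#' @examples
#' cfg <- mrs_config(translation_rpkm_threshold = 5)
#' cfg$translation_rpkm_threshold
#' @export
mrs_config <- function(...) {
  cfg <- config_defaults()
  override <- list(...)
  if (length(override) > 0) {
    if (is.null(names(override)) || any(names(override) == "")) {
      abort_metaribo("All configuration overrides must be named.")
    }
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown) > 0) {
      abort_metaribo(sprintf(
        "Unknown configuration key(s): %s", paste(unknown, collapse = ", ")
      ))
    }
    cfg[names(override)] <- override
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    min_orf_nt = 15L,
    smorf_aa_range = c(5L, 50L),
    translation_rpkm_threshold = 10,
    min_reads_metagene = 10L,
    family_identity_smorf = 0.50,
    family_identity_diff = 0.70,
    cluster_length_diff_cutoff = 0.95,
    cluster_long_coverage = 0.95,
    homolog_evalue_max = 0.05,
    homolog_length_window = c(0.90, 1.10),
    lfc_threshold = 1.0,
    fdr_threshold = 0.05,
    neighborhood_max_genes = 10L,
    domain_coverage_min = 0.80,
    localization_member_fraction = 0.80,
    other_abundance_threshold = 0.03,
    metagene_flank_nt = 50L,
    rng_seed = 1L
  )
}

validate_config <- function(cfg) {
  pair_fields <- c("smorf_aa_range", "homolog_length_window")
  for (f in pair_fields) {
    if (length(cfg[[f]]) != 2 || any(!is.finite(cfg[[f]]))) {
      abort_metaribo(sprintf("`%s` must be a finite pair of values.", f))
    }
  }
  scalar_fields <- setdiff(names(config_defaults()), pair_fields)
  for (f in scalar_fields) {
    if (length(cfg[[f]]) != 1 || !is.finite(as.numeric(cfg[[f]]))) {
      abort_metaribo(sprintf("`%s` must be a single finite value.", f))
    }
  }
  if (cfg$smorf_aa_range[1] < 2 || cfg$smorf_aa_range[1] > cfg$smorf_aa_range[2]) {
    abort_metaribo("`smorf_aa_range` must satisfy 2 <= lower <= upper.")
  }
  fraction_fields <- c(
    "family_identity_smorf", "family_identity_diff", "cluster_length_diff_cutoff",
    "cluster_long_coverage", "domain_coverage_min", "localization_member_fraction",
    "other_abundance_threshold"
  )
  for (f in fraction_fields) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) {
      abort_metaribo(sprintf("`%s` must lie in (0, 1].", f))
    }
  }
  positive_fields <- c(
    "min_orf_nt", "translation_rpkm_threshold", "min_reads_metagene",
    "homolog_evalue_max", "lfc_threshold", "fdr_threshold",
    "neighborhood_max_genes", "metagene_flank_nt"
  )
  for (f in positive_fields) {
    if (cfg[[f]] <= 0) {
      abort_metaribo(sprintf("`%s` must be strictly positive.", f))
    }
  }
  if (cfg$homolog_length_window[1] <= 0 ||
      cfg$homolog_length_window[1] > cfg$homolog_length_window[2]) {
    abort_metaribo("`homolog_length_window` must be an increasing positive pair.")
  }
  structure(cfg, class = "mrs_config")
}

#' Read a configuration file
#'
#' Parses a flat `key = value` text file. Unset keys take their defaults;
#' unknown keys raise an error so typos are caught rather than silently
#' ignored. Pair-valued fields are written as comma-separated values.
#'
#' @param path Path to the configuration file. An empty file yields the
#'   default configuration.
#' @return An `mrs_config` object.
#' @seealso [mrs_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_metaribo(sprintf("Configuration file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) return(mrs_config())
  parts <- stringr::str_split_fixed(lines, "=", 2)
  if (any(parts[, 2] == "")) {
    abort_metaribo("Configuration lines must be of the form `key = value`.")
  }
  keys <- stringr::str_trim(parts[, 1])
  vals <- stringr::str_trim(parts[, 2])
  parsed <- lapply(vals, function(v) {
    x <- suppressWarnings(as.numeric(stringr::str_trim(strsplit(v, ",")[[1]])))
    if (any(is.na(x))) abort_metaribo(sprintf("Non-numeric configuration value: %s", v))
    x
  })
  names(parsed) <- keys
  int_fields <- c("min_orf_nt", "min_reads_metagene", "neighborhood_max_genes",
                  "metagene_flank_nt", "rng_seed", "smorf_aa_range")
  parsed <- lapply(stats::setNames(names(parsed), names(parsed)), function(k) {
    if (k %in% int_fields) as.integer(parsed[[k]]) else parsed[[k]]
  })
  do.call(mrs_config, parsed)
}

#' Write a configuration file
#'
#' Serializes an `mrs_config` as flat `key = value` text. `load_config()` of
#' the written file reproduces the configuration exactly (serialize-parse is a
#' fixed point).
#'
#' @param config An `mrs_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mrs_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE, trim = TRUE),
                                collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.mrs_config <- function(x, ...) {
  cat("<mrs_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}
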