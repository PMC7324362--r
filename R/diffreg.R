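#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean across columns (genes with
#' any zero count are excluded); each column's size factor is the median of
#' its count/reference ratios, rescaled so the factors have geometric mean
#' 1.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector of per-column size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort_metaribo("Need at least two columns.")
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    abort_metaribo(paste0(
      "No gene has nonzero counts in every column; ",
      "filter low-count genes before normalization."
    ))
  }
  logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(cc) {
    stats::median(exp(log(cc) - logref))
  })
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; `NA` inputs are
#' propagated and excluded from the adjustment denominator.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values of the same length.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_metaribo("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Apply the differential call rule
#'
#' A gene is called `up` when log2FC is strictly above the threshold and
#' FDR is strictly below the cutoff, `down` symmetrically, otherwise `ns`.
#'
#' @param results Tibble with `log2fc` and `fdr` columns.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return `results` with a `call` column.
#' @export
call_differential <- function(results, lfc_threshold = 1, fdr_threshold = 0.05) {
  results$call <- dplyr::case_when(
    !is.na(results$fdr) & results$log2fc > lfc_threshold &
      results$fdr < fdr_threshold ~ "up",
    !is.na(results$fdr) & results$log2fc < -lfc_threshold &
      results$fdr < fdr_threshold ~ "down",
    TRUE ~ "ns"
  )
  results
}

# Moderated dispersion from the across-genes variance-mean trend.
# Per-gene within-cell variances v_i and means m_i (normalized counts) are
# pooled through the model Var = c1 * mu + c2 * mu^2 (c1 >= 1 absorbs
# extra-Poisson shot noise, c2 is the NB dispersion), fitted by weighted
# least squares with weights 1/Var^2, iterated. The fitted trend value is
# the plug-in dispersion: with few replicates per cell the gene-wise
# method-of-moments estimate is far too noisy to plug into a likelihood
# (see the methods vignette).
trended_dispersion <- function(norm_counts, cells, floor = 1e-8) {
  cells <- as.factor(cells)
  idx <- split(seq_along(cells), cells)
  idx <- idx[lengths(idx) >= 2]
  if (length(idx) == 0) {
    abort_metaribo("Dispersion estimation needs at least one cell with 2+ replicates.")
  }
  mns <- rowMeans(norm_counts)
  vars <- apply(norm_counts, 1, function(z) {
    mean(vapply(idx, function(i) stats::var(z[i]), numeric(1)))
  })
  ok <- is.finite(vars) & mns > 0
  if (sum(ok) < 2) {
    return(rep(floor, length(mns)))
  }
  m <- mns[ok]
  v <- vars[ok]
  c1 <- 1
  c2 <- 0.05
  for (it in 1:3) {
    w <- 1 / (c1 * m + c2 * m^2)^2
    xtx <- rbind(c(sum(w * m^2), sum(w * m^3)),
                 c(sum(w * m^3), sum(w * m^4)))
    xty <- c(sum(w * m * v), sum(w * m^2 * v))
    cf <- tryCatch(solve(xtx, xty), error = function(e) c(1, 0.05))
    c1 <- cf[1]
    c2 <- cf[2]
    if (!is.finite(c1) || !is.finite(c2)) {
      c1 <- 1; c2 <- 0.05
    }
    if (c2 < 0) {
      c2 <- 0
      c1 <- max(sum(w * m * v) / sum(w * m^2), 1)
    }
    if (c1 < 1) {
      c1 <- 1
      c2 <- max(sum(w * m^2 * (v - m)) / sum(w * m^4), 0)
    }
  }
  pmax((c1 - 1) / pmax(mns, 1e-8) + c2, floor)
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-10), log = TRUE))
}

#' Negative-binomial differential test
#'
#' Gene-wise negative-binomial GLMs (log link, size-factor offsets) with a
#' likelihood-ratio chi-square test. For the `rna` and `ribo` contrasts the
#' columns of that assay are tested for a condition effect
#' (`~ samplegroup` vs `~ 1`). The `interaction` contrast uses all columns
#' and tests the condition-by-assay coefficient
#' (`~ samplegroup * type` vs `~ samplegroup + type`), i.e. a change in
#' footprint abundance not explained by the RNA change -- translational
#' regulation controlling for transcription. Dispersion is a per-gene
#' method-of-moments estimate moderated through a mean-dispersion trend and
#' plugged into the likelihood. Genes with all-zero counts in the tested
#' columns are excluded; genes whose fit fails get `NA` p-values and are
#' excluded from the FDR denominator.
#'
#' @param counts Integer matrix, genes x columns (rownames are feature ids).
#' @param design Tibble with columns `column`, `samplegroup`, `type`,
#'   `replicate` matching `colnames(counts)`.
#' @param contrast `"rna"`, `"ribo"` or `"interaction"`.
#' @param lfc_threshold,fdr_threshold Call rule thresholds (defaults 1 and
#'   0.05, strict inequalities).
#' @return A tibble of class `mrs_diff`: `feature_id`, `base_mean`,
#'   `log2fc`, `p_value`, `fdr`, `call`, `contrast`.
#' @export
nb_fit_test <- function(counts, design, contrast = c("rna", "ribo", "interaction"),
                        lfc_threshold = 1, fdr_threshold = 0.05) {
  contrast <- match.arg(contrast)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (!all(c("column", "samplegroup", "type") %in% names(design))) {
    abort_metaribo("`design` must have columns `column`, `samplegroup`, `type`.")
  }
  if (!setequal(colnames(counts), design$column)) {
    abort_metaribo("`design$column` must match the count matrix columns.")
  }
  design <- design[match(colnames(counts), design$column), , drop = FALSE]

  if (contrast %in% c("rna", "ribo")) {
    keep_cols <- design$type == contrast
    if (sum(keep_cols) < 4) {
      abort_metaribo(sprintf("Contrast `%s` needs at least 4 columns of that assay.",
                             contrast))
    }
  } else {
    if (length(unique(design$samplegroup)) < 2 || length(unique(design$type)) < 2) {
      abort_metaribo("Interaction contrast needs >= 2 samplegroups and 2 assay types.")
    }
    keep_cols <- rep(TRUE, nrow(design))
  }
  sub <- counts[, keep_cols, drop = FALSE]
  dsub <- design[keep_cols, , drop = FALSE]
  group <- factor(dsub$samplegroup)
  type <- factor(dsub$type, levels = unique(c("rna", unique(dsub$type))))

  nonzero <- rowSums(sub) > 0
  if (any(!nonzero)) {
    rlang::inform(sprintf("Excluding %d gene(s) with all-zero counts.", sum(!nonzero)))
  }
  sub <- sub[nonzero, , drop = FALSE]
  if (nrow(sub) == 0) abort_metaribo("No genes left to test.")
  sf <- size_factors(sub)
  off <- log(sf)
  norm <- sweep(sub, 2, sf, "/")
  cells <- interaction(group, type, drop = TRUE)
  alpha <- trended_dispersion(norm, cells)

  if (contrast == "interaction") {
    x_full <- stats::model.matrix(~ group * type)
    x_red <- stats::model.matrix(~ group + type)
    coef_name <- colnames(x_full)[ncol(x_full)]
  } else {
    x_full <- stats::model.matrix(~ group)
    x_red <- stats::model.matrix(~ 1, data = data.frame(row.names = seq_along(group)))
    coef_name <- colnames(x_full)[2]
  }
  df_test <- ncol(x_full) - ncol(x_red)

  n <- nrow(sub)
  log2fc <- rep(NA_real_, n)
  pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- sub[i, ]
    a <- alpha[i]
    fam <- MASS::negative.binomial(theta = 1 / a)
    fit_full <- tryCatch(
      suppressWarnings(stats::glm.fit(x_full, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    fit_red <- tryCatch(
      suppressWarnings(stats::glm.fit(x_red, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    if (is.null(fit_full) || is.null(fit_red) ||
        !fit_full$converged || !fit_red$converged) {
      next
    }
    ll_full <- nb_loglik(y, fit_full$fitted.values, a)
    ll_red <- nb_loglik(y, fit_red$fitted.values, a)
    stat <- max(2 * (ll_full - ll_red), 0)
    pval[i] <- stats::pchisq(stat, df = df_test, lower.tail = FALSE)
    log2fc[i] <- unname(fit_full$coefficients[coef_name]) / log(2)
  }
  n_failed <- sum(is.na(pval))
  if (n_failed > 0) {
    rlang::inform(sprintf("%d gene(s) failed to converge; p set to NA.", n_failed))
  }
  res <- tibble::tibble(
    feature_id = rownames(sub),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    p_value = pval,
    fdr = bh_fdr(pval),
    contrast = contrast
  )
  res <- call_differential(res, lfc_threshold, fdr_threshold)
  res <- res[, c("feature_id", "base_mean", "log2fc", "p_value", "fdr",
                 "call", "contrast")]
  class(res) <- c("mrs_diff", class(res))
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential test result
#'
#' @param x An `mrs_diff` object.
#' @param ... Unused.
#' @return A plain tibble of the per-gene results.
#' @method tidy mrs_diff
#' @export
tidy.mrs_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mrs_diff")
  out
}

#' One-row summary of a differential test
#'
#' @param x An `mrs_diff` object.
#' @param ... Unused.
#' @return A one-row tibble: contrast, number of genes tested, and up /
#'   down / non-significant call counts.
#' @method glance mrs_diff
#' @export
glance.mrs_diff <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast[1],
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_ns = sum(x$call == "ns")
  )
}
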