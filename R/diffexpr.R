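#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (positive in
#' all samples) of \eqn{counts_{ij} / geomean_i}, where `geomean_i` is the
#' gene's geometric mean across samples. Factors are rescaled to geometric
#' mean 1 so that normalized counts stay on the raw-count scale.
#'
#' @param counts count matrix (genes x samples), >= 2 samples
#' @return named numeric vector of positive size factors, geometric mean 1
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  lg <- log(counts)
  loggeo <- rowMeans(lg)
  usable <- is.finite(loggeo)   # genes positive in every sample
  if (!any(usable)) {
    warning("no gene is positive in all samples; ",
            "falling back to column-sum size factors")
    sf <- colSums(counts)
  } else {
    sf <- apply(lg[usable, , drop = FALSE], 2,
                function(col) exp(stats::median(col - loggeo[usable])))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A count-based two-group engine: counts are normalized by size factors,
#' per-gene group means are compared on the log2 scale with a pseudo-count
#' of 0.5, the NB dispersion is estimated per gene by a pooled within-group
#' method of moments (floored at 1e-8), and the standard error of the log2
#' fold change follows from the NB variance \eqn{\mu + \alpha \mu^2} by the
#' delta method. The Wald statistic is referred to the standard normal;
#' p-values are BH-adjusted. Genes with zero counts in every sample are
#' excluded from testing and tallied.
#'
#' @param counts count matrix (genes x samples)
#' @param sizefactors named size factors from [estimate_size_factors()]
#' @param groups factor of length `ncol(counts)` with levels
#'   `c("lean", "fat")`; each group needs >= 2 samples. Fold changes are
#'   fat over lean.
#' @param alpha FDR level used for the direction call (default 0.05)
#' @return data.frame `gene_id`, `base_mean`, `log2fc`, `se`, `wald`, `p`,
#'   `padj`, `direction` (up_in_fat / down_in_fat / ns); the ids of excluded
#'   all-zero genes are in `attr(result, "excluded")`
#' @export
nb_wald_test <- function(counts, sizefactors, groups, alpha = 0.05) {
  groups <- factor(groups, levels = c("lean", "fat"))
  if (length(groups) != ncol(counts)) {
    stop("groups must have one label per sample column")
  }
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  sf <- sizefactors[colnames(counts)]
  if (anyNA(sf)) stop("size factors missing for some samples")

  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]

  k <- sweep(counts, 2, sf, "/")
  fat <- groups == "fat"
  lean <- groups == "lean"
  n_f <- sum(fat); n_l <- sum(lean)

  m_f <- rowMeans(k[, fat, drop = FALSE])
  m_l <- rowMeans(k[, lean, drop = FALSE])
  v_f <- rowSums((k[, fat, drop = FALSE] - m_f)^2) / (n_f - 1)
  v_l <- rowSums((k[, lean, drop = FALSE] - m_l)^2) / (n_l - 1)

  # pooled within-group method-of-moments NB dispersion, floored
  num <- (n_f - 1) * (v_f - m_f) + (n_l - 1) * (v_l - m_l)
  den <- (n_f - 1) * m_f^2 + (n_l - 1) * m_l^2
  disp <- pmax(ifelse(den > 0, num / den, 0), 1e-8)

  log2fc <- log2((m_f + 0.5) / (m_l + 0.5))
  var_mf <- (m_f + disp * m_f^2) / n_f
  var_ml <- (m_l + disp * m_l^2) / n_l
  log2sq <- log(2)^2
  se <- sqrt(var_mf / ((m_f + 0.5)^2 * log2sq) +
             var_ml / ((m_l + 0.5)^2 * log2sq))
  se <- pmax(se, 1e-12)
  wald <- log2fc / se
  p <- 2 * stats::pnorm(-abs(wald))
  padj <- bh_adjust(p)
  direction <- ifelse(padj < alpha & log2fc > 0, "up_in_fat",
                      ifelse(padj < alpha & log2fc < 0, "down_in_fat", "ns"))
  out <- data.frame(
    gene_id = rownames(counts), base_mean = rowMeans(k),
    log2fc = log2fc, se = se, wald = wald, p = p, padj = padj,
    direction = direction, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Partition DE results by direction
#'
#' @param results data.frame from [nb_wald_test()]
#' @param alpha FDR threshold (default 0.05)
#' @return list of gene-id vectors `up_in_fat`, `down_in_fat`, `ns`
#' @export
call_de <- function(results, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(results)))
  sig <- results$padj < alpha
  list(
    up_in_fat = results$gene_id[sig & results$log2fc > 0],
    down_in_fat = results$gene_id[sig & results$log2fc < 0],
    ns = results$gene_id[!(sig & results$log2fc != 0)]
  )
}
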