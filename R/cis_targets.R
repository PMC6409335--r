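#' Find neighboring gene pairs within a window
#'
#' Reports a (lincRNA gene, coding gene) pair iff both loci sit on the same
#' chromosome and their gap is below `window` bp, where the gap is
#' `max(0, max(startA, startB) - min(endA, endB))`; overlapping or touching
#' loci have gap 0. Strand is ignored.
#'
#' @param lincrna_loci,coding_loci data.frames with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open)
#' @param window maximum gap in bp, exclusive (default 100000: "<100 kb")
#' @return data.frame `lincrna_gene`, `coding_gene`, `gap`
#' @export
find_neighbors <- function(lincrna_loci, coding_loci, window = 100000) {
  stopifnot(window > 0)
  empty <- data.frame(lincrna_gene = character(), coding_gene = character(),
                      gap = numeric(), stringsAsFactors = FALSE)
  if (nrow(lincrna_loci) == 0 || nrow(coding_loci) == 0) return(empty)
  lgr <- intervals_to_granges(lincrna_loci)
  cgr <- intervals_to_granges(coding_loci)
  shared <- union(GenomeInfoDb::seqlevels(lgr), GenomeInfoDb::seqlevels(cgr))
  GenomeInfoDb::seqlevels(lgr) <- shared
  GenomeInfoDb::seqlevels(cgr) <- shared
  hits <- GenomicRanges::findOverlaps(lgr, cgr, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- pmax(0, pmax(lincrna_loci$start[qi], coding_loci$start[si]) -
                 pmin(lincrna_loci$end[qi], coding_loci$end[si]))
  keep <- gap < window
  out <- data.frame(lincrna_gene = lincrna_loci$gene_id[qi][keep],
                    coding_gene = coding_loci$gene_id[si][keep],
                    gap = gap[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (n >= 3) with nonzero variance
#' @param id optional label used in error messages
#' @return the product-moment correlation
#' @export
pearson_r <- function(x, y, id = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation (zero variance)",
         if (!is.null(id)) paste0(" for ", id) else "")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t-transform \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} referred
#' to Student's t with n-2 degrees of freedom.
#'
#' @param r correlation coefficient(s), |r| <= 1
#' @param n sample size (>= 3)
#' @return two-sided p-value(s); exactly 0 when |r| = 1
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Predict lincRNA target genes by expression correlation
#'
#' Tests every (lincRNA gene, coding gene) pair: a coding gene is a
#' potential target gene (PTG) of a lincRNA iff their expression profiles
#' are Pearson-correlated with raw two-sided p < `alpha`; a PTG that is
#' itself differentially expressed is a DEPTG. No multiple-testing
#' correction is applied by default (set `adjust = TRUE` for a BH-corrected
#' call).
#'
#' @param lincrna_expr,coding_expr expression matrices (genes x samples)
#'   with identical, identically ordered sample columns
#' @param de_coding_ids character vector of differentially expressed coding
#'   gene ids
#' @param alpha raw p-value threshold for the PTG call (default 0.05)
#' @param neighbors optional data.frame from [find_neighbors()] used to set
#'   the `is_neighbor` flag and, with `restrict = "neighbors"`, the tested
#'   universe
#' @param restrict `"all"` (every pair, the default) or `"neighbors"` (only
#'   pairs within the neighbor window)
#' @param adjust apply BH to the pair p-values before the PTG call
#' @return data.frame `lincrna_gene`, `coding_gene`, `r`, `p`, `n`,
#'   `is_neighbor`, `is_ptg`, `is_deptg`, `sign`
#' @export
predict_targets <- function(lincrna_expr, coding_expr, de_coding_ids,
                            alpha = 0.05, neighbors = NULL,
                            restrict = c("all", "neighbors"),
                            adjust = FALSE) {
  restrict <- match.arg(restrict)
  if (!identical(colnames(lincrna_expr), colnames(coding_expr))) {
    stop("sample columns of the two expression matrices do not match")
  }
  n <- ncol(lincrna_expr)
  if (n < 3) stop("need at least 3 samples")
  if (restrict == "neighbors" && is.null(neighbors)) {
    stop("restrict = 'neighbors' requires a neighbors table")
  }
  sd_l <- apply(lincrna_expr, 1, stats::sd)
  sd_c <- apply(coding_expr, 1, stats::sd)
  if (any(sd_l == 0)) {
    stop("undefined correlation (zero variance) for ",
         rownames(lincrna_expr)[sd_l == 0][1])
  }
  if (any(sd_c == 0)) {
    stop("undefined correlation (zero variance) for ",
         rownames(coding_expr)[sd_c == 0][1])
  }
  rmat <- stats::cor(t(lincrna_expr), t(coding_expr))
  pairs <- expand.grid(li = seq_len(nrow(lincrna_expr)),
                       ci = seq_len(nrow(coding_expr)))
  out <- data.frame(
    lincrna_gene = rownames(lincrna_expr)[pairs$li],
    coding_gene = rownames(coding_expr)[pairs$ci],
    r = rmat[cbind(pairs$li, pairs$ci)],
    n = n, stringsAsFactors = FALSE
  )
  out$p <- pearson_pvalue(out$r, n)
  out$is_neighbor <- FALSE
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    key <- paste(out$lincrna_gene, out$coding_gene, sep = "\r")
    nkey <- paste(neighbors$lincrna_gene, neighbors$coding_gene, sep = "\r")
    out$is_neighbor <- key %in% nkey
  }
  if (restrict == "neighbors") out <- out[out$is_neighbor, , drop = FALSE]
  p_call <- if (adjust) bh_adjust(out$p) else out$p
  out$is_ptg <- p_call < alpha
  out$is_deptg <- out$is_ptg & out$coding_gene %in% de_coding_ids
  out$sign <- ifelse(out$r >= 0, "positive", "negative")
  out <- out[, c("lincrna_gene", "coding_gene", "r", "p", "n",
                 "is_neighbor", "is_ptg", "is_deptg", "sign")]
  rownames(out) <- NULL
  out
}

#' Build the lincRNA-target co-expression network
#'
#' Bipartite graph over lincRNA and coding-gene nodes, one edge per
#' significant target pair.
#'
#' @param edges data.frame from [predict_targets()]
#' @param restrict `"deptg_only"` (default; keep DEPTG edges, as in a
#'   DEL-DEPTG network) or `"all"` (keep all PTG edges)
#' @return list with `nodes` (data.frame `id`, `type`) and `edges`
#'   (data.frame `lincrna_gene`, `coding_gene`, `r`, `p`, `sign`)
#' @export
build_network <- function(edges, restrict = c("deptg_only", "all")) {
  restrict <- match.arg(restrict)
  keep <- if (restrict == "deptg_only") edges$is_deptg else edges$is_ptg
  e <- edges[keep, c("lincrna_gene", "coding_gene", "r", "p", "sign"),
             drop = FALSE]
  rownames(e) <- NULL
  lid <- unique(e$lincrna_gene)
  cid <- unique(e$coding_gene)
  nodes <- data.frame(id = c(lid, cid),
                      type = rep(c("lincrna", "coding"),
                                 c(length(lid), length(cid))),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = e)
}
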