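#' Map lincRNA loci onto QTL intervals
#'
#' Reports one hit per (lincRNA locus, QTL) pair on the same chromosome
#' whose intervals intersect by at least 1 bp (half-open arithmetic:
#' touching intervals do not hit), the default intersect semantics of
#' interval tools such as BEDTools.
#'
#' @param loci data.frame with `gene_id`, `chrom`, `start`, `end` (typically
#'   the DEL gene loci from [gene_loci()])
#' @param qtls data.frame from [read_qtl_bed()]
#' @return data.frame `lincrna_id`, `qtl_id`, `overlap_bp`, `trait_name`,
#'   `trait_category`
#' @export
map_to_qtls <- function(loci, qtls) {
  empty <- data.frame(lincrna_id = character(), qtl_id = character(),
                      overlap_bp = numeric(), trait_name = character(),
                      trait_category = character(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0 || nrow(qtls) == 0) return(empty)
  lgr <- intervals_to_granges(loci)
  qgr <- intervals_to_granges(qtls)
  shared <- union(GenomeInfoDb::seqlevels(lgr), GenomeInfoDb::seqlevels(qgr))
  GenomeInfoDb::seqlevels(lgr) <- shared
  GenomeInfoDb::seqlevels(qgr) <- shared
  hits <- GenomicRanges::findOverlaps(lgr, qgr, minoverlap = 1,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  li <- S4Vectors::queryHits(hits)
  qi <- S4Vectors::subjectHits(hits)
  ov <- pmin(loci$end[li], qtls$end[qi]) - pmax(loci$start[li], qtls$start[qi])
  out <- data.frame(lincrna_id = loci$gene_id[li], qtl_id = qtls$qtl_id[qi],
                    overlap_bp = ov, trait_name = qtls$trait_name[qi],
                    trait_category = qtls$trait_category[qi],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize QTL hits
#'
#' @param hits data.frame from [map_to_qtls()]
#' @param qtls optional QTL table used to attach chromosomes to the
#'   per-chromosome counts; without it the chromosome summary is empty
#' @return list with
#'   \describe{
#'     \item{per_lincrna}{QTL hits per lincRNA (`lincrna_id`, `n_qtls`,
#'       `n_fat_qtls`)}
#'     \item{per_trait}{distinct lincRNAs per trait (`trait_name`,
#'       `trait_category`, `n_lincrnas`)}
#'     \item{per_chrom}{distinct hit QTLs per chromosome (`chrom`, `n_qtls`)}
#'     \item{n_hits,n_qtls_hit,n_fat_qtls_hit,n_lincrnas_hit}{scalar totals}
#'   }
#' @export
summarize_hits <- function(hits, qtls = NULL) {
  fat <- hits$trait_category == "fat_deposition"
  per_lincrna <- if (nrow(hits) == 0) {
    data.frame(lincrna_id = character(), n_qtls = integer(),
               n_fat_qtls = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(cbind(n_qtls = rep(1L, nrow(hits)),
                                  n_fat_qtls = as.integer(fat)),
                            by = list(lincrna_id = hits$lincrna_id), FUN = sum)
    agg[order(agg$lincrna_id), , drop = FALSE]
  }
  per_trait <- if (nrow(hits) == 0) {
    data.frame(trait_name = character(), trait_category = character(),
               n_lincrnas = integer(), stringsAsFactors = FALSE)
  } else {
    u <- unique(hits[, c("trait_name", "trait_category", "lincrna_id")])
    agg <- stats::aggregate(list(n_lincrnas = u$lincrna_id),
                            by = list(trait_name = u$trait_name,
                                      trait_category = u$trait_category),
                            FUN = length)
    agg[order(agg$trait_name), , drop = FALSE]
  }
  per_chrom <- data.frame(chrom = character(), n_qtls = integer(),
                          stringsAsFactors = FALSE)
  if (!is.null(qtls) && nrow(hits) > 0) {
    hit_q <- unique(hits$qtl_id)
    qsub <- qtls[qtls$qtl_id %in% hit_q, , drop = FALSE]
    agg <- stats::aggregate(list(n_qtls = qsub$qtl_id),
                            by = list(chrom = qsub$chrom), FUN = length)
    per_chrom <- agg[order(agg$chrom), , drop = FALSE]
  }
  rownames(per_lincrna) <- rownames(per_trait) <- rownames(per_chrom) <- NULL
  list(per_lincrna = per_lincrna, per_trait = per_trait,
       per_chrom = per_chrom,
       n_hits = nrow(hits),
       n_qtls_hit = length(unique(hits$qtl_id)),
       n_fat_qtls_hit = length(unique(hits$qtl_id[fat])),
       n_lincrnas_hit = length(unique(hits$lincrna_id)))
}
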