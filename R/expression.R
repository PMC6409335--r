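#' Compute FPKM from raw counts
#'
#' Fragments per kilobase of transcript per million mapped fragments, with
#' library size taken as the column sum of the supplied count matrix:
#' \deqn{FPKM_{ij} = counts_{ij} \cdot 10^9 / (length_i \cdot N_j)}
#'
#' @param counts non-negative count matrix (features x samples)
#' @param lengths named numeric vector of feature lengths in bp covering all
#'   rows of `counts`
#' @return numeric FPKM matrix, same dimnames as `counts`
#' @export
compute_fpkm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stop("counts must have feature rownames")
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len) > 0) {
    stop("lengths missing for: ", paste(utils::head(missing_len, 3),
                                        collapse = ", "))
  }
  len <- as.numeric(lengths[rownames(counts)])
  if (any(len <= 0)) stop("feature lengths must be positive")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    stop("zero library size in sample ", colnames(counts)[libsize <= 0][1])
  }
  sweep(sweep(counts * 1e9, 1, len, "/"), 2, libsize, "/")
}

#' Transcript-level FPKM from gene-level counts
#'
#' Assigns each transcript the read counts of its gene and normalizes by the
#' transcript's own exonic length. This mirrors expression quantified at the
#' gene level (as in htseq-count style counting) reported per transcript.
#'
#' @param counts gene-level count matrix
#' @param x a [transcript_set]; every transcript's gene_id must appear in
#'   `counts`
#' @return FPKM matrix with one row per transcript
#' @export
transcript_fpkm <- function(counts, x) {
  stopifnot(inherits(x, "transcript_set"))
  tx <- x$transcripts
  missing_gene <- setdiff(tx$gene_id, rownames(counts))
  if (length(missing_gene) > 0) {
    stop("genes missing from counts: ", paste(utils::head(missing_gene, 3),
                                              collapse = ", "))
  }
  m <- counts[tx$gene_id, , drop = FALSE]
  rownames(m) <- tx$transcript_id
  compute_fpkm(m, stats::setNames(tx$length, tx$transcript_id))
}

#' Characterize transcript classes
#'
#' For each named class of transcripts, computes the mean transcript length,
#' mean exon length (pooled over all exons of the class, not a mean of
#' per-transcript means), mean exon count, and mean FPKM over all
#' transcript-sample cells.
#'
#' @param sets named list of character vectors of transcript ids; classes
#'   must be disjoint
#' @param x a [transcript_set] covering all ids
#' @param fpkm transcript-level FPKM matrix covering all ids
#' @return data.frame `class`, `n_transcripts`, `mean_tx_length`,
#'   `mean_exon_length`, `mean_exon_count`, `mean_fpkm`; empty classes get
#'   `NA` means and are flagged in the `empty` column
#' @export
characterize_classes <- function(sets, x, fpkm) {
  stopifnot(inherits(x, "transcript_set"), !is.null(names(sets)))
  ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(ids)) stop("classes must be disjoint")
  missing_ids <- setdiff(ids, x$transcripts$transcript_id)
  if (length(missing_ids) > 0) {
    stop("transcripts not in set: ", paste(utils::head(missing_ids, 3),
                                           collapse = ", "))
  }
  rows <- lapply(names(sets), function(cl) {
    cid <- sets[[cl]]
    if (length(cid) == 0) {
      return(data.frame(class = cl, n_transcripts = 0L,
                        mean_tx_length = NA_real_, mean_exon_length = NA_real_,
                        mean_exon_count = NA_real_, mean_fpkm = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE))
    }
    tx <- x$transcripts[x$transcripts$transcript_id %in% cid, , drop = FALSE]
    ex <- x$exons[x$exons$transcript_id %in% cid, , drop = FALSE]
    data.frame(
      class = cl, n_transcripts = nrow(tx),
      mean_tx_length = mean(tx$length),
      mean_exon_length = mean(ex$end - ex$start),
      mean_exon_count = mean(tx$n_exons),
      mean_fpkm = mean(fpkm[cid, , drop = FALSE]),
      empty = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
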