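#' Build an overlap index over reference transcript spans
#'
#' Wraps the reference spans in a GRanges so that overlap queries run off an
#' interval index rather than an all-pairs scan. Strand is deliberately
#' dropped: intergenic status is span-level and strand-agnostic.
#'
#' @param reference a [transcript_set] (may be empty)
#' @return a `span_index` object usable with [query_index()]
#' @export
build_span_index <- function(reference) {
  stopifnot(inherits(reference, "transcript_set"))
  tx <- reference$transcripts
  gr <- if (nrow(tx) == 0) GenomicRanges::GRanges() else
    intervals_to_granges(tx, use_strand = FALSE)
  structure(list(granges = gr, transcript_id = tx$transcript_id,
                 chrom = tx$chrom, start = tx$start, end = tx$end),
            class = "span_index")
}

#' Query a span index for overlaps
#'
#' @param index a `span_index` from [build_span_index()]
#' @param chrom,start,end query interval(s), 0-based half-open; vectors are
#'   recycled to equal length
#' @return list with one integer vector per query: indices of overlapping
#'   reference spans (touching intervals do not overlap, half-open rule)
#' @export
query_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "span_index"))
  n <- max(length(chrom), length(start), length(end))
  q <- data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
                  end = rep_len(end, n))
  validate_intervals(q, what = "query")
  if (length(index$granges) == 0) {
    return(rep(list(integer(0)), n))
  }
  qgr <- intervals_to_granges(q, use_strand = FALSE)
  GenomeInfoDb::seqlevels(qgr) <- union(GenomeInfoDb::seqlevels(qgr),
                                        GenomeInfoDb::seqlevels(index$granges))
  GenomeInfoDb::seqlevels(index$granges) <- GenomeInfoDb::seqlevels(qgr)
  hits <- GenomicRanges::findOverlaps(qgr, index$granges, minoverlap = 1,
                                      ignore.strand = TRUE)
  out <- rep(list(integer(0)), n)
  if (length(hits) > 0) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

#' Classify assembled transcripts against a reference annotation
#'
#' A transcript is `intergenic_u` iff its span overlaps no reference
#' transcript span on any strand (the class-code-'u' notion of an intergenic
#' transcript); otherwise `overlapping_reference`. The nearest-reference gap
#' is the minimum distance in bp to any reference span on the same
#' chromosome (`Inf` if the chromosome carries no reference transcript);
#' adjacent (touching) spans have gap 0 but do not overlap.
#'
#' @param assembly a [transcript_set] of assembled transcripts
#' @param reference a [transcript_set] of reference transcripts
#' @return data.frame `transcript_id`, `class_label`, `nearest_reference_gap`
#' @export
classify_transcripts <- function(assembly, reference) {
  stopifnot(inherits(assembly, "transcript_set"),
            inherits(reference, "transcript_set"))
  tx <- assembly$transcripts
  out <- data.frame(transcript_id = tx$transcript_id,
                    class_label = rep("intergenic_u", nrow(tx)),
                    nearest_reference_gap = rep(Inf, nrow(tx)),
                    stringsAsFactors = FALSE)
  if (nrow(tx) == 0) return(out)
  ref <- reference$transcripts
  if (nrow(ref) == 0) return(out)

  idx <- build_span_index(reference)
  hits <- query_index(idx, tx$chrom, tx$start, tx$end)
  overlaps <- lengths(hits) > 0
  out$class_label[overlaps] <- "overlapping_reference"
  out$nearest_reference_gap[overlaps] <- 0

  # gap: per chromosome, distance to nearest reference span
  for (chr in unique(tx$chrom)) {
    qi <- which(tx$chrom == chr & !overlaps)
    if (length(qi) == 0) next
    ri <- which(ref$chrom == chr)
    if (length(ri) == 0) next
    qgr <- IRanges::IRanges(tx$start[qi] + 1, tx$end[qi])
    rgr <- IRanges::IRanges(ref$start[ri] + 1, ref$end[ri])
    nd <- IRanges::distanceToNearest(qgr, rgr)
    out$nearest_reference_gap[qi[S4Vectors::queryHits(nd)]] <-
      S4Vectors::mcols(nd)$distance
  }
  out
}
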