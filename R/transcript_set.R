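#' Transcript set container
#'
#' A `transcript_set` bundles transcript models with their exon structure.
#' All coordinates inside the package are 0-based half-open (BED arithmetic);
#' GTF, which is 1-based inclusive, is converted at the I/O boundary only.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`: one row per exon. Exons of one transcript must
#'   share `chrom`/`strand` and must not overlap each other.
#' @param biotype named character vector (or single string recycled) giving a
#'   biotype per transcript_id; one of `protein_coding`, `known_lincrna`,
#'   `novel`, `unassigned`. Unnamed single values are recycled.
#'
#' @return An object of class `transcript_set`: a list with
#'   \describe{
#'     \item{transcripts}{data.frame: `transcript_id`, `gene_id`, `chrom`,
#'       `start`, `end`, `strand`, `biotype`, `n_exons`, `length` (sum of
#'       exon lengths, bp)}
#'     \item{exons}{the exon table, sorted by transcript then start}
#'   }
#' @export
transcript_set <- function(exons, biotype = "unassigned") {
  required <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  validate_intervals(exons, what = "exon")
  if (!all(exons$strand %in% c("+", "-", "."))) {
    stop("exon strand must be one of '+', '-', '.'")
  }
  exons <- exons[order(exons$transcript_id, exons$start), required, drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) == 0) {
    transcripts <- data.frame(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      biotype = character(), n_exons = integer(), length = numeric(),
      stringsAsFactors = FALSE)
    return(structure(list(transcripts = transcripts, exons = exons),
                     class = "transcript_set"))
  }

  tid <- unique(exons$transcript_id)
  if (length(biotype) == 1 && is.null(names(biotype))) {
    biotype <- stats::setNames(rep(biotype, length(tid)), tid)
  }
  allowed <- c("protein_coding", "known_lincrna", "novel", "unassigned")
  if (!all(biotype %in% allowed)) {
    stop("biotype must be one of: ", paste(allowed, collapse = ", "))
  }

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx_rows <- lapply(names(by_tx), function(id) {
    ex <- exons[by_tx[[id]], , drop = FALSE]
    if (length(unique(ex$chrom)) != 1 || length(unique(ex$strand)) != 1) {
      stop("exons of transcript ", id, " span multiple chroms or strands")
    }
    if (length(unique(ex$gene_id)) != 1) {
      stop("exons of transcript ", id, " carry conflicting gene_ids")
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("exons of transcript ", id, " overlap")
    }
    bt <- if (id %in% names(biotype)) unname(biotype[[id]]) else "unassigned"
    data.frame(
      transcript_id = id, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
      start = min(ex$start), end = max(ex$end), strand = ex$strand[1],
      biotype = bt, n_exons = nrow(ex), length = sum(ex$end - ex$start),
      stringsAsFactors = FALSE
    )
  })
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  bt <- table(x$transcripts$biotype)
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of transcripts in a transcript_set
#' @param x a transcript_set
#' @return integer count
#' @export
n_transcripts <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  nrow(x$transcripts)
}

#' Restrict a transcript_set to a set of transcript ids
#' @param x a transcript_set
#' @param ids character vector of transcript ids to keep
#' @return a transcript_set with only the requested transcripts
#' @export
subset_transcripts <- function(x, ids) {
  stopifnot(inherits(x, "transcript_set"))
  keep_tx <- x$transcripts$transcript_id %in% ids
  keep_ex <- x$exons$transcript_id %in% ids
  structure(list(transcripts = x$transcripts[keep_tx, , drop = FALSE],
                 exons = x$exons[keep_ex, , drop = FALSE]),
            class = "transcript_set")
}

#' Gene loci from a transcript_set
#'
#' Collapses transcripts to gene level: the locus of a gene is the union span
#' (min start, max end) of its transcripts on its chromosome.
#'
#' @param x a transcript_set
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`
#' @export
gene_loci <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  tx <- x$transcripts
  by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    t2 <- tx[by_gene[[g]], , drop = FALSE]
    data.frame(gene_id = g, chrom = t2$chrom[1],
               start = min(t2$start), end = max(t2$end),
               strand = t2$strand[1], biotype = t2$biotype[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shared interval validation: 0 <= start < end, non-empty chrom
validate_intervals <- function(df, what = "interval") {
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(what, " coordinates contain NA")
  }
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad) > 0) {
    stop("invalid ", what, " interval at row ", bad[1],
         ": need 0 <= start < end, got [", df$start[bad[1]], ", ",
         df$end[bad[1]], ")")
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) {
    stop(what, " with empty chromosome name")
  }
  invisible(TRUE)
}

# GRanges view of a 0-based half-open interval table (chrom/start/end[/strand])
intervals_to_granges <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}
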