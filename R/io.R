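#' Read transcripts from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`,
#' optionally `gene_biotype`) into a [transcript_set]. GTF coordinates are
#' 1-based inclusive on disk; they are converted to the package-internal
#' 0-based half-open convention here and nowhere else.
#'
#' @param path path to a GTF file
#' @param kind `"reference"` or `"assembly"`; recorded for error messages
#'   only, the parse is identical.
#' @return a [transcript_set]. Biotype comes from the `gene_biotype`
#'   attribute when present and recognized, else `unassigned`.
#' @export
read_gtf <- function(path, kind = c("reference", "assembly")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "' (", kind, "): ",
                             conditionMessage(e))
  )
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) {
    stop("GTF '", path, "' (", kind, ") contains no exon features")
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id) ||
      anyNA(mc$transcript_id) || anyNA(mc$gene_id)) {
    stop("GTF '", path, "' has exon records without transcript_id/gene_id")
  }
  exons <- data.frame(
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  exons$strand[exons$strand == "*"] <- "."
  biotype <- "unassigned"
  if (!is.null(mc$gene_biotype)) {
    bt <- as.character(mc$gene_biotype)
    bt[is.na(bt) | !bt %in% c("protein_coding", "known_lincrna", "novel")] <-
      "unassigned"
    first <- !duplicated(exons$transcript_id)
    biotype <- stats::setNames(bt[first], exons$transcript_id[first])
  }
  transcript_set(exons, biotype = biotype)
}

#' Write a transcript_set to GTF
#'
#' Emits one `transcript` feature plus its `exon` features per transcript,
#' converting back to GTF's 1-based inclusive coordinates. The biotype is
#' written as the `gene_biotype` attribute so that `read_gtf(write_gtf(x))`
#' is the identity.
#'
#' @param x a [transcript_set]
#' @param path output path
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(x, path, source = "adipolinc") {
  stopifnot(inherits(x, "transcript_set"))
  tx <- x$transcripts
  ex <- x$exons
  if (nrow(tx) == 0) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  bt <- stats::setNames(tx$biotype, tx$transcript_id)
  feat <- rbind(
    data.frame(type = "transcript", transcript_id = tx$transcript_id,
               gene_id = tx$gene_id, chrom = tx$chrom, start = tx$start,
               end = tx$end, strand = tx$strand, stringsAsFactors = FALSE),
    data.frame(type = "exon", transcript_id = ex$transcript_id,
               gene_id = ex$gene_id, chrom = ex$chrom, start = ex$start,
               end = ex$end, strand = ex$strand, stringsAsFactors = FALSE)
  )
  feat <- feat[order(feat$transcript_id, feat$type != "transcript", feat$start), ]
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1, end = feat$end),
    strand = ifelse(feat$strand == ".", "*", feat$strand)
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feat$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- unname(bt[feat$transcript_id])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a QTL interval table
#'
#' Six tab-separated columns, no header: chrom, start, end, qtl_id,
#' trait_name, trait_category. Coordinates are BED-style 0-based half-open
#' and are kept as-is.
#'
#' @param path path to the QTL TSV/BED file
#' @return data.frame `qtl_id`, `chrom`, `start`, `end`, `trait_name`,
#'   `trait_category` (category one of `fat_deposition`, `other`)
#' @export
read_qtl_bed <- function(path) {
  if (!file.exists(path)) stop("QTL file not found: ", path)
  empty <- data.frame(qtl_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      trait_name = character(), trait_category = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character", "character"))
  if (ncol(raw) != 6) stop("QTL file must have 6 tab-separated columns, got ",
                           ncol(raw))
  names(raw) <- c("chrom", "start", "end", "qtl_id", "trait_name",
                  "trait_category")
  validate_intervals(raw, what = "QTL")
  if (any(!nzchar(raw$trait_name))) stop("QTL with empty trait_name")
  bad <- setdiff(unique(raw$trait_category), c("fat_deposition", "other"))
  if (length(bad) > 0) {
    stop("unknown QTL trait_category '", bad[1],
         "'; allowed: fat_deposition, other")
  }
  raw[, c("qtl_id", "chrom", "start", "end", "trait_name", "trait_category")]
}

#' Write a QTL interval table
#' @param qtls data.frame as returned by [read_qtl_bed()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_qtl_bed <- function(qtls, path) {
  out <- qtls[, c("chrom", "start", "end", "qtl_id", "trait_name",
                  "trait_category")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path path to an (uncompressed) FASTA file
#' @return named character vector of upper-case nucleotide sequences over
#'   A/C/G/T/N, named by the first whitespace-delimited token of each header
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read without alphabet coercion so invalid letters are caught here
  # rather than silently dropped
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA sequence '", names(seqs)[bad][1],
         "' contains non-ACGTN characters")
  }
  seqs
}

#' Write transcript sequences to FASTA
#' @param seqs named character vector of nucleotide sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a read-count matrix
#'
#' Tab-separated with a header line: first column `gene_id`, one column per
#' sample. Cells must be non-negative integers.
#'
#' @param path path to counts TSV
#' @param samples optional data.frame from [read_samples()]; when given, the
#'   count columns must match `samples$sample_id` exactly (any order on disk
#'   is accepted, columns are reordered to the metadata order).
#' @return integer matrix, rownames gene ids, colnames sample ids
#' @export
read_counts <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("counts file must start with a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in counts file")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("counts matrix contains missing cells")
  if (any(m < 0)) stop("counts must be non-negative; found ", min(m))
  if (any(m != round(m))) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  if (!is.null(samples)) {
    if (!setequal(colnames(m), samples$sample_id)) {
      stop("counts columns do not match sample metadata ids")
    }
    m <- m[, samples$sample_id, drop = FALSE]
  }
  m
}

#' Write a read-count matrix
#' @param counts integer matrix with gene rownames and sample colnames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with header columns `sample_id`, `group`, `ebv`. Groups must
#' be `fat`/`lean`; `ebv` is the backfat-thickness estimated breeding value
#' in mm (signed).
#'
#' @param path path to samples TSV
#' @return data.frame `sample_id`, `group` (factor fat/lean), `ebv`
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "ebv")
  if (!all(need %in% names(df))) {
    stop("samples file needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in samples file")
  if (!all(df$group %in% c("fat", "lean"))) {
    stop("sample group must be 'fat' or 'lean'")
  }
  df$group <- factor(df$group, levels = c("lean", "fat"))
  df$ebv <- as.numeric(df$ebv)
  df[, need]
}

#' Write sample metadata
#' @param samples data.frame as returned by [read_samples()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_samples <- function(samples, path) {
  out <- samples
  out$group <- as.character(out$group)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
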