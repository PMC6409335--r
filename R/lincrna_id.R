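#' Structural lincRNA filter
#'
#' Retains transcripts with length >= `min_length` bp (sum of exon lengths)
#' and exon number >= `min_exons`; both boundaries inclusive. The 200 bp /
#' 2 exon defaults are the conventional lncRNA definition plus a guard
#' against mono-exonic assembly artifacts.
#'
#' @param x a [transcript_set]
#' @param min_length minimum transcript length in bp (default 200)
#' @param min_exons minimum exon count (default 2)
#' @return character vector of surviving transcript ids
#' @export
filter_structure <- function(x, min_length = 200, min_exons = 2) {
  stopifnot(inherits(x, "transcript_set"))
  tx <- x$transcripts
  tx$transcript_id[tx$length >= min_length & tx$n_exons >= min_exons]
}

#' Read a protein homology-evidence table
#'
#' Tab-separated with header `transcript_id`, `source`, `evalue`: one row
#' per hit of a transcript's six-frame translation against a protein or
#' domain database. The table is produced upstream (HMMER/Pfam, BLASTX vs
#' NR/UniRef90); the package only consumes it.
#'
#' @param path path to evidence TSV
#' @return data.frame `transcript_id`, `source` (pfam/nr/uniref90), `evalue`
#' @export
read_homology_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("transcript_id", "source", "evalue")
  if (!all(need %in% names(df))) {
    stop("evidence file needs columns: ", paste(need, collapse = ", "))
  }
  df$evalue <- as.numeric(df$evalue)
  if (!all(df$source %in% c("pfam", "nr", "uniref90"))) {
    stop("evidence source must be pfam, nr or uniref90")
  }
  if (anyNA(df$evalue) || any(!is.finite(df$evalue)) || any(df$evalue < 0)) {
    stop("evidence E-values must be finite and >= 0")
  }
  df[, need]
}

#' Homology filter
#'
#' Discards a transcript iff any evidence row for it has
#' `evalue < threshold`; transcripts with no evidence (or only hits at or
#' above the threshold) are retained.
#'
#' @param ids character vector of candidate transcript ids
#' @param evidence data.frame from [read_homology_evidence()]; may be empty
#' @param threshold E-value cutoff (default 1e-5)
#' @return character vector of surviving ids
#' @export
filter_homology <- function(ids, evidence, threshold = 1e-5) {
  if (is.null(evidence) || nrow(evidence) == 0) return(ids)
  if (any(evidence$evalue < 0)) stop("negative E-value in evidence table")
  hit <- unique(evidence$transcript_id[evidence$evalue < threshold])
  setdiff(ids, hit)
}

#' Expression filter
#'
#' Retains transcripts with FPKM > 0 in at least one sample.
#'
#' @param ids character vector of candidate transcript ids
#' @param fpkm numeric matrix (transcripts x samples) covering all `ids`
#' @return character vector of surviving ids
#' @export
filter_expression <- function(ids, fpkm) {
  missing_ids <- setdiff(ids, rownames(fpkm))
  if (length(missing_ids) > 0) {
    stop("transcripts missing from expression matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (length(ids) == 0) return(character(0))
  keep <- apply(fpkm[ids, , drop = FALSE], 1, max) > 0
  ids[keep]
}

#' Coding-potential filter
#'
#' Retains transcripts whose ORF-based coding-potential score is negative
#' (predicted noncoding).
#'
#' @param ids candidate transcript ids
#' @param seqs named nucleotide sequences covering all `ids`
#' @param l0,c0 score constants, see [coding_potential_score()]
#' @return character vector of surviving ids
#' @export
filter_coding_potential <- function(ids, seqs, l0 = 300, c0 = 0.35) {
  missing_ids <- setdiff(ids, names(seqs))
  if (length(missing_ids) > 0) {
    stop("transcripts missing from sequence set: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (length(ids) == 0) return(character(0))
  cp <- coding_potential_score(orf_table(seqs[ids]), l0 = l0, c0 = c0)
  cp$transcript_id[cp$label == "noncoding"]
}

#' Run the full lincRNA identification cascade
#'
#' Applies, in order: intergenic classification against the (non-lincRNA)
#' reference transcripts, the structural filter, the ORF coding-potential
#' filter, the homology-evidence filter, and the expression filter.
#' Survivors are labelled `known` when their span overlaps a reference
#' transcript of biotype `known_lincrna`, else `novel`.
#'
#' @param assembly a [transcript_set] of assembled transcripts
#' @param reference a [transcript_set]; transcripts with biotype
#'   `known_lincrna` are excluded from the intergenic screen (they are
#'   noncoding loci, not protein-coding neighborhood) and used only for the
#'   known/novel call.
#' @param seqs named nucleotide sequences for (at least) the assembly
#'   transcripts that reach the coding-potential stage
#' @param evidence homology-evidence data.frame (may be empty / NULL)
#' @param fpkm transcript-level FPKM matrix
#' @param min_length,min_exons,evalue,orf_l0,orf_c0 stage thresholds
#' @return list with
#'   \describe{
#'     \item{lincrna}{data.frame `transcript_id`, `status` (novel/known)}
#'     \item{report}{data.frame `stage`, `n_in`, `n_out` for the five
#'       stages, with the per-stage survivor id sets in
#'       `attr(report, "survivors")`}
#'     \item{eliminated}{data.frame `transcript_id`, `stage` naming the
#'       stage at which each non-surviving transcript fell}
#'   }
#' @export
run_identification <- function(assembly, reference, seqs, evidence, fpkm,
                               min_length = 200, min_exons = 2,
                               evalue = 1e-5, orf_l0 = 300, orf_c0 = 0.35) {
  stopifnot(inherits(assembly, "transcript_set"),
            inherits(reference, "transcript_set"))
  all_ids <- assembly$transcripts$transcript_id

  ref_tx <- reference$transcripts
  screen_ref <- subset_transcripts(
    reference, ref_tx$transcript_id[ref_tx$biotype != "known_lincrna"])
  known_ref <- subset_transcripts(
    reference, ref_tx$transcript_id[ref_tx$biotype == "known_lincrna"])

  stages <- c("intergenic", "structure", "coding_potential", "homology",
              "expression")
  surv <- vector("list", length(stages))
  names(surv) <- stages

  cls <- classify_transcripts(assembly, screen_ref)
  surv$intergenic <- cls$transcript_id[cls$class_label == "intergenic_u"]
  surv$structure <- intersect(
    filter_structure(assembly, min_length, min_exons), surv$intergenic)
  surv$coding_potential <- filter_coding_potential(
    surv$structure, seqs, l0 = orf_l0, c0 = orf_c0)
  surv$homology <- filter_homology(surv$coding_potential, evidence, evalue)
  surv$expression <- filter_expression(surv$homology, fpkm)

  n_in <- c(length(all_ids), lengths(surv)[-length(surv)])
  report <- data.frame(stage = stages, n_in = unname(n_in),
                       n_out = unname(lengths(surv)),
                       stringsAsFactors = FALSE)
  attr(report, "survivors") <- surv

  prev <- all_ids
  elim <- list()
  for (s in stages) {
    dropped <- setdiff(prev, surv[[s]])
    if (length(dropped) > 0) {
      elim[[s]] <- data.frame(transcript_id = dropped, stage = s,
                              stringsAsFactors = FALSE)
    }
    prev <- surv[[s]]
  }
  eliminated <- if (length(elim) > 0) do.call(rbind, elim) else
    data.frame(transcript_id = character(), stage = character(),
               stringsAsFactors = FALSE)
  rownames(eliminated) <- NULL

  final <- surv$expression
  status <- rep("novel", length(final))
  if (length(final) > 0 && n_transcripts(known_ref) > 0) {
    fin_set <- subset_transcripts(assembly, final)
    fin_tx <- fin_set$transcripts
    fin_tx <- fin_tx[match(final, fin_tx$transcript_id), ]
    hits <- query_index(build_span_index(known_ref),
                        fin_tx$chrom, fin_tx$start, fin_tx$end)
    status[lengths(hits) > 0] <- "known"
  }
  lincrna <- data.frame(transcript_id = final, status = status,
                        stringsAsFactors = FALSE)
  list(lincrna = lincrna, report = report, eliminated = eliminated)
}
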