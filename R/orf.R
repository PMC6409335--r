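#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames with the
#' standard genetic code. Frames `+1/+2/+3` read the sequence as given with
#' offsets 0/1/2; frames `-1/-2/-3` read the reverse complement likewise.
#' Stops are rendered `*`; any codon containing `N` is rendered `X`;
#' trailing 1-2 nt that do not fill a codon are dropped.
#'
#' @param seq a single nucleotide string over A/C/G/T/N (case-insensitive)
#' @return named character vector of 6 amino-acid strings, names
#'   `+1,+2,+3,-1,-2,-3`
#' @export
six_frame_translate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- vapply(seq_along(frames), function(i) {
    src <- if (i <= 3) fwd else rev
    off <- (i - 1) %% 3
    len <- length(src) - off
    len <- len - len %% 3
    if (len <= 0) return("")
    sub <- Biostrings::subseq(src, start = off + 1, width = len)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }, character(1))
  stats::setNames(out, frames)
}

#' Find the longest complete open reading frame
#'
#' An ORF is an `ATG` followed by an in-frame stop codon, both contained in
#' one of the six frames; its length in nt includes the stop codon. The
#' longest ORF wins; ties break by frame order `+1,+2,+3,-1,-2,-3`, then by
#' leftmost start within the frame.
#'
#' @param seq a single nucleotide string over A/C/G/T/N
#' @return list with `longest_orf_nt` (0 if no complete ORF), `orf_frame`
#'   (`"none"` if no ORF), and `orf_coverage` (= longest_orf_nt / nchar(seq))
#' @export
find_longest_orf <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  n <- nchar(seq)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  best_nt <- 0L
  best_frame <- "none"
  for (i in seq_along(frames)) {
    s <- if (i <= 3) seq else rc
    off <- (i - 1) %% 3
    n_cod <- (n - off) %/% 3
    if (n_cod < 2) next
    starts <- off + 1 + 3 * (seq_len(n_cod) - 1)
    cod <- substring(s, starts, starts + 2)
    atg <- which(cod == "ATG")
    stp <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0 || length(stp) == 0) next
    # first stop at or after each ATG (never equal); NA if none downstream
    nxt <- stp[findInterval(atg, stp) + 1]
    len_nt <- 3L * (nxt - atg + 1L)
    len_nt <- len_nt[!is.na(len_nt)]
    if (length(len_nt) == 0) next
    # which.max is leftmost on ties; strict > keeps the earliest frame
    if (max(len_nt) > best_nt) {
      best_nt <- max(len_nt)
      best_frame <- frames[i]
    }
  }
  list(longest_orf_nt = best_nt, orf_frame = best_frame,
       orf_coverage = if (n > 0) best_nt / n else 0)
}

#' ORF table for a set of transcripts
#'
#' @param seqs named character vector of nucleotide sequences
#' @return data.frame `transcript_id`, `longest_orf_nt`, `orf_frame`,
#'   `orf_coverage`
#' @export
orf_table <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  rows <- lapply(seqs, find_longest_orf)
  data.frame(
    transcript_id = names(seqs),
    longest_orf_nt = vapply(rows, `[[`, integer(1), "longest_orf_nt"),
    orf_frame = vapply(rows, `[[`, character(1), "orf_frame"),
    orf_coverage = vapply(rows, `[[`, numeric(1), "orf_coverage"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Transparent ORF-based coding-potential score
#'
#' A two-term stand-in for SVM-based coding-potential classifiers, keeping
#' their sign convention (score < 0 means predicted noncoding):
#' \deqn{score = (orf_{nt}/L_0 - 1) + (coverage - C_0)}
#' with reference ORF length \eqn{L_0 = 300} nt (the classical 100-codon
#' noncoding cutoff) and reference ORF coverage \eqn{C_0 = 0.35}. A
#' transcript scores positive when its longest ORF is long in absolute terms
#' and covers much of the transcript.
#'
#' @param orfs data.frame from [orf_table()] (columns `transcript_id`,
#'   `longest_orf_nt`, `orf_coverage`); an optional numeric column `score`
#'   overrides the built-in formula (e.g. an externally computed score).
#' @param l0 reference ORF length in nt (default 300)
#' @param c0 reference ORF coverage (default 0.35)
#' @return data.frame `transcript_id`, `score`, `label` (`coding` iff
#'   score >= 0, else `noncoding`)
#' @export
coding_potential_score <- function(orfs, l0 = 300, c0 = 0.35) {
  stopifnot(l0 > 0, c0 >= 0)
  score <- if ("score" %in% names(orfs)) {
    as.numeric(orfs$score)
  } else {
    (orfs$longest_orf_nt / l0 - 1) + (orfs$orf_coverage - c0)
  }
  data.frame(
    transcript_id = orfs$transcript_id,
    score = score,
    label = ifelse(score < 0, "noncoding", "coding"),
    stringsAsFactors = FALSE
  )
}
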