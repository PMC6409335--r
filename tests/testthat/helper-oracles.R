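# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's interval-index / Biostrings code
# paths so that agreement tests compare two distinct routes.

# all-pairs interval overlap on 0-based half-open intervals
brute_overlap_sets <- function(queries, subjects) {
  lapply(seq_len(nrow(queries)), function(i) {
    hits <- integer(0)
    for (j in seq_len(nrow(subjects))) {
      if (queries$chrom[i] == subjects$chrom[j] &&
          queries$start[i] < subjects$end[j] &&
          subjects$start[j] < queries$end[i]) {
        hits <- c(hits, j)
      }
    }
    hits
  })
}

# all-pairs gap computation (0 when overlapping or touching)
brute_gap <- function(a_start, a_end, b_start, b_end) {
  max(0, max(a_start, b_start) - min(a_end, b_end))
}

# hand-rolled standard genetic code
ORACLE_CODON <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

oracle_translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  n_cod <- (n - offset) %/% 3
  if (n_cod <= 0) return("")
  aa <- character(n_cod)
  for (k in seq_len(n_cod)) {
    cod <- substr(seq, offset + 3 * k - 2, offset + 3 * k)
    aa[k] <- if (grepl("N", cod)) "X" else ORACLE_CODON[[cod]]
  }
  paste(aa, collapse = "")
}

oracle_six_frames <- function(seq) {
  rc <- oracle_revcomp(seq)
  c("+1" = oracle_translate_frame(seq, 0),
    "+2" = oracle_translate_frame(seq, 1),
    "+3" = oracle_translate_frame(seq, 2),
    "-1" = oracle_translate_frame(rc, 0),
    "-2" = oracle_translate_frame(rc, 1),
    "-3" = oracle_translate_frame(rc, 2))
}

# exhaustive ORF scan: for every frame and every ATG codon, walk forward
# codon by codon to the first stop; track the global maximum
brute_longest_orf <- function(seq) {
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rc <- oracle_revcomp(seq)
  best <- 0L
  best_frame <- "none"
  for (i in seq_along(frames)) {
    s <- if (i <= 3) seq else rc
    off <- (i - 1) %% 3
    n_cod <- (nchar(s) - off) %/% 3
    if (n_cod < 2) next
    codons <- substring(s, off + 1 + 3 * (seq_len(n_cod) - 1),
                        off + 3 * seq_len(n_cod))
    for (a in which(codons == "ATG")) {
      for (k in a:n_cod) {
        if (codons[k] %in% c("TAA", "TAG", "TGA")) {
          len <- 3L * (k - a + 1L)
          if (len > best) { best <- len; best_frame <- frames[i] }
          break
        }
      }
    }
  }
  list(longest_orf_nt = best, orf_frame = best_frame)
}

# compact transcript_set builder: one row per exon given as
# list(c(tx, gene, chrom, start, end, strand))
make_ts <- function(..., biotype = "unassigned") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r[[1]], gene_id = r[[2]], chrom = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]),
               strand = r[[6]], stringsAsFactors = FALSE)
  }))
  transcript_set(df, biotype = biotype)
}

# random multi-exon transcript set for round-trip tests
random_ts <- function(n, seed) {
  set.seed(seed)
  ex <- NULL
  for (i in seq_len(n)) {
    chrom <- paste0("chr", sample(1:3, 1))
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    pos <- sample(0:99999, 1)
    for (k in seq_len(n_ex)) {
      len <- sample(50:400, 1)
      ex <- rbind(ex, data.frame(
        transcript_id = sprintf("tx%03d", i), gene_id = sprintf("g%03d", i),
        chrom = chrom, start = pos, end = pos + len, strand = strand,
        stringsAsFactors = FALSE))
      pos <- pos + len + sample(50:500, 1)
    }
  }
  bt <- setNames(sample(c("protein_coding", "known_lincrna", "novel"),
                        n, replace = TRUE), sprintf("tx%03d", seq_len(n)))
  transcript_set(ex, biotype = bt)
}

# random interval table
random_intervals <- function(n, seed, chroms = paste0("chr", 1:3),
                             max_pos = 1e6, len_range = c(100, 50000)) {
  set.seed(seed)
  start <- sample(0:(max_pos - len_range[2]), n, replace = TRUE)
  data.frame(
    gene_id = sprintf("iv%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample(len_range[1]:len_range[2], n, replace = TRUE),
    stringsAsFactors = FALSE)
}
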