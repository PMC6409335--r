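#!/usr/bin/env Rscript
# Step 3 — characterize transcript classes.
#
# Compares protein-coding transcripts with novel and known lincRNAs on
# transcript length, pooled exon length, exon number, and mean FPKM — the
# standard structural contrasts (lincRNAs: shorter, fewer but longer exons,
# lower expression).

suppressPackageStartupMessages(library(adipolinc))

indir <- "results/study/inputs"
outdir <- "results/study"
samples <- read_samples(file.path(indir, "samples.tsv"))
counts <- read_counts(file.path(indir, "counts.tsv"), samples)
assembly <- read_gtf(file.path(indir, "assembly.gtf"), "assembly")
reference <- read_gtf(file.path(indir, "reference.gtf"), "reference")
fpkm <- transcript_fpkm(counts, assembly)

linc <- read.delim(file.path(outdir, "lincrna.tsv"))
cls <- classify_transcripts(assembly, reference)
coding_ids <- setdiff(
  cls$transcript_id[cls$class_label == "overlapping_reference"],
  linc$transcript_id)

char <- characterize_classes(
  list(protein_coding = coding_ids,
       novel_lincrna = linc$transcript_id[linc$status == "novel"],
       known_lincrna = linc$transcript_id[linc$status == "known"]),
  assembly, fpkm)
write.table(char, file.path(outdir, "characterization.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(char[, c("class", "n_transcripts", "mean_tx_length",
               "mean_exon_length", "mean_exon_count", "mean_fpkm")],
      row.names = FALSE, digits = 3)
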