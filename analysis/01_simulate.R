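#!/usr/bin/env Rscript
# Step 1 — simulate the study.
#
# Generates the miniature fat-vs-lean adipose RNA-seq study that the rest of
# the analysis runs on: a reference annotation (200 protein-coding and 20
# known lincRNA genes), an assembled transcriptome carrying 30 planted novel
# intergenic noncoding transcripts plus 23 decoys (long-ORF, structural,
# homology and unexpressed), NB gene counts for 10 fat vs 10 lean samples
# with planted fold changes, sample metadata with signed backfat-thickness
# EBVs, a 50-interval QTL catalogue, and a protein homology-evidence table.
# The planted ground truth is written alongside as JSON.

suppressPackageStartupMessages(library(adipolinc))

cfg <- sim_config(seed = 1)
indir <- "results/study/inputs"
truth <- generate_study(cfg, indir)

cat("wrote study inputs to", indir, "\n")
cat("planted novel lincRNAs:   ", length(truth$true_lincrna_ids), "\n")
cat("known lincRNA re-assemblies:", length(truth$true_known_lincrna_ids), "\n")
cat("decoys by defect stage:    ",
    paste(names(truth$true_decoy_ids), lengths(truth$true_decoy_ids),
          sep = "=", collapse = ", "), "\n")
cat("planted DE genes:          ", nrow(truth$true_de_genes), "\n")
cat("planted correlated pairs:  ", nrow(truth$true_correlated_pairs), "\n")
cat("planted lincRNA-QTL hits:  ", nrow(truth$true_qtl_hits), "\n")
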