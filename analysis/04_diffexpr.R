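#!/usr/bin/env Rscript
# Step 4 — differential expression, fat vs lean.
#
# Median-of-ratios normalization followed by the per-gene NB Wald test and
# BH adjustment at FDR 0.05. Reports differentially expressed lincRNA genes
# (DELs) and protein-coding genes separately.

suppressPackageStartupMessages(library(adipolinc))

indir <- "results/study/inputs"
outdir <- "results/study"
samples <- read_samples(file.path(indir, "samples.tsv"))
counts <- read_counts(file.path(indir, "counts.tsv"), samples)
assembly <- read_gtf(file.path(indir, "assembly.gtf"), "assembly")

sf <- estimate_size_factors(counts)
groups <- samples$group[match(colnames(counts), samples$sample_id)]
res <- nb_wald_test(counts, sf, groups)
write.table(res, file.path(outdir, "de_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

calls <- call_de(res)
tx2gene <- setNames(assembly$transcripts$gene_id,
                    assembly$transcripts$transcript_id)
linc <- read.delim(file.path(outdir, "lincrna.tsv"))
linc_genes <- unique(tx2gene[linc$transcript_id])
de_all <- c(calls$up_in_fat, calls$down_in_fat)
dels <- intersect(de_all, linc_genes)

cat("genes tested:", nrow(res),
    "(excluded all-zero:", length(attr(res, "excluded")), ")\n")
cat("DE lincRNA genes (DELs):", length(dels),
    "( up:", length(intersect(calls$up_in_fat, linc_genes)),
    "down:", length(intersect(calls$down_in_fat, linc_genes)), ")\n")
cat("DE non-lincRNA genes:", length(setdiff(de_all, linc_genes)), "\n")
writeLines(dels, file.path(outdir, "del_genes.txt"))
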