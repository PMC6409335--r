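#!/usr/bin/env Rscript
# Step 6 — QTL colocalization of the DELs.
#
# Intersects DEL gene loci with the QTL catalogue (>= 1 bp, half-open) and
# summarizes hits per lincRNA, per trait and per chromosome, with the
# fat-deposition subset broken out.

suppressPackageStartupMessages(library(adipolinc))

indir <- "results/study/inputs"
outdir <- "results/study"
assembly <- read_gtf(file.path(indir, "assembly.gtf"), "assembly")
qtls <- read_qtl_bed(file.path(indir, "qtl.tsv"))
dels <- readLines(file.path(outdir, "del_genes.txt"))

gl <- gene_loci(assembly)
hits <- map_to_qtls(gl[gl$gene_id %in% dels, ], qtls)
s <- summarize_hits(hits, qtls)
write.table(hits, file.path(outdir, "qtl_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("DELs located in QTLs:", s$n_lincrnas_hit, "of", length(dels), "\n")
cat("QTLs hit:", s$n_qtls_hit,
    "( fat-deposition:", s$n_fat_qtls_hit, ")\n")
cat("\nhits per DEL:\n")
print(s$per_lincrna, row.names = FALSE)
cat("\nQTLs hit per chromosome:\n")
print(s$per_chrom, row.names = FALSE)
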