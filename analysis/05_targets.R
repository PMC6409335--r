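#!/usr/bin/env Rscript
# Step 5 — cis target prediction for the DELs.
#
# Finds protein-coding neighbors (<100 kb) of each DEL gene, tests every
# DEL-coding pair for Pearson correlation of FPKM (raw p < 0.05 defines a
# potential target gene, PTG; a differentially expressed PTG is a DEPTG),
# and exports the DEL-DEPTG co-expression network edge list.

suppressPackageStartupMessages(library(adipolinc))

indir <- "results/study/inputs"
outdir <- "results/study"
samples <- read_samples(file.path(indir, "samples.tsv"))
counts <- read_counts(file.path(indir, "counts.tsv"), samples)
assembly <- read_gtf(file.path(indir, "assembly.gtf"), "assembly")
linc <- read.delim(file.path(outdir, "lincrna.tsv"))
res <- read.delim(file.path(outdir, "de_results.tsv"))
dels <- readLines(file.path(outdir, "del_genes.txt"))

tx2gene <- setNames(assembly$transcripts$gene_id,
                    assembly$transcripts$transcript_id)
linc_genes <- unique(tx2gene[linc$transcript_id])
coding_genes <- setdiff(unique(assembly$transcripts$gene_id), linc_genes)
de_genes <- res$gene_id[res$padj < 0.05]

gene_len <- tapply(assembly$transcripts$length,
                   assembly$transcripts$gene_id, max)
fpkm <- compute_fpkm(counts, setNames(as.numeric(gene_len), names(gene_len)))
testable <- rownames(fpkm)[apply(fpkm, 1, sd) > 0]
dels <- intersect(dels, testable)
coding_use <- intersect(coding_genes, testable)

gl <- gene_loci(assembly)
neighbors <- find_neighbors(gl[gl$gene_id %in% dels, ],
                            gl[gl$gene_id %in% coding_use, ])
edges <- predict_targets(fpkm[dels, , drop = FALSE],
                         fpkm[coding_use, , drop = FALSE],
                         de_coding_ids = intersect(de_genes, coding_use),
                         neighbors = neighbors)
net <- build_network(edges, restrict = "deptg_only")
write.table(edges, file.path(outdir, "target_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(net$edges, file.path(outdir, "network_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("DEL-coding pairs tested:", nrow(edges), "\n")
cat("neighbor pairs (<100 kb):", nrow(neighbors), "\n")
cat("PTGs:", sum(edges$is_ptg), "  DEPTGs:", sum(edges$is_deptg), "\n")
cat("network:", nrow(net$nodes), "nodes,", nrow(net$edges), "edges\n")
truth <- jsonlite::fromJSON(file.path(indir, "ground_truth.json"))
planted <- paste(truth$true_correlated_pairs$lincrna_gene,
                 truth$true_correlated_pairs$coding_gene)
key <- paste(edges$lincrna_gene, edges$coding_gene)
hit <- edges$is_ptg[match(planted, key)]
cat("planted correlated pairs recovered as PTGs:",
    sum(hit, na.rm = TRUE), "of", sum(!is.na(hit)), "testable\n")
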