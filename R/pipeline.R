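#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic study (unless `outdir/inputs` already holds one
#' from the same call), reads every input back through the package's file
#' readers, and executes the stages in order: intergenic classification +
#' lincRNA identification, class characterization, two-group differential
#' expression, correlation-based target prediction, and QTL colocalization.
#' All stage tables are written as TSV under `outdir/results` together with
#' a machine-readable `report.json`.
#'
#' @param config a [sim_config()]
#' @param outdir working directory for inputs and results
#' @param alpha_de FDR threshold for the DE call (default 0.05)
#' @param alpha_ptg raw p threshold for the PTG call (default 0.05)
#' @param window_bp neighbor window in bp (default 100000)
#' @param min_length,min_exons,evalue,orf_l0,orf_c0 identification thresholds
#' @param stages character subset of
#'   `c("characterize", "de", "targets", "qtl")`; identification always
#'   runs, `targets`/`qtl` require `de`. A skipped stage is reported as
#'   absent (NULL) in the run report.
#' @return the run report, invisibly: a list with `config`, `filter_report`,
#'   `n_lincrna`, `n_novel`, `n_known`, and per-stage summaries (`de`,
#'   `characterization`, `targets`, `qtl`)
#' @export
run_study <- function(config = sim_config(), outdir,
                      alpha_de = 0.05, alpha_ptg = 0.05, window_bp = 100000,
                      min_length = 200, min_exons = 2, evalue = 1e-5,
                      orf_l0 = 300, orf_c0 = 0.35,
                      stages = c("characterize", "de", "targets", "qtl")) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("targets", "qtl") %in% stages) && !"de" %in% stages) {
    stop("stages 'targets' and 'qtl' require stage 'de'")
  }
  indir <- file.path(outdir, "inputs")
  resdir <- file.path(outdir, "results")
  dir.create(resdir, showWarnings = FALSE, recursive = TRUE)
  generate_study(config, indir)

  reference <- read_gtf(file.path(indir, "reference.gtf"), "reference")
  assembly <- read_gtf(file.path(indir, "assembly.gtf"), "assembly")
  seqs <- read_fasta(file.path(indir, "transcripts.fa"))
  samples <- read_samples(file.path(indir, "samples.tsv"))
  counts <- read_counts(file.path(indir, "counts.tsv"), samples)
  qtls <- read_qtl_bed(file.path(indir, "qtl.tsv"))
  evidence <- read_homology_evidence(file.path(indir, "homology_evidence.tsv"))

  fpkm_tx <- transcript_fpkm(counts, assembly)
  ident <- run_identification(assembly, reference, seqs, evidence, fpkm_tx,
                              min_length = min_length, min_exons = min_exons,
                              evalue = evalue, orf_l0 = orf_l0, orf_c0 = orf_c0)
  surv <- attr(ident$report, "survivors")
  all_ids <- assembly$transcripts$transcript_id
  coding_tx_ids <- setdiff(all_ids, surv$intergenic)
  tx2gene <- stats::setNames(assembly$transcripts$gene_id,
                             assembly$transcripts$transcript_id)
  linc_genes <- unique(tx2gene[ident$lincrna$transcript_id])
  coding_genes <- unique(tx2gene[coding_tx_ids])

  utils::write.table(ident$report, file.path(resdir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ident$eliminated, file.path(resdir, "eliminated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ident$lincrna, file.path(resdir, "lincrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gtf(subset_transcripts(assembly, ident$lincrna$transcript_id),
            file.path(resdir, "lincrna.gtf"))

  report <- list(
    package_version = as.character(utils::packageVersion("adipolinc")),
    config = unclass(config),
    thresholds = list(alpha_de = alpha_de, alpha_ptg = alpha_ptg,
                      window_bp = window_bp, min_length = min_length,
                      min_exons = min_exons, evalue = evalue,
                      orf_l0 = orf_l0, orf_c0 = orf_c0),
    filter_report = ident$report,
    n_lincrna = nrow(ident$lincrna),
    n_novel = sum(ident$lincrna$status == "novel"),
    n_known = sum(ident$lincrna$status == "known"),
    characterization = NULL, de = NULL, targets = NULL, qtl = NULL
  )

  if ("characterize" %in% stages) {
    sets <- list(
      protein_coding = coding_tx_ids,
      novel_lincrna = ident$lincrna$transcript_id[ident$lincrna$status == "novel"],
      known_lincrna = ident$lincrna$transcript_id[ident$lincrna$status == "known"]
    )
    char <- characterize_classes(sets, assembly, fpkm_tx)
    utils::write.table(char, file.path(resdir, "characterization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$characterization <- char
  }

  de_res <- NULL
  del_genes <- de_coding <- character(0)
  if ("de" %in% stages) {
    sf <- estimate_size_factors(counts)
    de_res <- nb_wald_test(counts, sf, samples$group[match(colnames(counts),
                                                           samples$sample_id)],
                           alpha = alpha_de)
    de_call <- call_de(de_res, alpha = alpha_de)
    de_all <- c(de_call$up_in_fat, de_call$down_in_fat)
    del_genes <- intersect(de_all, linc_genes)
    de_coding <- intersect(de_all, coding_genes)
    utils::write.table(de_res, file.path(resdir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$de <- list(
      n_tested = nrow(de_res),
      n_excluded = length(attr(de_res, "excluded")),
      lincrna = list(up = length(intersect(de_call$up_in_fat, linc_genes)),
                     down = length(intersect(de_call$down_in_fat, linc_genes)),
                     del_genes = del_genes),
      coding = list(up = length(intersect(de_call$up_in_fat, coding_genes)),
                    down = length(intersect(de_call$down_in_fat, coding_genes)),
                    de_genes = de_coding)
    )
  }

  gl <- gene_loci(assembly)
  if ("targets" %in% stages && length(del_genes) > 0) {
    gene_len <- tapply(assembly$transcripts$length,
                       assembly$transcripts$gene_id, max)
    fpkm_gene <- compute_fpkm(
      counts, stats::setNames(as.numeric(gene_len), names(gene_len)))
    keep_var <- apply(fpkm_gene, 1, stats::sd) > 0
    del_use <- del_genes[keep_var[del_genes]]
    cod_use <- coding_genes[keep_var[coding_genes]]
    neighbors <- find_neighbors(gl[gl$gene_id %in% del_use, , drop = FALSE],
                                gl[gl$gene_id %in% cod_use, , drop = FALSE],
                                window = window_bp)
    edges <- predict_targets(fpkm_gene[del_use, , drop = FALSE],
                             fpkm_gene[cod_use, , drop = FALSE],
                             de_coding, alpha = alpha_ptg,
                             neighbors = neighbors)
    net <- build_network(edges, restrict = "deptg_only")
    utils::write.table(edges, file.path(resdir, "target_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, file.path(resdir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$targets <- list(
      n_pairs_tested = nrow(edges),
      n_ptg = sum(edges$is_ptg),
      n_deptg = sum(edges$is_deptg),
      n_neighbor_pairs = nrow(neighbors),
      network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges))
    )
  }

  if ("qtl" %in% stages && length(del_genes) > 0) {
    del_loci <- gl[gl$gene_id %in% del_genes, , drop = FALSE]
    hits <- map_to_qtls(del_loci, qtls)
    qs <- summarize_hits(hits, qtls)
    utils::write.table(hits, file.path(resdir, "qtl_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$qtl <- list(n_hits = qs$n_hits, n_qtls_hit = qs$n_qtls_hit,
                       n_fat_qtls_hit = qs$n_fat_qtls_hit,
                       n_dels_in_qtls = qs$n_lincrnas_hit,
                       per_lincrna = qs$per_lincrna)
  }

  jsonlite::write_json(report, file.path(resdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
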