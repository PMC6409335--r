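# Shared synthetic-study fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default study (the canonical recovery conditions: seed 1, 200 coding,
# 30 novel, 10 ORF decoys, 5 structural decoys, 5 homology decoys,
# 3 unexpressed decoys)
study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "adipolinc-study-fixture")
    truth <- generate_study(sim_config(), dir)
    samples <- read_samples(file.path(dir, "samples.tsv"))
    .fixture_env$study <- list(
      dir = dir, truth = truth,
      reference = read_gtf(file.path(dir, "reference.gtf"), "reference"),
      assembly = read_gtf(file.path(dir, "assembly.gtf"), "assembly"),
      seqs = read_fasta(file.path(dir, "transcripts.fa")),
      samples = samples,
      counts = read_counts(file.path(dir, "counts.tsv"), samples),
      qtls = read_qtl_bed(file.path(dir, "qtl.tsv")),
      evidence = read_homology_evidence(
        file.path(dir, "homology_evidence.tsv"))
    )
  }
  .fixture_env$study
}

# identification run on the default study, cached
ident_fixture <- function() {
  if (is.null(.fixture_env$ident)) {
    st <- study_fixture()
    fpkm <- transcript_fpkm(st$counts, st$assembly)
    .fixture_env$ident <- run_identification(
      st$assembly, st$reference, st$seqs, st$evidence, fpkm)
  }
  .fixture_env$ident
}

# a small, fast study configuration for determinism / end-to-end tests
small_config <- function(seed = 1) {
  sim_config(seed = seed, n_chroms = 3, chrom_length = 3e6,
             n_coding_genes = 40, n_known_lincrnas = 6,
             n_novel_intergenic = 8, n_decoy_orf = 3, n_decoy_structure = 2,
             n_decoy_homology = 2, n_decoy_unexpressed = 1,
             qtl_count = 10, n_de_lincrnas = 3)
}

two_group_factor <- function(nps = 10) {
  factor(rep(c("fat", "lean"), each = nps), levels = c("lean", "fat"))
}
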