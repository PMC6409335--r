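test_that("the generator is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  generate_study(small_config(), d1)
  generate_study(small_config(), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("planted intergenic transcripts never overlap the reference (brute force)", {
  st <- study_fixture()
  planted <- c(st$truth$true_lincrna_ids,
               unlist(st$truth$true_decoy_ids, use.names = FALSE))
  ptx <- st$assembly$transcripts
  ptx <- ptx[ptx$transcript_id %in% planted, ]
  rtx <- st$reference$transcripts
  hits <- brute_overlap_sets(ptx, rtx)
  expect_true(all(lengths(hits) == 0))
})

test_that("a different seed changes the data but not the ground-truth set sizes", {
  d3 <- file.path(tempdir(), "seed3")
  t1 <- generate_study(small_config(seed = 1), file.path(tempdir(), "seed1b"))
  t3 <- generate_study(small_config(seed = 3), d3)
  expect_equal(length(t3$true_lincrna_ids), length(t1$true_lincrna_ids))
  expect_equal(lengths(t3$true_decoy_ids), lengths(t1$true_decoy_ids))
  expect_false(identical(
    read_counts(file.path(d3, "counts.tsv")),
    read_counts(file.path(tempdir(), "seed1b", "counts.tsv"))))
})

test_that("planted fold changes are recovered in the empirical group-mean ratios", {
  st <- study_fixture()
  truth_de <- st$truth$true_de_genes
  grp <- st$samples$group[match(colnames(st$counts), st$samples$sample_id)]
  m_fat <- rowMeans(st$counts[truth_de$gene_id, grp == "fat", drop = FALSE])
  m_lean <- rowMeans(st$counts[truth_de$gene_id, grp == "lean", drop = FALSE])
  emp <- log2((m_fat + 0.5) / (m_lean + 0.5))
  expect_true(all(sign(emp) == sign(truth_de$log2fc)))
  expect_lt(median(abs(emp - truth_de$log2fc)), 0.5)
})

test_that("noncoding transcripts are built below the coding-potential boundary and decoys above it", {
  st <- study_fixture()
  linc_ids <- c(st$truth$true_lincrna_ids, st$truth$true_known_lincrna_ids)
  cp <- coding_potential_score(orf_table(st$seqs[linc_ids]))
  expect_true(all(cp$label == "noncoding"))
  orf_decoys <- st$truth$true_decoy_ids$coding_potential
  cp_decoy <- coding_potential_score(orf_table(st$seqs[orf_decoys]))
  expect_true(all(cp_decoy$label == "coding"))
  orfs <- orf_table(st$seqs[linc_ids])
  expect_true(all(orfs$longest_orf_nt < 300))
})

test_that("null count generator has the documented shape and exclusion behavior", {
  cfg <- sim_config(seed = 7)
  m <- generate_null_counts(2000, cfg)
  expect_identical(dim(m), c(2000L, 20L))
  res <- nb_wald_test(m, estimate_size_factors(m), two_group_factor())
  expect_lt(nrow(res), 2000)
  expect_equal(nrow(res) + length(attr(res, "excluded")), 2000)
})

test_that("infeasible placement is reported as a configuration error", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 60000, n_coding_genes = 100)
  expect_error(generate_study(cfg, file.path(tempdir(), "never")),
               "infeasible")
})

test_that("a study without planted novel transcripts yields zero novel lincRNAs", {
  cfg <- sim_config(seed = 2, n_chroms = 2, chrom_length = 2e6,
                    n_coding_genes = 30, n_known_lincrnas = 4,
                    n_novel_intergenic = 0, n_decoy_orf = 2,
                    n_decoy_structure = 2, n_decoy_homology = 1,
                    n_decoy_unexpressed = 1, qtl_count = 5,
                    n_de_lincrnas = 2)
  dir <- file.path(tempdir(), "nonovel")
  generate_study(cfg, dir)
  samples <- read_samples(file.path(dir, "samples.tsv"))
  counts <- read_counts(file.path(dir, "counts.tsv"), samples)
  assembly <- read_gtf(file.path(dir, "assembly.gtf"), "assembly")
  out <- run_identification(
    assembly, read_gtf(file.path(dir, "reference.gtf"), "reference"),
    read_fasta(file.path(dir, "transcripts.fa")),
    read_homology_evidence(file.path(dir, "homology_evidence.tsv")),
    transcript_fpkm(counts, assembly))
  expect_equal(sum(out$lincrna$status == "novel"), 0)
})
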