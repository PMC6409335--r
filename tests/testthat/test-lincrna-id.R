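test_that("structural filter applies inclusive length and exon-count boundaries", {
  ts <- make_ts(
    list("len200", "g1", "chr1", 0, 100, "+"),
    list("len200", "g1", "chr1", 200, 300, "+"),   # 200 bp, 2 exons
    list("len199", "g2", "chr2", 0, 99, "+"),
    list("len199", "g2", "chr2", 200, 300, "+"),   # 199 bp, 2 exons
    list("mono", "g3", "chr3", 0, 5000, "+")       # 5000 bp, 1 exon
  )
  expect_equal(filter_structure(ts), "len200")
  expect_setequal(filter_structure(ts, min_length = 150), c("len200", "len199"))
  expect_setequal(filter_structure(ts, min_length = 100, min_exons = 1),
                  c("len200", "len199", "mono"))
})

test_that("six-frame translation follows the standard code", {
  expect_equal(unname(six_frame_translate("ATG")["+1"]), "M")
  expect_equal(unname(six_frame_translate("ATGTTTTAA")["+1"]), "MF*")
  # reverse-complement frames: revcomp of CAT is ATG
  expect_equal(unname(six_frame_translate("CAT")["-1"]), "M")
  # codons containing N become X; trailing bases are dropped
  expect_equal(unname(six_frame_translate("ATNAAAG")["+1"]), "XK")
  expect_error(six_frame_translate("ATGR"), "outside")
})

test_that("six-frame translation matches a hand-rolled codon-table oracle", {
  set.seed(12)
  for (k in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    expect_equal(six_frame_translate(s), oracle_six_frames(s))
  }
  # with N characters
  s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                    prob = c(rep(0.23, 4), 0.08)), collapse = "")
  expect_equal(six_frame_translate(s), oracle_six_frames(s))
})

test_that("longest-ORF finder handles canonical cases", {
  o <- find_longest_orf("ATGAAATAA")
  expect_equal(o$longest_orf_nt, 9L)
  expect_equal(o$orf_frame, "+1")
  expect_equal(o$orf_coverage, 1)
  o2 <- find_longest_orf("CCCCCCCCC")
  expect_equal(o2$longest_orf_nt, 0L)
  expect_equal(o2$orf_frame, "none")
  # ATG without a downstream in-frame stop is not a complete ORF
  expect_equal(find_longest_orf("ATGAAAAAA")$longest_orf_nt, 0L)
})

test_that("longest-ORF finder equals the exhaustive frame/start/stop scan", {
  set.seed(33)
  for (k in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    got <- find_longest_orf(s)
    want <- brute_longest_orf(s)
    expect_equal(got$longest_orf_nt, want$longest_orf_nt)
    expect_equal(got$orf_frame, want$orf_frame)
  }
})

test_that("coding-potential score follows the two-term formula", {
  orfs <- data.frame(transcript_id = c("a", "b", "c"),
                     longest_orf_nt = c(600, 90, 0),
                     orf_coverage = c(0.60, 0.10, 0))
  cp <- coding_potential_score(orfs)
  expect_equal(cp$score, c(1.25, -0.95, -1.35))
  expect_equal(cp$label, c("coding", "noncoding", "noncoding"))
  # externally supplied score column overrides the formula
  orfs$score <- c(-1, 2, 0)
  cp2 <- coding_potential_score(orfs)
  expect_equal(cp2$label, c("noncoding", "coding", "coding"))
})

test_that("homology filter discards on any sub-threshold hit and keeps the rest", {
  ev <- data.frame(transcript_id = c("t1", "t2", "t2"),
                   source = c("pfam", "nr", "uniref90"),
                   evalue = c(1e-6, 1e-4, 2e-5))
  expect_equal(filter_homology(c("t1", "t2", "t3"), ev), c("t2", "t3"))
  expect_equal(filter_homology(c("t1", "t2"), NULL), c("t1", "t2"))
  ev$evalue[1] <- -1
  expect_error(filter_homology("t1", ev), "negative")
})

test_that("expression filter retains any transcript expressed in at least one sample", {
  fpkm <- rbind(allzero = rep(0, 20),
                faint = c(0.01, rep(0, 19)),
                strong = runif(20, 1, 5))
  expect_setequal(filter_expression(rownames(fpkm), fpkm),
                  c("faint", "strong"))
  expect_error(filter_expression("ghost", fpkm), "missing")
})

test_that("identification cascade is monotone and order-insensitive in its final set", {
  st <- study_fixture()
  id <- ident_fixture()
  expect_true(all(id$report$n_out <= id$report$n_in))
  surv <- attr(id$report, "survivors")
  for (i in 2:length(surv)) {
    expect_true(all(surv[[i]] %in% surv[[i - 1]]))
  }
  # applying the four post-classification predicates in a different order
  # changes per-stage counts but not the final survivor set
  fpkm <- transcript_fpkm(st$counts, st$assembly)
  base <- surv$intergenic
  alt <- filter_expression(base, fpkm)
  alt <- filter_homology(alt, st$evidence)
  alt <- intersect(alt, filter_structure(st$assembly))
  alt <- filter_coding_potential(alt, st$seqs)
  expect_setequal(alt, surv$expression)
})

test_that("identification recovers planted lincRNAs and labels known vs novel", {
  st <- study_fixture()
  id <- ident_fixture()
  novel <- id$lincrna$transcript_id[id$lincrna$status == "novel"]
  known <- id$lincrna$transcript_id[id$lincrna$status == "known"]
  expect_setequal(novel, st$truth$true_lincrna_ids)
  expect_setequal(known, st$truth$true_known_lincrna_ids)
})

test_that("empty assembly yields an empty result with an all-zero report", {
  empty <- transcript_set(data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    start = numeric(), end = numeric(), strand = character()))
  st <- study_fixture()
  out <- run_identification(empty, st$reference, st$seqs, st$evidence,
                            transcript_fpkm(st$counts, st$assembly))
  expect_equal(nrow(out$lincrna), 0)
  expect_true(all(out$report$n_in == 0) && all(out$report$n_out == 0))
})
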