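test_that("span index answers trivial overlap queries", {
  empty <- transcript_set(data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    start = numeric(), end = numeric(), strand = character()))
  idx <- build_span_index(empty)
  expect_equal(query_index(idx, "chr1", 0, 100), list(integer(0)))

  ref <- make_ts(list("r1", "g1", "chr1", 1000, 2000, "+"))
  idx <- build_span_index(ref)
  expect_length(query_index(idx, "chr1", 1500, 1600)[[1]], 1)
  expect_length(query_index(idx, "chr1", 2000, 2100)[[1]], 0)  # touching
  expect_length(query_index(idx, "chr2", 1500, 1600)[[1]], 0)
})

test_that("classification separates intergenic from reference-overlapping transcripts", {
  ref <- make_ts(list("r1", "g1", "chr1", 1000, 2000, "+"),
                 biotype = "protein_coding")
  asm <- make_ts(
    list("u1", "gu1", "chr1", 3000, 3200, "-"),
    list("u1", "gu1", "chr1", 3500, 3700, "-"),
    list("o1", "go1", "chr1", 1500, 2500, "+")
  )
  cls <- classify_transcripts(asm, ref)
  u1 <- cls[cls$transcript_id == "u1", ]
  expect_equal(u1$class_label, "intergenic_u")
  expect_equal(u1$nearest_reference_gap, 1000)
  expect_equal(cls$class_label[cls$transcript_id == "o1"],
               "overlapping_reference")

  # chromosome absent from the reference: intergenic with infinite gap
  asm2 <- make_ts(list("u2", "gu2", "chrX", 10, 500, "+"))
  cls2 <- classify_transcripts(asm2, ref)
  expect_equal(cls2$class_label, "intergenic_u")
  expect_equal(cls2$nearest_reference_gap, Inf)
})

test_that("classification is span-level, strand-agnostic and exon-order invariant", {
  ref <- make_ts(list("r1", "g1", "chr1", 1000, 2000, "+"))
  plus <- make_ts(list("q", "gq", "chr1", 1500, 1600, "+"))
  minus <- make_ts(list("q", "gq", "chr1", 1500, 1600, "-"))
  expect_equal(classify_transcripts(plus, ref)$class_label,
               classify_transcripts(minus, ref)$class_label)
  # intronic query (between exons, inside the span) is NOT intergenic
  ref2 <- make_ts(list("r2", "g2", "chr1", 1000, 1100, "+"),
                  list("r2", "g2", "chr1", 1900, 2000, "+"))
  intronic <- make_ts(list("q", "gq", "chr1", 1400, 1500, "+"))
  expect_equal(classify_transcripts(intronic, ref2)$class_label,
               "overlapping_reference")
})

test_that("index and classification agree with brute force on random fixtures", {
  subjects <- random_intervals(500, seed = 101)
  queries <- random_intervals(500, seed = 202)
  ref <- transcript_set(data.frame(
    transcript_id = subjects$gene_id, gene_id = subjects$gene_id,
    chrom = subjects$chrom, start = subjects$start, end = subjects$end,
    strand = "+", stringsAsFactors = FALSE))
  idx <- build_span_index(ref)
  got <- query_index(idx, queries$chrom, queries$start, queries$end)
  ref_tx <- ref$transcripts  # constructor may reorder; map back to input rows
  want <- brute_overlap_sets(queries, ref_tx[, c("chrom", "start", "end")])
  expect_equal(lapply(got, sort), lapply(want, sort))

  asm <- transcript_set(data.frame(
    transcript_id = queries$gene_id, gene_id = queries$gene_id,
    chrom = queries$chrom, start = queries$start, end = queries$end,
    strand = "+", stringsAsFactors = FALSE))
  cls <- classify_transcripts(asm, ref)
  cls <- cls[match(queries$gene_id, cls$transcript_id), ]
  expect_equal(cls$class_label == "intergenic_u", lengths(want) == 0)
  expect_equal(sum(cls$class_label == "intergenic_u") +
                 sum(cls$class_label == "overlapping_reference"),
               nrow(queries))
})

test_that("classification on the synthetic study recovers planted intergenic transcripts", {
  st <- study_fixture()
  cls <- classify_transcripts(st$assembly, st$reference)
  intergenic <- cls$transcript_id[cls$class_label == "intergenic_u"]
  planted <- c(st$truth$true_lincrna_ids,
               unlist(st$truth$true_decoy_ids, use.names = FALSE))
  expect_setequal(intergenic, planted)
})
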