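test_that("neighbor search applies the <100 kb gap rule", {
  linc <- data.frame(gene_id = "L1", chrom = "chr1",
                     start = 200000, end = 201000)
  coding <- data.frame(
    gene_id = c("near", "far", "overlap", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(150000, 350000, 200500, 200000),
    end = c(160000, 360000, 202000, 201000))
  nb <- find_neighbors(linc, coding)
  expect_setequal(nb$coding_gene, c("near", "overlap"))
  expect_equal(nb$gap[nb$coding_gene == "near"], 40000)
  expect_equal(nb$gap[nb$coding_gene == "overlap"], 0)
  # 149 kb separation is not a neighbor at the default window
  expect_false("far" %in% nb$coding_gene)
  expect_equal(nrow(find_neighbors(linc, coding, window = 150000)), 3)
})

test_that("neighbor search equals brute-force gap computation on random loci", {
  linc <- random_intervals(50, seed = 55)
  coding <- random_intervals(200, seed = 66)
  got <- find_neighbors(linc, coding)
  got_keys <- sort(paste(got$lincrna_gene, got$coding_gene))
  want <- NULL
  for (i in seq_len(nrow(linc))) {
    for (j in seq_len(nrow(coding))) {
      if (linc$chrom[i] != coding$chrom[j]) next
      gap <- brute_gap(linc$start[i], linc$end[i],
                       coding$start[j], coding$end[j])
      if (gap < 100000) {
        want <- c(want, paste(linc$gene_id[i], coding$gene_id[j]))
      }
    }
  }
  expect_equal(got_keys, sort(want))
  # and the reported gaps agree
  for (k in seq_len(nrow(got))) {
    i <- match(got$lincrna_gene[k], linc$gene_id)
    j <- match(got$coding_gene[k], coding$gene_id)
    expect_equal(got$gap[k], brute_gap(linc$start[i], linc$end[i],
                                       coding$start[j], coding$end[j]))
  }
})

test_that("Pearson helpers match closed forms and cor.test", {
  x <- c(1, 2, 3, 4, 5, 7, 11, 13)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 8), id = "flat"), "zero variance")

  set.seed(77)
  for (k in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20) + 0.5 * a
    r <- pearson_r(a, b)
    ct <- cor.test(a, b)
    expect_equal(r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pearson_pvalue(r, 20), ct$p.value, tolerance = 1e-12)
  }
  expect_equal(pearson_pvalue(0, 20), 1)
  expect_equal(pearson_pvalue(1, 20), 0)
})

test_that("correlation p-value is sign-symmetric and decreasing in |r|", {
  rs <- seq(0.05, 0.95, by = 0.05)
  p_pos <- pearson_pvalue(rs, 20)
  p_neg <- pearson_pvalue(-rs, 20)
  expect_equal(p_pos, p_neg)
  expect_true(all(diff(p_pos) < 0))
})

test_that("target prediction flags PTG and DEPTG per definition", {
  set.seed(88)
  n <- 20
  latent <- rnorm(n)
  lexpr <- rbind(L1 = 2 + latent + rnorm(n, sd = 0.4),
                 L2 = rnorm(n))
  cexpr <- rbind(C1 = 5 + latent + rnorm(n, sd = 0.4),   # correlated with L1
                 C2 = rnorm(n),
                 C3 = 1 + latent + rnorm(n, sd = 0.4))
  colnames(lexpr) <- colnames(cexpr) <- paste0("s", 1:n)
  edges <- predict_targets(lexpr, cexpr, de_coding_ids = "C1")
  e <- function(l, c) edges[edges$lincrna_gene == l & edges$coding_gene == c, ]
  expect_true(e("L1", "C1")$is_ptg)
  expect_true(e("L1", "C1")$is_deptg)
  expect_true(e("L1", "C3")$is_ptg)
  expect_false(e("L1", "C3")$is_deptg)   # significant but not DE
  expect_equal(e("L1", "C1")$sign, "positive")
  # flags reproduce the raw threshold rule exactly
  expect_equal(edges$is_ptg, edges$p < 0.05)
  expect_error(predict_targets(lexpr, cexpr[, rev(colnames(cexpr))], "C1"),
               "do not match")
})

test_that("planted correlated lincRNA-coding pairs are recovered as PTGs", {
  st <- study_fixture()
  id <- ident_fixture()
  pairs <- st$truth$true_correlated_pairs
  gene_len <- tapply(st$assembly$transcripts$length,
                     st$assembly$transcripts$gene_id, max)
  fpkm <- compute_fpkm(st$counts,
                       setNames(as.numeric(gene_len), names(gene_len)))
  lgenes <- unique(pairs$lincrna_gene)
  cgenes <- unique(pairs$coding_gene)
  edges <- predict_targets(fpkm[lgenes, , drop = FALSE],
                           fpkm[cgenes, , drop = FALSE],
                           de_coding_ids = character(0))
  key <- paste(edges$lincrna_gene, edges$coding_gene)
  planted <- paste(pairs$lincrna_gene, pairs$coding_gene)
  sens <- mean(edges$is_ptg[match(planted, key)])
  expect_gte(sens, 0.9)
})

test_that("network export counts nodes and edges as a bipartite graph", {
  expect_equal(build_network(data.frame(
    lincrna_gene = character(), coding_gene = character(), r = numeric(),
    p = numeric(), sign = character(), is_ptg = logical(),
    is_deptg = logical()))$edges |> nrow(), 0)
  edges <- expand.grid(lincrna_gene = c("L1", "L2"),
                       coding_gene = c("C1", "C2", "C3"),
                       stringsAsFactors = FALSE)
  edges$r <- 0.9
  edges$p <- 0.001
  edges$n <- 20
  edges$is_neighbor <- TRUE
  edges$is_ptg <- TRUE
  edges$is_deptg <- TRUE
  edges$sign <- "positive"
  net <- build_network(edges)
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 6)
  # degree of each coding node equals the number of passing DEL edges
  deg <- table(net$edges$coding_gene)
  expect_true(all(deg == 2))
})
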