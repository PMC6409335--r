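test_that("median-of-ratios size factors match closed forms", {
  set.seed(3)
  base <- rpois(50, 100) + 1L
  m <- cbind(s1 = base, s2 = 2L * base)
  rownames(m) <- paste0("g", 1:50)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  m2 <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m2) <- rownames(m)
  expect_equal(unname(estimate_size_factors(m2)), rep(1, 3))
  # geometric mean is always 1
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors are scale-equivariant and recover planted depths within 5%", {
  set.seed(31)
  depths <- exp(runif(20, -0.5, 0.5))
  depths <- depths / exp(mean(log(depths)))
  mu <- exp(runif(2000, log(5), log(5000)))
  m <- t(vapply(mu, function(mi) rnbinom(20, mu = mi * depths, size = 20),
                numeric(20)))
  dimnames(m) <- list(paste0("g", 1:2000), paste0("s", 1:20))
  sf <- estimate_size_factors(m)
  expect_lt(max(abs(sf / depths - 1)), 0.05)
  # multiplying one column by c multiplies its factor by c (pre-centering)
  m3 <- m
  m3[, 5] <- m3[, 5] * 3
  sf3 <- estimate_size_factors(m3)
  ratio <- sf3 / sf   # constant except for the scaled column
  expect_equal(unname(ratio[5] / ratio[1]), 3, tolerance = 1e-12)
  expect_equal(unname(ratio[2] / ratio[1]), 1, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 median-of-ratios implementation", {
  set.seed(5)
  m <- matrix(rnbinom(500 * 20, mu = 300, size = 20), nrow = 500,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
  m[, 1:5] <- m[, 1:5] * 2L
  d <- DESeq2::estimateSizeFactorsForMatrix(m)
  d <- d / exp(mean(log(d)))
  expect_equal(unname(estimate_size_factors(m)), unname(d),
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.001, 0.5, 0.04)), c(0.003, 0.5, 0.06))
  p <- runif(100)
  adj <- bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Wald engine excludes all-zero genes and respects direction thresholds", {
  set.seed(8)
  m <- rbind(matrix(rnbinom(50 * 20, mu = 100, size = 20), nrow = 50),
             zeros = rep(0L, 20))
  rownames(m) <- c(paste0("g", 1:50), "allzero")
  colnames(m) <- paste0("s", 1:20)
  res <- nb_wald_test(m, estimate_size_factors(m), two_group_factor())
  expect_false("allzero" %in% res$gene_id)
  expect_equal(attr(res, "excluded"), "allzero")
  expect_true(all(res$padj >= res$p))
  calls <- call_de(data.frame(gene_id = c("a", "b", "c"),
                              log2fc = c(1.2, -0.8, 2),
                              padj = c(0.049, 0.049, 0.051)))
  expect_equal(calls$up_in_fat, "a")
  expect_equal(calls$down_in_fat, "b")
  expect_equal(calls$ns, "c")
  expect_error(nb_wald_test(m, estimate_size_factors(m),
                            factor(c(rep("fat", 19), "lean"),
                                   levels = c("lean", "fat"))),
               "at least 2")
})

test_that("swapping group labels negates fold changes and preserves p-values", {
  set.seed(9)
  m <- matrix(rnbinom(200 * 20, mu = 150, size = 20), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
  sf <- estimate_size_factors(m)
  g1 <- two_group_factor()
  g2 <- factor(ifelse(g1 == "fat", "lean", "fat"), levels = c("lean", "fat"))
  r1 <- nb_wald_test(m, sf, g1)
  r2 <- nb_wald_test(m, sf, g2)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("p-values are uniform under the null at large counts", {
  set.seed(5)
  m <- matrix(rnbinom(2000 * 20, mu = 1000, size = 20), nrow = 2000,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:20)))
  res <- nb_wald_test(m, estimate_size_factors(m), two_group_factor())
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("planted 4-fold changes at mean 500 are recovered within 0.25 log2 units", {
  cal <- generate_calibration_counts(4000, sim_config(seed = 1),
                                     de_fraction = 0.5)
  res <- nb_wald_test(cal$counts, estimate_size_factors(cal$counts),
                      two_group_factor())
  lfc <- res$log2fc[match(cal$de_gene_ids, res$gene_id)]
  expect_gte(mean(abs(abs(lfc) - 2) <= 0.25), 0.9)
  expect_true(all(sign(lfc) == sign(cal$log2fc)))
})
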