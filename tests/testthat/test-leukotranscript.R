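# strip class and method attribute so factors compare as plain named vectors
sf <- function(x) {
  x <- unclass(x)
  attr(x, "method") <- NULL
  x
}

test_that("median-of-ratios factors satisfy their defining identities", {
  m <- matrix(c(10, 50, 100, 10, 50, 100), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  expect_equal(sf(size_factors_mor(m)), c(a = 1, b = 1))
  m2 <- matrix(c(2, 8, 4, 16), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  # geomeans are sqrt(8) and sqrt(128); ratios are (1/sqrt2, sqrt2) per column
  s <- sf(size_factors_mor(m2))
  expect_equal(s, c(a = 1 / sqrt(2), b = sqrt(2)))
  # exact scaling equivariance: tripling one library triples its factor ratio
  cnt <- toy_counts(seed = 2)
  cnt3 <- cnt
  cnt3[, 4] <- cnt[, 4] * 3
  s1 <- sf(size_factors_mor(cnt))
  s3 <- sf(size_factors_mor(cnt3))
  expect_equal(s3[4] / s3[1], 3 * s1[4] / s1[1], tolerance = 1e-12)
  allzero <- matrix(c(0, 5, 0, 7), nrow = 2,
                    dimnames = list(c("g1", "g2"), c("a", "b")))
  allzero[2, 1] <- 0
  expect_error(size_factors_mor(allzero), "reference")
})

test_that("median-of-ratios agrees with DESeq2 when available", {
  skip_if_not_installed("DESeq2")
  cnt <- toy_counts(seed = 3, G = 200, S = 8)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  # with an even reference-gene count DESeq2 averages the two middle ratios
  # on the log scale, ours on the linear scale: agreement is ~1e-5, not exact
  expect_equal(sf(size_factors_mor(cnt)), ref, tolerance = 1e-3)
})

test_that("TMM factors are unit for identical libraries and scale-invariant", {
  m <- matrix(rep(c(5, 80, 300, 12), 3), ncol = 3,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:3)))
  expect_equal(sf(tmm_factors(m)), c(s1 = 1, s2 = 1, s3 = 1))
  # a pure library-size change is absorbed by the offset, not the factor
  cnt <- toy_counts(seed = 4, G = 300, S = 4)
  cnt4 <- cnt
  cnt4[, 2] <- cnt[, 2] * 4L
  f <- sf(tmm_factors(cnt4))
  f0 <- sf(tmm_factors(cnt))
  expect_equal(f, f0, tolerance = 0.02)
  # normalization property: factors have geometric mean one
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # column permutation permutes the factors
  perm <- c(3, 1, 4, 2)
  fp <- sf(tmm_factors(cnt[, perm]))
  expect_equal(fp, f0[perm], tolerance = 1e-12)
})

test_that("TMM agrees with edgeR when available", {
  skip_if_not_installed("edgeR")
  cnt <- toy_counts(seed = 5, G = 400, S = 8)
  ref <- edgeR::calcNormFactors(cnt, method = "TMM")
  ref <- ref / exp(mean(log(ref)))
  expect_equal(sf(tmm_factors(cnt)), stats::setNames(ref, colnames(cnt)),
               tolerance = 5e-3)
})

test_that("upper-quartile factors are quartile ratios", {
  m <- matrix(c(rep(50, 9), 0, rep(200, 9), 0), ncol = 2,
              dimnames = list(sprintf("g%02d", 1:10), c("a", "b")))
  # positive counts are constant per column: quartiles 50 and 200, geomean 100
  expect_equal(sf(upperquartile_factors(m)), c(a = 0.5, b = 2))
  cnt <- toy_counts(seed = 6)
  u <- apply(cnt, 2, function(y) unname(stats::quantile(y[y > 0], 0.75, type = 7)))
  expect_equal(sf(upperquartile_factors(cnt)), u / exp(mean(log(u))),
               tolerance = 1e-12)
})

test_that("normalize_counts divides by factors and optionally logs", {
  cnt <- toy_counts(seed = 7, G = 20, S = 3)
  s <- stats::setNames(c(0.5, 1, 2), colnames(cnt))
  norm <- normalize_counts(cnt, s)
  expect_equal(norm[, 1], cnt[, 1] / 0.5)
  expect_equal(norm[, 3], cnt[, 3] / 2)
  expect_equal(normalize_counts(cnt, s, log2 = TRUE), log2(norm + 1))
  expect_error(normalize_counts(cnt, c(a = 1, b = 1)), "sample")
})

test_that("UPGMA reproduces hand-computed merge heights", {
  # two points: single merge at their distance
  m2 <- matrix(c(0, 3), nrow = 1, dimnames = list("g", c("a", "b")))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$height, 3)
  # three points at 0, 1, 10: merges at 1 then mean(|10-0|,|10-1|) = 9.5
  m3 <- matrix(c(0, 1, 10), nrow = 1, dimnames = list("g", c("a", "b", "c")))
  hc3 <- hierarchical_cluster(m3)
  expect_equal(hc3$height, c(1, 9.5))
  expect_s3_class(hc3, "hclust")
  expect_equal(hc3$labels, c("a", "b", "c"))
})

test_that("UPGMA matches the exhaustive recomputation oracle", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    G <- sample(2:6, 1)
    mat <- matrix(stats::rnorm(G * n), nrow = G,
                  dimnames = list(NULL, sprintf("s%d", seq_len(n))))
    if (i > 8) mat <- matrix(sample(0:2, G * n, TRUE), nrow = G,
                             dimnames = dimnames(mat))  # force distance ties
    hc <- hierarchical_cluster(mat)
    D <- as.matrix(stats::dist(t(mat)))
    oracle <- upgma_bruteforce(D)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_identical(hclust_merge_sets(hc), oracle$merges)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("UPGMA agrees with stats::hclust average linkage", {
  set.seed(29)
  mat <- matrix(stats::rnorm(80), nrow = 8,
                dimnames = list(NULL, sprintf("s%d", 1:10)))
  hc <- hierarchical_cluster(mat)
  ref <- stats::hclust(stats::dist(t(mat)), method = "average")
  expect_equal(sort(hc$height), sort(ref$height), tolerance = 1e-9)
  expect_equal(stats::cophenetic(hc), stats::cophenetic(ref), tolerance = 1e-9)
})

test_that("Newick export round-trips through ape with correct cophenetics", {
  m3 <- matrix(c(0, 1, 10), nrow = 1, dimnames = list("g", c("a", "b", "c")))
  hc3 <- hierarchical_cluster(m3)
  nwk <- dendrogram_newick(hc3)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(grepl("a:1", nwk) && grepl("c:9.5", nwk))
  skip_if_not_installed("ape")
  set.seed(31)
  mat <- matrix(stats::rnorm(60), nrow = 6,
                dimnames = list(NULL, sprintf("s%d", 1:10)))
  hc <- hierarchical_cluster(mat)
  tr <- ape::read.tree(text = dendrogram_newick(hc, digits = 10))
  cd <- ape::cophenetic.phylo(tr)
  ch <- as.matrix(stats::cophenetic(hc))
  # ultrametric: tip-to-tip path length is twice the merge height
  expect_equal(cd[rownames(ch), colnames(ch)], 2 * ch, tolerance = 1e-6)
})

test_that("NB likelihood-ratio engine honours its edge-case conventions", {
  cnt <- toy_counts(seed = 8, G = 40, S = 8)
  cnt["g005", ] <- 0L
  meta <- data.frame(sample_id = colnames(cnt),
                     group = rep(c("IVP-Normal", "IVP-LOS"), each = 4),
                     extreme = rep(c(FALSE, TRUE), each = 4),
                     stringsAsFactors = FALSE)
  tb <- nb_lrt(cnt, meta, ~extreme, ~1, backend = "B")
  z <- tb[tb$gene == "g005", ]
  expect_equal(z$p, 1)
  expect_equal(z$log2FC, 0)
  expect_equal(z$status, "untestable")
  ok <- tb$status == "ok"
  expect_true(all(tb$lrt_stat[ok] >= 0))
  expect_true(all(tb$df[ok] == 1))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  expect_equal(tb$adj_p, bh_hand(tb$p), tolerance = 1e-12)
  # reduced model must nest in the full model
  meta$batch <- rep(c("x", "y"), 4)
  expect_error(nb_lrt(cnt, meta, ~extreme, ~batch, backend = "B"), "nested")
})

test_that("planted differential genes dominate the NB-LRT ranking on both backends", {
  cfg <- sim_config(seed = 41, n_genes = 250, n_de_genes = 12, n_stable_genes = 0,
                    de_log2fc = 3, dam_effect_sd = 0)
  coh <- simulate_cohort(cfg, day = 105)
  meta <- sample_meta_from_cohort(coh$fetuses, n_dams = 23)
  sc <- simulate_counts(cfg, meta)
  de <- names(which(sc$truth$de))
  for (bk in c("A", "B")) {
    tb <- nb_lrt(sc$counts, meta, ~extreme, ~1, backend = bk)
    top <- tb$gene[order(tb$p)][seq_along(de)]
    expect_gte(length(intersect(top, de)), length(de) - 2)
    # estimated log2 fold changes point the planted way
    expect_gt(median(tb$log2FC[tb$gene %in% de] * sign(sc$truth$log2fc[de])), 1.5)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(43)
  for (i in 1:10) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_hand(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-15)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "p")
})

test_that("consensus is the intersection of per-backend discoveries", {
  mk <- function(genes, adj) data.frame(gene = genes, adj_p = adj,
                                        stringsAsFactors = FALSE)
  a <- mk(c("g1", "g2", "g3", "g4"), c(0.01, 0.20, 0.03, 0.80))
  b <- mk(c("g1", "g2", "g3", "g4"), c(0.04, 0.01, 0.30, 0.90))
  res <- consensus_genes(a, b, alpha = 0.05)
  expect_identical(res$consensus, "g1")
  expect_identical(res$significant_a, c("g1", "g3"))
  expect_identical(res$significant_b, c("g1", "g2"))
  none <- consensus_genes(a, b, alpha = 0.001)
  expect_length(none$consensus, 0)
  expect_error(consensus_genes(a, mk("g9", 0.5), alpha = 0.05), "gene")
})

test_that("reference-gene selection enforces all three criteria", {
  genes <- sprintf("g%02d", 1:6)
  mk <- function(adj) data.frame(gene = genes, adj_p = adj, stringsAsFactors = FALSE)
  a <- mk(c(1, 1, 1, 0.5, 1, 1))      # g4 fails the FDR-one criterion in A
  b <- mk(c(0.9, 0.9, 0.9, 0.9, 0.5, 0.9))  # g5 fails the backend-B floor
  norm <- matrix(100, nrow = 6, ncol = 8, dimnames = list(genes, sprintf("s%d", 1:8)))
  norm["g06", ] <- c(80, 120, 80, 120, 80, 120, 80, 120)  # CV ~ 0.21 > 0.10
  sel <- select_reference_genes(a, b, norm)
  expect_identical(sort(unclass(sel)), c("g01", "g02", "g03"))
  crit <- attr(sel, "criteria")
  expect_equal(crit$reason[crit$gene == "g04"], "not null enough")
  expect_equal(crit$reason[crit$gene == "g05"], "not null enough")
  expect_equal(crit$reason[crit$gene == "g06"], "CV too high")
})
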