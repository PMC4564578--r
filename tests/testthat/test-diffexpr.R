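test_that("size factors match the hand-computed median-of-ratios example", {
  counts <- matrix(c(100, 400, 200, 800), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
})

test_that("size factors are 1 for identical columns and scale-equivariant", {
  set.seed(1)
  counts <- matrix(rpois(300, 50) + 1, ncol = 3)
  rownames(counts) <- paste0("g", 1:100)
  colnames(counts) <- paste0("s", 1:3)
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))

  sf <- estimate_size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 4
  sf2 <- estimate_size_factors(scaled)
  # ratios between samples respond to the scaling as c^(1 - 1/m) etc.;
  # the clean invariant is that the ratio of factors scales by c
  expect_equal(sf2[2] / sf2[1], 4 * sf[2] / sf[1], tolerance = 1e-10)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 1e-10)
})

test_that("size factors need at least one all-positive gene", {
  counts <- matrix(c(0, 5, 3, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(counts), "all-positive")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  cond <- factor(rep(c("A", "B"), each = 3))
  set.seed(7)
  pois <- matrix(rpois(2000 * 6, 1000), ncol = 6,
                 dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  dp <- estimate_dispersions(pois, rep(1, 6), cond)
  expect_lte(median(dp$dispersion), 0.01)

  nb <- matrix(rnbinom(2000 * 6, mu = 500, size = 10), ncol = 6,
               dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  dn <- estimate_dispersions(nb, rep(1, 6), cond)
  trend <- attr(dn, "trend")
  expect_gt(trend[["a0"]], 0.05)
  expect_lt(trend[["a0"]], 0.2)
})

test_that("identical replicates fall back to the fitted trend", {
  cond <- factor(c("A", "A", "B", "B"))
  base <- matrix(rep(c(10, 100, 1000, 50, 500), each = 4),
                 ncol = 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  d <- estimate_dispersions(base, rep(1, 4), cond)
  expect_true(all(d$disp_gene == 1e-8))
  expect_equal(d$dispersion, d$disp_fit)
})

test_that("all-zero genes are flagged with undefined dispersion", {
  cond <- factor(c("A", "A", "B", "B"))
  counts <- rbind(g1 = c(5, 6, 7, 8), g0 = c(0, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:4)
  d <- estimate_dispersions(counts, rep(1, 4), cond)
  expect_true(d["g0", "all_zero"])
  expect_true(is.na(d["g0", "dispersion"]))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  counts <- matrix(rnbinom(500 * 4, mu = 100, size = 5) + 1, ncol = 4,
                   dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  ours <- estimate_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("exact test reproduces the Poisson-limit binomial example", {
  # dispersion 0, unit size factors, observed split (0, 10):
  # conditional law is Binomial(10, 1/2), two-sided tail = 2/1024
  p <- nb_exact_test(0, 10, 1, 1, dispersion = 0)
  expect_equal(p, 2 / 1024, tolerance = 1e-12)
})

test_that("exact test is 1 at the modal split and symmetric under swap", {
  expect_equal(nb_exact_test(c(25, 25), c(25, 25), rep(1, 2), rep(1, 2),
                             dispersion = 0.1), 1)
  set.seed(5)
  for (i in 1:20) {
    kA <- rpois(2, 40); kB <- rpois(2, 60)
    sfA <- runif(2, 0.8, 1.2); sfB <- runif(2, 0.8, 1.2)
    a <- nb_exact_test(kA, kB, sfA, sfB, 0.05)
    b <- nb_exact_test(kB, kA, sfB, sfA, 0.05)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("exact test matches the enumeration oracle for totals <= 200", {
  set.seed(13)
  for (i in 1:60) {
    total <- sample(1:200, 1)
    KA <- sample(0:total, 1)
    kA <- c(KA)
    kB <- c(total - KA)
    alpha <- sample(c(0, 0.01, 0.1, 0.5), 1)
    sfA <- runif(1, 0.5, 2); sfB <- runif(1, 0.5, 2)
    expect_equal(nb_exact_test(kA, kB, sfA, sfB, alpha),
                 oracle_nb_exact(kA, kB, sfA, sfB, alpha),
                 tolerance = 1e-8)
  }
})

test_that("normal approximation agrees with enumeration near the switch", {
  set.seed(17)
  for (i in 1:10) {
    kA <- rpois(2, 150); kB <- rpois(2, 220)
    exact <- nb_exact_test(kA, kB, rep(1, 2), rep(1, 2), 0.05,
                           exact_threshold = 5000)
    approx <- nb_exact_test(kA, kB, rep(1, 2), rep(1, 2), 0.05,
                            exact_threshold = 1)
    expect_lt(abs(log10(approx) - log10(exact)), 0.35)
  }
})

test_that("zero-total genes get p = 1", {
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), rep(1, 2), rep(1, 2), 0.1), 1)
})

test_that("BH adjustment matches hand examples and the brute-force oracle", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(0.2, 7)), rep(0.2, 7))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:300) {
    p <- round(runif(sample(1:40, 1)), sample(1:4, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotonicity in p
  p <- runif(100)
  q <- adjust_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("the DE filter cascade applies its rules in order", {
  # gene low: baseMean < 5 in all samples -> low_expression
  # gene zer: 0 in condition A, expressed in B -> zero_in_condition
  # gene bnd: |log2FC| ~ 2 exactly -> not_de despite tiny padj
  # gene sig: strong, clean signal -> down
  counts <- rbind(
    low = c(4, 5, 5, 5),
    zer = c(0, 0, 50, 55),
    bnd = c(400, 400, 100, 100),
    sig = c(800, 820, 20, 22),
    ref1 = c(300, 310, 290, 305),
    ref2 = c(150, 160, 155, 148),
    ref3 = c(1000, 980, 1010, 1005))
  colnames(counts) <- c("A_1", "A_2", "B_1", "B_2")
  cm <- count_matrix(counts, factor(c("A", "A", "B", "B")))
  de <- run_de(cm)
  expect_equal(de$reason[de$gene == "low"], "low_expression")
  expect_equal(de$reason[de$gene == "zer"], "zero_in_condition")
  expect_true(is.na(de$pval[de$gene == "low"]))
  bnd <- de[de$gene == "bnd", ]
  expect_equal(bnd$log2FoldChange, -2, tolerance = 0.2)
  expect_equal(bnd$status, "not_de")
  expect_equal(de$status[de$gene == "sig"], "down")
  # BH was applied to survivors only
  expect_equal(sum(!is.na(de$padj)), sum(!de$filtered))
  expect_true(all(de$padj >= de$pval, na.rm = TRUE))
})

test_that("a strict fold-change boundary excludes |log2FC| == 2 exactly", {
  de <- data.frame(gene = c("a", "b"),
                   baseMean = c(100, 100), baseMeanA = c(100, 100),
                   baseMeanB = c(25, 24), log2FoldChange = c(-2, -2.06),
                   pval = c(1e-6, 1e-6), padj = c(1e-5, 1e-5),
                   filtered = FALSE, reason = NA, status = "not_de")
  sig <- !de$filtered & de$padj <= 0.01 & abs(de$log2FoldChange) > 2
  expect_equal(sig, c(FALSE, TRUE))
})

test_that("null data give a calibrated raw p-value rate", {
  cfg <- sim_config(n_genes = 2000, frac_down = 0, frac_up = 0, seed = 31,
                    n_decoy_tfs = 2, n_decoy_marks = 2,
                    n_decoy_pathways = 2)
  truth <- generate_truth(cfg)
  cm <- generate_counts(truth, cfg)
  de <- run_de(cm)
  frac <- mean(de$pval < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
  expect_equal(sum(de$status != "not_de"), 0)
})
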