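test_that("truth generation apportions subfamily counts by largest remainder", {
  cfg <- sim_config(n_genes = 1000, frac_down = 0.5, frac_up = 0,
                    subfamily_down = c(REST_only = 0.05,
                                       REST_and_PRC = 0.25,
                                       PRC_only = 0.34, unknown = 0.36))
  truth <- generate_truth(cfg)
  counts <- table(truth$subfamily[truth$direction == "down"])
  expect_equal(counts[["REST_only"]], 25)
  expect_equal(counts[["REST_and_PRC"]], 125)
  expect_equal(counts[["PRC_only"]], 170)
  expect_equal(counts[["unknown"]], 180)
  expect_equal(sum(truth$direction == "null"), 500)
  expect_equal(nrow(truth), 1000)
})

test_that("largest-remainder apportionment is exact and conserving", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:5000, 1)
    f <- runif(sample(2:8, 1))
    f <- f / sum(f)
    counts <- restmech:::apportion_largest_remainder(n, f)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * f) < 1))
  }
})

test_that("degenerate fractions give an all-null truth table", {
  cfg <- small_config(frac_down = 0, frac_up = 0)
  truth <- generate_truth(cfg)
  expect_true(all(truth$direction == "null"))
  expect_true(all(truth$subfamily == "none"))
  expect_true(all(truth$planted_log2fc == 0))
})

test_that("truth invariants hold: subfamily/direction/effect consistency", {
  truth <- generate_truth(small_config())
  expect_false(anyDuplicated(truth$gene_id) > 0)
  expect_true(all((truth$subfamily == "none") == (truth$direction == "null")))
  expect_true(all((abs(truth$planted_log2fc) > 0) ==
                    (truth$direction != "null")))
  expect_true(all(truth$planted_log2fc[truth$direction == "down"] < 0))
  expect_true(all(truth$planted_log2fc[truth$direction == "up"] > 0))
  expect_true(all(truth$base_expression > 0))
})

test_that("generators are deterministic given the seed", {
  cfg <- small_config()
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(generate_counts(t1, cfg), generate_counts(t2, cfg))
  map <- generate_ortholog_map(t1$gene_id, 0.01, 0.05, seed = 3)
  expect_identical(map, generate_ortholog_map(t1$gene_id, 0.01, 0.05,
                                              seed = 3))
  expect_identical(generate_libraries(t1, cfg, map),
                   generate_libraries(t1, cfg, map))
})

test_that("counts approach the planted means in the Poisson limit", {
  cfg <- small_config(n_genes = 200, nb_dispersion = 0,
                      size_factor_spread = 0,
                      base_expression_meanlog = log(2e5),
                      base_expression_sdlog = 0.1)
  truth <- generate_truth(cfg)
  cm <- generate_counts(truth, cfg)
  half <- truth$planted_log2fc / 2
  expected <- cbind(A = truth$base_expression * 2^(-half),
                    B = truth$base_expression * 2^(half))
  observed <- cbind(A = rowMeans(cm$counts[, cm$condition == "A"]),
                    B = rowMeans(cm$counts[, cm$condition == "B"]))
  expect_true(all(abs(observed / expected - 1) < 0.01))
})

test_that("null genes have log2 fold changes centered at zero", {
  cfg <- small_config(n_genes = 500, frac_down = 0, frac_up = 0,
                      size_factor_spread = 0, seed = 5,
                      base_expression_meanlog = log(500),
                      base_expression_sdlog = 0.2)
  truth <- generate_truth(cfg)
  cm <- generate_counts(truth, cfg)
  a <- rowMeans(cm$counts[, cm$condition == "A"])
  b <- rowMeans(cm$counts[, cm$condition == "B"])
  lfc <- log2(b / a)
  # per-gene lfc sd is ~0.46 at this depth and dispersion, so the mean of
  # 500 null genes has standard error ~0.02; 3 s.e. band
  expect_lt(abs(mean(lfc)), 0.06)
})

test_that("counts are rejected for nonpositive base expression", {
  cfg <- small_config()
  truth <- generate_truth(cfg)
  truth$base_expression[1] <- 0
  expect_error(generate_counts(truth, cfg), "base_expression")
})

test_that("noise-free libraries equal the planted target sets exactly", {
  cfg <- small_config(library_sensitivity = 1,
                      library_background_rate = 0)
  truth <- generate_truth(cfg)
  libs <- generate_libraries(truth, cfg)
  rest_planted <- sort(toupper(truth$gene_id[
    truth$direction != "null" &
      truth$subfamily %in% c("REST_only", "REST_and_PRC")]))
  rest_terms <- names(libs$tf_chip$factor_group)[
    libs$tf_chip$factor_group == "REST"]
  for (tm in rest_terms) {
    expect_identical(libs$tf_chip$terms[[tm]], rest_planted)
  }
  prc_planted <- sort(toupper(truth$gene_id[
    truth$direction != "null" &
      truth$subfamily %in% c("REST_and_PRC", "PRC_only")]))
  suz_terms <- names(libs$tf_chip$factor_group)[
    libs$tf_chip$factor_group == "SUZ12"]
  expect_identical(libs$tf_chip$terms[[suz_terms[1]]], prc_planted)
})

test_that("expected term size is sensitivity*planted + background*rest", {
  # 2000 genes, planted set of ~200, sensitivity .8, background .05:
  # E[size] = 160 + 90 = 250
  cfg <- sim_config(n_genes = 2000, frac_down = 0.1, frac_up = 0,
                    subfamily_down = c(REST_only = 1, REST_and_PRC = 0,
                                       PRC_only = 0, unknown = 0),
                    library_sensitivity = 0.8,
                    library_background_rate = 0.05,
                    n_terms_per_group = 5, n_decoy_tfs = 2,
                    n_decoy_marks = 2, n_decoy_pathways = 2, seed = 9)
  truth <- generate_truth(cfg)
  libs <- generate_libraries(truth, cfg)
  rest_terms <- libs$tf_chip$terms[
    names(libs$tf_chip$factor_group)[
      libs$tf_chip$factor_group == "REST"]]
  sizes <- lengths(rest_terms)
  # binomial sd of the sensitivity part is ~6; the shared background part
  # is common to all five terms, so allow a generous sampling band
  expect_true(all(abs(sizes - 250) < 40))
})

test_that("decoy-term Fisher p-values are uniform against a planted list", {
  # decoy terms are large enough that the hypergeometric p-value lattice is
  # fine relative to the KS resolution at 200 decoys
  cfg <- sim_config(n_genes = 4000, frac_down = 0.15, frac_up = 0.15,
                    library_background_rate = 0.06,
                    n_decoy_tfs = 70, n_decoy_marks = 2,
                    n_decoy_pathways = 2, seed = 21)
  truth <- generate_truth(cfg)
  libs <- generate_libraries(truth, cfg)
  universe <- toupper(truth$gene_id)
  down <- toupper(truth$gene_id[truth$direction == "down"])
  decoy_terms <- libs$tf_chip$terms[
    grepl("^DECOY_TF", libs$tf_chip$factor_group)]
  p <- vapply(decoy_terms[seq_len(200)], function(tm) {
    fisher_enrich(down, tm, universe)$pvalue
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ortholog map handles drops, collisions and idempotence", {
  genes <- sprintf("Gene%04d", 1:1000)
  bij <- generate_ortholog_map(genes)
  expect_equal(nrow(bij), 1000)
  expect_equal(anyDuplicated(bij$human_symbol), 0)
  expect_identical(bij$human_symbol, toupper(bij$rat_symbol))

  dropped <- generate_ortholog_map(genes, drop_rate = 0.1, seed = 2)
  expect_true(abs(nrow(dropped) - 900) < 40)

  collided <- generate_ortholog_map(genes, collision_rate = 0.2, seed = 2)
  expect_gt(anyDuplicated(collided$human_symbol), 0)

  once <- map_orthologs(genes[1:50], bij, quiet = TRUE)
  twice <- map_orthologs(once, bij, quiet = TRUE)
  expect_identical(twice, once)
})

test_that("sim_config rejects inconsistent configurations", {
  expect_error(sim_config(frac_down = 0.7, frac_up = 0.5), "exceeds 1")
  expect_error(sim_config(subfamily_down = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(sim_config(library_sensitivity = 0.01,
                          library_background_rate = 0.5),
               "undetectable")
})

test_that("config and data round-trip through their file formats", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_genes = 80, frac_down = 0.2, frac_up = 0.2,
                      n_decoy_tfs = 3, n_decoy_marks = 2,
                      n_decoy_pathways = 2)
  write_sim_config(cfg, file.path(dir, "cfg.yaml"))
  expect_equal(read_sim_config(file.path(dir, "cfg.yaml")), cfg)

  truth <- generate_truth(cfg)
  cm <- generate_counts(truth, cfg)
  write_count_matrix(cm, file.path(dir, "c.tsv"), file.path(dir, "s.tsv"))
  cm2 <- read_count_matrix(file.path(dir, "c.tsv"), file.path(dir, "s.tsv"))
  expect_equal(cm2$counts, cm$counts)
  expect_equal(as.character(cm2$condition), as.character(cm$condition))

  libs <- generate_libraries(truth, cfg)
  write_gmt(libs$tf_chip, file.path(dir, "chip.gmt"))
  lib2 <- read_gmt(file.path(dir, "chip.gmt"), "synthetic_tf_chip",
                   "tf_chip")
  expect_identical(lib2$terms, libs$tf_chip$terms)
  expect_identical(lib2$factor_group, libs$tf_chip$factor_group)
})
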