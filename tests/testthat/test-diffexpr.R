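test_that("median-of-ratios size factors behave like the classic estimator", {
  set.seed(181)
  counts <- matrix(rnbinom(200 * 4, mu = 100, size = 10), nrow = 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  counts[counts == 0] <- 1
  doubled <- cbind(counts, s5 = 2L * counts[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["s5"] / sf["s1"]), 2, tolerance = 1e-10)

  same <- size_factors(cbind(a = counts[, 1], b = counts[, 1]))
  expect_equal(unname(same["a"]), unname(same["b"]))

  # scaling one sample by c multiplies its factor by c, relative to the rest
  scaled <- counts
  scaled[, 2] <- 3L * scaled[, 2]
  sf0 <- size_factors(counts)
  sf3 <- size_factors(scaled)
  expect_equal(unname((sf3[2] / sf3[1]) / (sf0[2] / sf0[1])), 3,
               tolerance = 1e-10)

  sparse <- matrix(c(0L, 5L, 0L, 3L, 0L, 2L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_warning(size_factors(sparse), "upper-quartile")
})

test_that("a noiseless doubled gene yields exactly one log2 unit of change", {
  n_rep <- 6
  counts <- matrix(50L, nrow = 20, ncol = 2 * n_rep,
                   dimnames = list(paste0("g", 1:20),
                                   paste0("s", 1:(2 * n_rep))))
  counts["g1", 1:n_rep] <- 100L
  meta <- data.frame(sample = colnames(counts),
                     strain = rep(c("mut", "wt"), each = n_rep),
                     batch = "batch1", replicate = rep(1:n_rep, 2))
  de <- suppressMessages(de_test(counts, meta, "mut", "wt", batch = TRUE))
  # size factors absorb part of the doubling; the target gene still dominates
  expect_gt(de$log2fc[de$gene == "g1"], 0.9)
  expect_equal(de$log2fc[de$gene == "g2"], de$log2fc[de$gene == "g3"])
})

test_that("null cohorts respect the FDR gate and planted four-fold genes are recovered", {
  null_cfg <- sim_config(n_mutant_strains = 2,
                         strain_longevity_effects = c(0.3, 0.6),
                         n_genes = 2000, effect_size = 0,
                         module_sizes = c(shared_driver = 0,
                                          lifespan_only = 0,
                                          stress_specific = 0),
                         alt_control_strain = NULL, seed = 191)
  co <- generate_cohort(null_cfg)
  de <- de_test(co$counts, co$metadata, "mutant_1", "wildtype", fdr = 0.01)
  expect_lte(mean(de$significant), 0.01)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.025)

  planted_cfg <- sim_config(n_mutant_strains = 2,
                            strain_longevity_effects = c(1, 1),
                            assays = shared_panel(), n_genes = 2000,
                            effect_size = 2, negative_fraction = 0,
                            module_sizes = c(shared_driver = 200,
                                             lifespan_only = 0,
                                             stress_specific = 0),
                            alt_control_strain = NULL, seed = 192)
  co2 <- generate_cohort(planted_cfg)
  de2 <- de_test(co2$counts, co2$metadata, "mutant_1", "wildtype", fdr = 0.01)
  planted <- co2$truth$genes$gene[co2$truth$genes$module == "shared_driver"]
  expect_gte(mean(planted %in% de2$gene[de2$significant]), 0.9)
  up <- de_direction_sets(de2)$up
  expect_gt(length(intersect(up, planted)) / length(up), 0.8)
})

test_that("the DE test is invariant to sample order and batch relabeling", {
  cfg <- tiny_cfg(seed = 201)
  co <- generate_cohort(cfg)
  de <- de_test(co$counts, co$metadata, "mutant_2", "wildtype")
  perm <- sample(ncol(co$counts))
  de_p <- de_test(co$counts[, perm], co$metadata[perm, ],
                  "mutant_2", "wildtype")
  expect_equal(de$p, de_p$p, tolerance = 1e-12)

  relabeled <- co$metadata
  relabeled$batch <- c(batch1 = "B", batch2 = "A")[relabeled$batch]
  de_r <- de_test(co$counts, relabeled, "mutant_2", "wildtype")
  expect_equal(de$p, de_r$p, tolerance = 1e-12)

  expect_error(de_test(co$counts, co$metadata[co$metadata$replicate == 1, ],
                       "mutant_2", "wildtype"), "2 replicates")
})

test_that("the batch-adjusted linear model agrees with limma's ordinary statistics", {
  skip_if_not_installed("limma")
  cfg <- tiny_cfg(seed = 211)
  co <- generate_cohort(cfg)
  sel <- co$metadata$strain %in% c("mutant_1", "wildtype")
  meta <- co$metadata[sel, ]
  de <- de_test(co$counts, co$metadata, "mutant_1", "wildtype", batch = TRUE,
                moderate = FALSE)

  sf <- size_factors(co$counts)
  logn <- log2(sweep(co$counts[, meta$sample], 2, sf[meta$sample], "/") + 1)
  design <- stats::model.matrix(~ mut + bat,
                                data.frame(mut = as.integer(meta$strain == "mutant_1"),
                                           bat = factor(meta$batch)))
  fit <- limma::lmFit(logn, design)
  t_ord <- fit$coefficients[, "mut"] /
    (fit$stdev.unscaled[, "mut"] * fit$sigma)
  p_ord <- 2 * stats::pt(-abs(t_ord), df = fit$df.residual)
  expect_equal(de$log2fc, unname(fit$coefficients[, "mut"]), tolerance = 1e-10)
  expect_equal(de$p, unname(p_ord), tolerance = 1e-10)
})

test_that("external DE tables round-trip and are validated", {
  de <- data.frame(gene = paste0("g", 1:5),
                   log2fc = c(1.2, -0.5, 0.1, 2.4, -1.8),
                   p = c(0.001, 0.2, 0.9, 1e-5, 0.04))
  de$q <- bh_adjust(de$p)
  de$significant <- de$q < 0.01
  class(de) <- c("de_result", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, path)
  back <- import_external_de(path, fdr = 0.01)
  expect_equal(back$gene, de$gene)
  expect_equal(back$q, de$q)
  expect_equal(back$significant, de$significant)

  # p-only table: q recomputed by Benjamini-Hochberg
  p_only <- de[, c("gene", "log2fc", "p")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(p_only, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back2 <- import_external_de(path2)
  expect_equal(back2$q, bh_adjust(de$p))

  # missing and malformed columns are named
  path3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(de[, c("gene", "p")], path3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(import_external_de(path3), "log2fc")
  broken <- p_only
  broken$p <- as.character(broken$p)
  broken$p[3] <- "oops"
  path4 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(broken, path4, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(import_external_de(path4), "row")
})

test_that("the expression filter defines a plausible detected-gene universe", {
  cfg <- tiny_cfg(seed = 221)
  co <- generate_cohort(cfg)
  uni <- expression_universe(co$counts, co$metadata)
  expect_true(length(uni) > 0.9 * nrow(co$counts))
  # an all-zero gene is excluded
  counts <- co$counts
  counts["gene_00001", ] <- 0L
  expect_false("gene_00001" %in% expression_universe(counts, co$metadata))
})
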