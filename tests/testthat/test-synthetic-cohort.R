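test_that("identical config and seed give identical cohorts", {
  cfg <- tiny_cfg(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$survival, b$survival)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("survival time generation respects censoring and the exponential mean", {
  x <- generate_survival_times(12, 400, censor_rate = 0, seed = 3)
  expect_true(all(x$event == 1))
  expect_true(all(x$time > 0))

  y <- generate_survival_times(12, 4000, censor_rate = 0.3, seed = 4)
  expect_lt(abs(mean(y$event == 0) - 0.3), 0.03)

  # shape 1 is exponential: sample mean of death times converges to the scale
  z <- generate_survival_times(10, 20000, seed = 5, shape = 1)
  expect_lt(abs(mean(z$time) - 10) / 10, 0.02)

  expect_error(generate_survival_times(10, 0), "integer|positive")
  expect_error(generate_survival_times(-1, 10), "positive")
})

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_mutant_strains = 0), "positive|integer")
  expect_error(sim_config(n_genes = 100,
                          module_sizes = c(shared_driver = 90,
                                           lifespan_only = 20,
                                           stress_specific = 10)),
               "module sizes")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(assay_spec("x", endpoint = "fraction_alive"), "endpoint time")
})

test_that("realized lifespan extension matches the configured effect", {
  cfg <- sim_config(n_mutant_strains = 1, strain_longevity_effects = 0.5,
                    n_worms_per_assay_arm = 2000, n_genes = 20,
                    module_sizes = c(shared_driver = 0, lifespan_only = 0,
                                     stress_specific = 0),
                    censor_rate = 0, alt_control_strain = NULL, seed = 21)
  co <- generate_cohort(cfg)
  life <- co$survival[co$survival$assay == "lifespan", ]
  mut <- mean(life$time[life$strain == "mutant_1"])
  wt <- mean(life$time[life$strain == "wildtype"])
  expect_lt(abs((mut / wt - 1) - 0.5) / 0.5, 0.05)
})

test_that("well-separated survival scales are detected by the log-rank test", {
  set.seed(31)
  g <- two_arm(1000, 10, 20, shape = 1)
  res <- logrank_test(g$a, rep(1, 1000), g$b, rep(1, 1000))
  expect_lt(res$p_value, 1e-10)
})

test_that("count matrix structure, batches and arm sizes follow the design", {
  cfg <- tiny_cfg(seed = 41)
  co <- generate_cohort(cfg)
  expect_true(is.integer(co$counts))
  expect_true(all(co$counts >= 0))
  expect_equal(dim(co$counts),
               c(300, 6 * cfg$n_rnaseq_replicates))  # 4 mutants + 2 controls
  # batches round-robin over replicates
  expect_equal(co$metadata$batch,
               sprintf("batch%d", (co$metadata$replicate - 1) %% 2 + 1))
  # every strain x assay arm has the configured number of worms
  arm <- table(co$survival$strain, co$survival$assay)
  expect_true(all(arm == cfg$n_worms_per_assay_arm))
  # the alternate-temperature strain is matched to the 25C control
  expect_equal(unique(co$survival$control_group[
    co$survival$strain == "mutant_4"]), "wildtype_25C")
})

test_that("zero dispersion gives Poisson-like counts, positive dispersion inflates them", {
  base <- sim_config(n_mutant_strains = 1, strain_longevity_effects = 0.5,
                     n_genes = 200, n_rnaseq_replicates = 30,
                     module_sizes = c(shared_driver = 0, lifespan_only = 0,
                                      stress_specific = 0),
                     alt_control_strain = NULL, batch_count = 1,
                     nb_dispersion = 0, seed = 51)
  pois <- generate_expression_counts(cohort_truth(base), base)
  nb_cfg <- sim_config(n_mutant_strains = 1, strain_longevity_effects = 0.5,
                       n_genes = 200, n_rnaseq_replicates = 30,
                       module_sizes = c(shared_driver = 0, lifespan_only = 0,
                                        stress_specific = 0),
                       alt_control_strain = NULL, batch_count = 1,
                       nb_dispersion = 0.2, seed = 51)
  nb <- generate_expression_counts(cohort_truth(nb_cfg), nb_cfg)
  vmr <- function(m) {
    wt <- m$metadata$sample[m$metadata$strain == "wildtype"]
    x <- m$counts[, wt]
    mean(apply(x, 1, stats::var) / rowMeans(x))
  }
  expect_lt(abs(vmr(pois) - 1), 0.15)   # variance ~ mean
  expect_gt(vmr(nb), 3)                 # strongly overdispersed
})

test_that("a planted unit coupling with traits {0, 1} yields a unit log2 fold-change", {
  cfg <- sim_config(n_mutant_strains = 1, strain_longevity_effects = 1,
                    assays = shared_panel(), n_genes = 400,
                    module_sizes = c(shared_driver = 60, lifespan_only = 0,
                                     stress_specific = 0),
                    effect_size = 1, negative_fraction = 0,
                    n_rnaseq_replicates = 12,
                    alt_control_strain = NULL, seed = 61)
  co <- generate_cohort(cfg)
  shared <- co$truth$genes$module == "shared_driver"
  mut <- co$metadata$sample[co$metadata$strain == "mutant_1"]
  wt <- co$metadata$sample[co$metadata$strain == "wildtype"]
  lfc <- log2(rowMeans(co$counts[shared, mut]) + 1) -
    log2(rowMeans(co$counts[shared, wt]) + 1)
  expect_lt(abs(mean(lfc) - 1), 0.1)
})

test_that("with zero coupling, gene-phenotype discoveries stay at the false-positive rate", {
  # many replicate null cohorts; each contributes the per-gene significance
  # fraction at alpha = 0.05 against a stress phenotype
  frac <- vapply(1:200, function(s) {
    cfg <- sim_config(n_mutant_strains = 6,
                      strain_longevity_effects = seq(0.2, 1.3, length.out = 6),
                      n_genes = 40, effect_size = 0,
                      module_sizes = c(shared_driver = 10, lifespan_only = 0,
                                       stress_specific = 0),
                      n_rnaseq_replicates = 4, alt_control_strain = NULL,
                      seed = 1000 + s)
    truth <- cohort_truth(cfg)
    expr <- generate_expression_counts(truth, cfg)
    summ <- strain_expression_summary(expr$counts, expr$metadata,
                                      mode = "log2_mean")
    pheno <- truth$expected$expected_endpoint[
      truth$expected$assay == "pathogen"]
    names(pheno) <- truth$expected$strain[truth$expected$assay == "pathogen"]
    gc <- suppressWarnings(gene_phenotype_correlation(summ, pheno))
    mean(gc$significant)
  }, numeric(1))
  rate <- mean(frac)
  # binomial 95% interval around alpha for 200 x 40 weakly dependent genes
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
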