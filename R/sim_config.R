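#' Describe one survival assay of the panel
#'
#' An assay specification carries everything the pipeline needs to know about
#' a single assay: how its per-strain endpoint is computed, which significance
#' test compares a strain against its control, and -- for simulation -- the
#' wild-type Weibull scale, how strongly the strain stress trait shifts that
#' scale, and how much of the trait is shared robustness versus
#' stressor-specific physiology.
#'
#' @param id assay identifier (e.g. `"heat"`).
#' @param stressor stressor label; several assays (severity levels) may map to
#'   one stressor and are then collapsed by [resistance_count()].
#' @param endpoint `"fraction_alive"` (proportion surviving at `time`) or
#'   `"mean_survival"` (restricted mean survival time).
#' @param time endpoint time; required iff `endpoint == "fraction_alive"`.
#' @param unit time unit label (`"hours"` or `"days"`), used in reports only.
#' @param test significance test versus control: `"logrank"`, `"gehan"`,
#'   `"anova_dunnett"` (one-way ANOVA with Dunnett's comparison over replicate
#'   proportions), or `"t_test"`.
#' @param baseline_scale wild-type Weibull scale parameter for simulation, in
#'   `unit`s.
#' @param coupling multiplicative trait coupling: a strain with stress trait
#'   `t` gets scale `baseline_scale * (1 + coupling * t)`.
#' @param shared_weight fraction (0-1) of the strain stress trait contributed
#'   by the shared robustness factor (the longevity effect); the remainder
#'   comes from an independent stressor-specific factor.
#' @return an object of class `assay_spec`.
#' @export
assay_spec <- function(id, stressor = id,
                       endpoint = c("fraction_alive", "mean_survival"),
                       time = NULL, unit = "hours",
                       test = c("logrank", "gehan", "anova_dunnett", "t_test"),
                       baseline_scale = 10, coupling = 1, shared_weight = 0.6) {
  endpoint <- match.arg(endpoint)
  test <- match.arg(test)
  if (endpoint == "fraction_alive" && is.null(time))
    stopf("assay '%s': endpoint 'fraction_alive' requires an endpoint time", id)
  if (endpoint == "mean_survival" && !is.null(time))
    stopf("assay '%s': endpoint 'mean_survival' takes no endpoint time", id)
  if (!is.null(time)) assert_number(time, "time", positive = TRUE)
  assert_number(baseline_scale, "baseline_scale", positive = TRUE)
  assert_number(coupling, "coupling")
  assert_number(shared_weight, "shared_weight", min = 0, max = 1)
  structure(
    list(id = id, stressor = stressor, endpoint = endpoint, time = time,
         unit = unit, test = test, baseline_scale = baseline_scale,
         coupling = coupling, shared_weight = shared_weight),
    class = "assay_spec"
  )
}

#' Default lifespan + six-stressor assay panel
#'
#' Emulates the classic worm panel: lifespan at 20 degrees C, heat stress
#' (37 degrees C, scored to 10 h), chronic oxidative stress (4 mM paraquat,
#' scored to death), acute oxidative stress (300 uM juglone, scored to 10 h),
#' bacterial pathogen slow killing (scored to death), osmotic stress (survival
#' at 48 h), and anoxia (survival at 72 h). Wild-type Weibull scales are set
#' so the wild-type endpoint sits mid-range (roughly 50% alive at fixed-time
#' endpoints), where assay power is best. The bacterial-pathogen assay carries
#' the largest shared-robustness weight, reflecting that pathogen resistance
#' tracks longevity more closely than any other stressor. Per-assay coupling
#' strengths are graded so that assays differ in how much longevity effect a
#' strain needs before its resistance becomes detectable -- calibrated so the
#' expected number of resistant strains per assay in a default cohort
#' reproduces the published pattern (nearly all strains heat- and
#' pathogen-resistant, only the longest-lived anoxia-resistant), which is
#' what makes the resistance count a graded, monotone correlate of
#' longevity.
#'
#' @param wt_lifespan_mean wild-type mean lifespan in days.
#' @param weibull_shape Weibull shape used to convert a target mean into a
#'   scale (mean = scale * gamma(1 + 1/shape)).
#' @return a named list of [assay_spec()] objects, first element `lifespan`.
#' @export
default_assay_panel <- function(wt_lifespan_mean = 20, weibull_shape = 3) {
  g <- gamma(1 + 1 / weibull_shape)
  specs <- list(
    assay_spec("lifespan", endpoint = "mean_survival", unit = "days",
               test = "logrank", baseline_scale = wt_lifespan_mean / g,
               coupling = 1, shared_weight = 1),
    assay_spec("heat", endpoint = "fraction_alive", time = 10, unit = "hours",
               test = "anova_dunnett", baseline_scale = 11.3,
               coupling = 1.3, shared_weight = 0.9),
    assay_spec("oxidative_chronic", endpoint = "mean_survival", unit = "days",
               test = "logrank", baseline_scale = 5 / g,
               coupling = 0.5, shared_weight = 0.9),
    assay_spec("oxidative_acute", endpoint = "fraction_alive", time = 10,
               unit = "hours", test = "anova_dunnett", baseline_scale = 11.3,
               coupling = 0.36, shared_weight = 0.9),
    assay_spec("pathogen", endpoint = "mean_survival", unit = "days",
               test = "logrank", baseline_scale = 7 / g,
               coupling = 0.53, shared_weight = 0.95),
    assay_spec("osmotic", endpoint = "fraction_alive", time = 48,
               unit = "hours", test = "anova_dunnett", baseline_scale = 54,
               coupling = 0.45, shared_weight = 0.9),
    assay_spec("anoxia", endpoint = "fraction_alive", time = 72,
               unit = "hours", test = "anova_dunnett", baseline_scale = 81,
               coupling = 0.24, shared_weight = 0.9)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
}

#' Configuration for a synthetic study cohort
#'
#' Defines an in-silico panel of long-lived mutant strains plus matched
#' wild-type controls: survival assays (lifespan + stress panel), a bulk
#' RNA-seq count matrix with batch structure, and planted gene modules that
#' couple expression to the longevity and stress traits. Defaults mirror a
#' nine-mutant worm panel: longevity effects spanning ~26% to ~138% lifespan
#' extension, six RNA-seq replicates per strain, and one temperature-sensitive
#' strain (`alt_control_strain`) that requires a separate wild-type control
#' reared at 25 degrees C.
#'
#' @param n_mutant_strains number of mutant strains.
#' @param wt_lifespan_mean wild-type mean lifespan (days).
#' @param strain_longevity_effects fractional lifespan extensions, one per
#'   mutant (0.5 = 50% longer-lived). Names, if present, are used as strain
#'   ids; otherwise strains are `mutant_1 ... mutant_k`.
#' @param assays assay panel, a list of [assay_spec()] including `lifespan`.
#' @param n_worms_per_assay_arm worms per strain per assay.
#' @param n_survival_replicates biological replicates the worms of each arm
#'   are split across.
#' @param n_rnaseq_replicates RNA-seq biological replicates per strain.
#' @param n_genes number of simulated genes.
#' @param module_sizes named vector with elements `shared_driver`,
#'   `lifespan_only` and `stress_specific` (the latter is per stress assay);
#'   remaining genes form the null module.
#' @param effect_size expression coupling in log2 units per unit trait.
#' @param negative_fraction fraction of non-null genes given a negative
#'   coupling sign.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-12 switch to Poisson sampling.
#' @param batch_count number of RNA-seq batches, assigned round-robin over
#'   replicates.
#' @param batch_sd standard deviation (log2 units) of per-gene batch effects.
#' @param specific_min lower bound of the stressor-specific trait factors,
#'   as a multiple of the largest longevity effect (upper bound is that
#'   effect itself). Negative values let individual stressors oppose the
#'   shared robustness factor, so some long-lived strains show decreased
#'   resistance to particular stressors, as published panels do.
#' @param censor_rate fraction of animals censored uniformly over their own
#'   survival window.
#' @param weibull_shape Weibull shape for death times (3 gives the sigmoidal
#'   survival curves typical of worm assays).
#' @param alt_control_strain index or name of the strain compared against the
#'   alternate-temperature wild-type control (`NULL` for none).
#' @param seed master seed; every random stream is derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_mutant_strains = 9,
                       wt_lifespan_mean = 20,
                       strain_longevity_effects = c(
                         0.263, 0.334, 0.372, 0.456, 0.654,
                         0.792, 0.838, 0.892, 1.384
                       )[seq_len(n_mutant_strains)],
                       assays = default_assay_panel(wt_lifespan_mean,
                                                    weibull_shape),
                       n_worms_per_assay_arm = 120,
                       n_survival_replicates = 3,
                       n_rnaseq_replicates = 6,
                       n_genes = 5000,
                       module_sizes = c(shared_driver = 200,
                                        lifespan_only = 100,
                                        stress_specific = 50),
                       effect_size = 1,
                       negative_fraction = 0.3,
                       nb_dispersion = 0.1,
                       batch_count = 2,
                       batch_sd = 0.2,
                       specific_min = -1,
                       censor_rate = 0.05,
                       weibull_shape = 3,
                       alt_control_strain = if (n_mutant_strains >= 8) 8L else NULL,
                       seed = 1L) {
  n_mutant_strains <- assert_count(n_mutant_strains, "n_mutant_strains")
  assert_number(wt_lifespan_mean, "wt_lifespan_mean", positive = TRUE)
  if (length(strain_longevity_effects) != n_mutant_strains ||
      anyNA(strain_longevity_effects))
    stopf("'strain_longevity_effects' must supply one finite effect per mutant strain")
  if (!all(is.finite(strain_longevity_effects)))
    stopf("'strain_longevity_effects' must be finite")
  if (is.null(names(strain_longevity_effects)))
    names(strain_longevity_effects) <-
      paste0("mutant_", seq_len(n_mutant_strains))
  if (anyDuplicated(names(strain_longevity_effects)))
    stopf("strain names must be unique")
  if (!is.list(assays) || !all(vapply(assays, inherits, logical(1), "assay_spec")))
    stopf("'assays' must be a list of assay_spec objects")
  if (!"lifespan" %in% vapply(assays, `[[`, character(1), "id"))
    stopf("the assay panel must include a 'lifespan' assay")
  n_worms_per_assay_arm <- assert_count(n_worms_per_assay_arm,
                                        "n_worms_per_assay_arm")
  n_survival_replicates <- assert_count(n_survival_replicates,
                                        "n_survival_replicates")
  n_rnaseq_replicates <- assert_count(n_rnaseq_replicates, "n_rnaseq_replicates")
  n_genes <- assert_count(n_genes, "n_genes")
  req <- c("shared_driver", "lifespan_only", "stress_specific")
  if (!all(req %in% names(module_sizes)))
    stopf("'module_sizes' must name %s", paste(req, collapse = ", "))
  if (any(module_sizes < 0) || any(module_sizes != round(module_sizes)))
    stopf("module sizes must be non-negative integers")
  n_stress <- sum(vapply(assays, `[[`, character(1), "id") != "lifespan")
  total_planted <- module_sizes[["shared_driver"]] +
    module_sizes[["lifespan_only"]] +
    n_stress * module_sizes[["stress_specific"]]
  if (total_planted > n_genes)
    stopf("module sizes sum to %d but only %d genes are simulated",
          total_planted, n_genes)
  assert_number(effect_size, "effect_size")
  assert_number(negative_fraction, "negative_fraction", min = 0, max = 1)
  assert_number(nb_dispersion, "nb_dispersion", min = 0)
  batch_count <- assert_count(batch_count, "batch_count")
  assert_number(batch_sd, "batch_sd", min = 0)
  assert_number(specific_min, "specific_min", max = 1)
  assert_number(censor_rate, "censor_rate", min = 0, max = 1 - 1e-12)
  assert_number(weibull_shape, "weibull_shape", positive = TRUE)
  if (!is.null(alt_control_strain)) {
    if (is.numeric(alt_control_strain))
      alt_control_strain <- names(strain_longevity_effects)[alt_control_strain]
    if (!alt_control_strain %in% names(strain_longevity_effects))
      stopf("'alt_control_strain' is not one of the mutant strains")
  }
  seed <- assert_count(seed, "seed", min = 0L)

  structure(
    list(n_mutant_strains = n_mutant_strains,
         wt_lifespan_mean = wt_lifespan_mean,
         strain_longevity_effects = strain_longevity_effects,
         assays = assays,
         n_worms_per_assay_arm = n_worms_per_assay_arm,
         n_survival_replicates = n_survival_replicates,
         n_rnaseq_replicates = n_rnaseq_replicates,
         n_genes = n_genes,
         module_sizes = module_sizes,
         effect_size = effect_size,
         negative_fraction = negative_fraction,
         nb_dispersion = nb_dispersion,
         batch_count = batch_count,
         batch_sd = batch_sd,
         specific_min = specific_min,
         censor_rate = censor_rate,
         weibull_shape = weibull_shape,
         alt_control_strain = alt_control_strain,
         seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d mutant strains (+ matched wild-type controls%s)\n",
              x$n_mutant_strains,
              if (is.null(x$alt_control_strain)) ""
              else sprintf(", alt 25C control for %s", x$alt_control_strain)))
  cat(sprintf("  assays: %s\n",
              paste(vapply(x$assays, `[[`, character(1), "id"),
                    collapse = ", ")))
  cat(sprintf("  %d worms/arm in %d replicates; %d RNA-seq reps; %d genes\n",
              x$n_worms_per_assay_arm, x$n_survival_replicates,
              x$n_rnaseq_replicates, x$n_genes))
  cat(sprintf("  modules: %d shared, %d lifespan-only, %d per-stressor; effect %.2g log2/trait\n",
              x$module_sizes[["shared_driver"]],
              x$module_sizes[["lifespan_only"]],
              x$module_sizes[["stress_specific"]], x$effect_size))
  cat(sprintf("  NB dispersion %.3g, %d batches, censor rate %.2g, seed %d\n",
              x$nb_dispersion, x$batch_count, x$censor_rate, x$seed))
  invisible(x)
}
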