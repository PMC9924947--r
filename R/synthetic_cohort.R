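#' Simulate right-censored survival times for one assay arm
#'
#' Death times follow a Weibull distribution (shape 3 by default, giving the
#' roughly sigmoidal survival curves seen in worm assays; shape 1 recovers the
#' exponential). Censoring is independent and uniform over each animal's own
#' survival window, the simplest ignorable mechanism, emulating removals for
#' internal hatching or extruded vulva.
#'
#' @param strain_scale Weibull scale parameter (same time unit as the assay).
#' @param n number of animals.
#' @param censor_rate expected fraction of censored animals, in `[0, 1)`.
#' @param seed optional integer seed for a self-contained stream; when given,
#'   the caller's RNG state is untouched.
#' @param shape Weibull shape parameter.
#' @return a data.frame with columns `time` (> 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @examples
#' x <- generate_survival_times(20, 50, censor_rate = 0.1, seed = 1)
#' stopifnot(all(x$time > 0), all(x$event %in% 0:1))
#' @export
generate_survival_times <- function(strain_scale, n, censor_rate = 0,
                                    seed = NULL, shape = 3) {
  assert_number(strain_scale, "strain_scale", positive = TRUE)
  n <- assert_count(n, "n")
  assert_number(censor_rate, "censor_rate", min = 0, max = 1 - 1e-12)
  assert_number(shape, "shape", positive = TRUE)
  draw <- function() {
    death <- stats::rweibull(n, shape = shape, scale = strain_scale)
    cens <- stats::runif(n) < censor_rate
    ctime <- stats::runif(n) * death
    time <- ifelse(cens, ctime, death)
    data.frame(time = pmax(time, .Machine$double.xmin),
               event = as.integer(!cens))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Strain trait matrix: one row per strain (mutants then controls), one column
# per assay. The lifespan trait is the configured longevity effect; each
# stress trait mixes the shared robustness factor (equal to the longevity
# effect) with an independent stressor-specific factor drawn once per assay.
# Specific factors may be negative, so a long-lived strain can still show
# decreased resistance to an individual stressor, as real panels do.
strain_traits <- function(config) {
  eff <- config$strain_longevity_effects
  strains <- c(names(eff), "wildtype",
               if (!is.null(config$alt_control_strain)) "wildtype_25C")
  assay_ids <- vapply(config$assays, `[[`, character(1), "id")
  traits <- matrix(0, nrow = length(strains), ncol = length(assay_ids),
                   dimnames = list(strains, assay_ids))
  traits[names(eff), "lifespan"] <- eff
  span <- max(eff)
  for (a in config$assays) {
    if (a$id == "lifespan") next
    lo <- (config$specific_min %||% -0.5) * span
    spec <- with_seed(derive_seed(config$seed, "specific", a$id),
                      stats::runif(length(eff), lo, span))
    traits[names(eff), a$id] <-
      a$shared_weight * eff + (1 - a$shared_weight) * spec
  }
  traits
}

#' Planted ground truth for a synthetic cohort
#'
#' Assigns every gene to exactly one module (`shared_driver`, `lifespan_only`,
#' `stress_specific:<assay>`, or `null`), draws coupling signs, and records the
#' strain-level latent traits together with the expected per-strain survival
#' scale and endpoint for every assay. Null-module genes have coupling zero.
#'
#' @param config a [sim_config()].
#' @return an object of class `cohort_truth` with elements `genes` (gene,
#'   module, beta), `traits` (strain x assay matrix), and `expected`
#'   (strain/assay Weibull scale and expected endpoint value).
#' @export
cohort_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  stress_ids <- setdiff(vapply(config$assays, `[[`, character(1), "id"),
                        "lifespan")
  labels <- c(rep("shared_driver", config$module_sizes[["shared_driver"]]),
              rep("lifespan_only", config$module_sizes[["lifespan_only"]]),
              rep(paste0("stress_specific:", stress_ids),
                  each = config$module_sizes[["stress_specific"]]))
  labels <- c(labels, rep("null", config$n_genes - length(labels)))
  assigned <- with_seed(derive_seed(config$seed, "modules"), {
    lab <- sample(labels)
    sgn <- ifelse(stats::runif(config$n_genes) < config$negative_fraction,
                  -1, 1)
    list(lab = lab, sgn = sgn)
  })
  beta <- ifelse(assigned$lab == "null", 0,
                 assigned$sgn * config$effect_size)
  traits <- strain_traits(config)

  expected <- do.call(rbind, lapply(config$assays, function(a) {
    scale <- a$baseline_scale * (1 + a$coupling * traits[, a$id])
    if (any(scale <= 0))
      stopf("assay '%s': trait coupling drives a survival scale below zero; weaken 'coupling'",
            a$id)
    endpoint <- if (a$endpoint == "mean_survival") {
      scale * gamma(1 + 1 / config$weibull_shape)
    } else {
      exp(-(a$time / scale)^config$weibull_shape)
    }
    data.frame(strain = rownames(traits), assay = a$id,
               scale = unname(scale), expected_endpoint = unname(endpoint),
               row.names = NULL)
  }))

  structure(
    list(genes = data.frame(gene = genes, module = assigned$lab, beta = beta),
         traits = traits, expected = expected),
    class = "cohort_truth"
  )
}

# The latent driver value of a gene in a strain: the shared robustness factor
# is read through the mean stress trait, lifespan-only genes track the
# longevity effect, stress-specific genes track their assay's trait.
gene_driver_matrix <- function(truth, config) {
  traits <- truth$traits
  stress_ids <- setdiff(colnames(traits), "lifespan")
  drivers <- matrix(0, nrow = nrow(truth$genes), ncol = nrow(traits),
                    dimnames = list(truth$genes$gene, rownames(traits)))
  module <- truth$genes$module
  shared_val <- rowMeans(traits[, stress_ids, drop = FALSE])
  if (any(module == "shared_driver"))
    drivers[module == "shared_driver", ] <-
      matrix(shared_val, nrow = sum(module == "shared_driver"),
             ncol = nrow(traits), byrow = TRUE)
  if (any(module == "lifespan_only"))
    drivers[module == "lifespan_only", ] <-
      matrix(traits[, "lifespan"], nrow = sum(module == "lifespan_only"),
             ncol = nrow(traits), byrow = TRUE)
  for (a in stress_ids) {
    sel <- module == paste0("stress_specific:", a)
    if (any(sel))
      drivers[sel, ] <- matrix(traits[, a], nrow = sum(sel),
                               ncol = nrow(traits), byrow = TRUE)
  }
  drivers
}

#' Simulate the RNA-seq count matrix of a cohort
#'
#' Gene/sample means follow `baseline_g * 2^(beta_g * driver_g(strain) +
#' batch_effect)`; counts are negative binomial with the configured
#' dispersion (Poisson when dispersion is below 1e-12). Batches are assigned
#' round-robin across replicates and batch effects are per-gene log2 shifts
#' relative to batch 1.
#'
#' @param truth a [cohort_truth()].
#' @param config the matching [sim_config()].
#' @return list with `counts` (integer gene x sample matrix) and `metadata`
#'   (sample, strain, batch, replicate).
#' @export
generate_expression_counts <- function(truth, config) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(config, "sim_config"))
  if (nrow(truth$genes) != config$n_genes)
    stopf("truth and config disagree on the number of genes")
  strains <- rownames(truth$traits)
  reps <- seq_len(config$n_rnaseq_replicates)
  metadata <- data.frame(
    sample = as.vector(vapply(strains, function(s)
      sprintf("%s_rep%d", s, reps), character(length(reps)))),
    strain = rep(strains, each = length(reps)),
    batch = rep(sprintf("batch%d", (reps - 1L) %% config$batch_count + 1L),
                times = length(strains)),
    replicate = rep(reps, times = length(strains))
  )

  baseline <- with_seed(derive_seed(config$seed, "baseline"),
                        exp(stats::rnorm(config$n_genes, log(200), 1)))
  batch_eff <- with_seed(derive_seed(config$seed, "batcheffects"), {
    m <- matrix(0, nrow = config$n_genes, ncol = config$batch_count)
    if (config$batch_count > 1)
      m[, -1] <- stats::rnorm(config$n_genes * (config$batch_count - 1),
                              0, config$batch_sd)
    m
  })
  drivers <- gene_driver_matrix(truth, config)
  beta <- truth$genes$beta
  disp <- config$nb_dispersion

  counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(metadata),
                   dimnames = list(truth$genes$gene, metadata$sample))
  for (j in seq_len(nrow(metadata))) {
    s <- metadata$strain[j]
    b <- as.integer(sub("batch", "", metadata$batch[j]))
    mu <- baseline * 2^(beta * drivers[, s] + batch_eff[, b])
    counts[, j] <- as.integer(with_seed(
      derive_seed(config$seed, "rnaseq", s, metadata$replicate[j]),
      if (disp < 1e-12) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
    ))
  }
  list(counts = counts, metadata = metadata)
}

#' Generate a complete synthetic study cohort
#'
#' Produces every input the analysis pipeline consumes -- individual-level
#' survival records for the lifespan and stress assays, an RNA-seq count
#' matrix with sample metadata, reference gene sets in GMT form derived from
#' the planted modules, and the ground truth itself. The same configuration
#' and seed always yield identical output: every randomized arm draws from
#' its own stream whose seed is a hash of the master seed and the arm's
#' identity, so generation order is irrelevant.
#'
#' @param config a [sim_config()].
#' @return an object of class `stress_cohort`: list with `survival` (strain,
#'   assay, replicate, animal_id, time, event, control_group), `counts`,
#'   `metadata`, `gene_sets` (named list of gene-id vectors), `truth`
#'   ([cohort_truth()]) and `config`.
#' @examples
#' cfg <- sim_config(n_mutant_strains = 3, n_genes = 50,
#'                   module_sizes = c(shared_driver = 5, lifespan_only = 5,
#'                                    stress_specific = 2),
#'                   n_worms_per_assay_arm = 20, alt_control_strain = NULL)
#' cohort <- generate_cohort(cfg)
#' table(cohort$survival$assay)[1:3]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- cohort_truth(config)
  mutants <- names(config$strain_longevity_effects)
  alt <- config$alt_control_strain
  control_of <- function(strain) {
    if (!is.null(alt) && strain %in% c(alt, "wildtype_25C")) "wildtype_25C"
    else "wildtype"
  }

  n <- config$n_worms_per_assay_arm
  reps <- rep_len(seq_len(config$n_survival_replicates), n)
  survival <- do.call(rbind, lapply(config$assays, function(a) {
    do.call(rbind, lapply(rownames(truth$traits), function(s) {
      scale <- truth$expected$scale[truth$expected$strain == s &
                                      truth$expected$assay == a$id]
      rec <- generate_survival_times(
        scale, n, censor_rate = config$censor_rate,
        seed = derive_seed(config$seed, "survival", a$id, s),
        shape = config$weibull_shape
      )
      data.frame(strain = s, assay = a$id, replicate = reps,
                 animal_id = sprintf("%s_%s_%04d", s, a$id, seq_len(n)),
                 time = rec$time, event = rec$event,
                 control_group = control_of(s), row.names = NULL)
    }))
  }))
  rownames(survival) <- NULL

  stress_ids <- setdiff(colnames(truth$traits), "lifespan")
  module <- truth$genes$module
  gene_sets <- c(
    list(shared_robustness_targets =
           truth$genes$gene[module == "shared_driver"],
         lifespan_reference =
           truth$genes$gene[module %in% c("shared_driver", "lifespan_only")]),
    stats::setNames(
      lapply(stress_ids, function(a)
        truth$genes$gene[module == paste0("stress_specific:", a)]),
      paste0("specific_", stress_ids, "_targets")
    )
  )

  expr <- generate_expression_counts(truth, config)
  structure(
    list(survival = survival, counts = expr$counts,
         metadata = expr$metadata, gene_sets = gene_sets,
         truth = truth, config = config),
    class = "stress_cohort"
  )
}

#' @export
print.stress_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d strains, %d assays, %d x %d counts\n",
              nrow(x$truth$traits), length(x$config$assays),
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a cohort to its on-disk interchange formats
#'
#' Writes `survival.tsv`, `counts.tsv`, `metadata.tsv`, `gene_sets.gmt` and
#' `truth.json` into `dir`. These are the files [run_all()] reads back.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stress_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(survival = file.path(dir, "survival.tsv"),
             counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_survival(cohort$survival, paths[["survival"]])
  write_counts(cohort$counts, cohort$metadata,
               paths[["counts"]], paths[["metadata"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  jsonlite::write_json(
    list(genes = cohort$truth$genes,
         traits = as.data.frame(cohort$truth$traits),
         strains = rownames(cohort$truth$traits),
         expected = cohort$truth$expected),
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}
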