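#' Configuration for an end-to-end pipeline run
#'
#' Bundles the input paths, the assay panel and the statistical settings of a
#' full analysis. All referenced paths must exist when the run starts.
#'
#' @param survival_path individual-level survival table (see
#'   [read_survival()]).
#' @param counts_path,metadata_path count matrix and sample metadata (see
#'   [read_counts()]).
#' @param pathway_gmt GMT file of stress-response pathway target sets, or
#'   `NULL` to skip the pathway-enrichment stage.
#' @param assays assay panel ([default_assay_panel()] by default).
#' @param alpha significance level for direction calls and correlation
#'   significance.
#' @param fdr FDR threshold for differential expression.
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param correlation_criterion gate gene-phenotype significance on raw
#'   `"p"` or BH `"q"`.
#' @param summary_mode expression summary for correlations: `"lfc"`
#'   (fold-change versus matched control) or `"log2_mean"`.
#' @param universe optional explicit gene universe (character vector or path
#'   to a one-id-per-line file); default: genes passing the expression
#'   filter.
#' @param resistance_policy passed to [resistance_count()].
#' @param seed recorded seed (the analysis itself is deterministic; the seed
#'   is echoed so simulation + analysis runs are fully reproducible).
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(survival_path, counts_path, metadata_path,
                       pathway_gmt = NULL,
                       assays = default_assay_panel(),
                       alpha = 0.05, fdr = 0.01,
                       correlation_method = c("pearson", "spearman"),
                       correlation_criterion = c("p", "q"),
                       summary_mode = c("lfc", "log2_mean"),
                       universe = NULL,
                       resistance_policy = c("any", "both"),
                       seed = 1L, out_dir = tempfile("stresspan_run_")) {
  for (p in c(survival_path, counts_path, metadata_path, pathway_gmt)) {
    if (!is.null(p) && !file.exists(p)) stopf("input path does not exist: %s", p)
  }
  assert_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  assert_number(fdr, "fdr", min = 1e-12, max = 1 - 1e-12)
  structure(
    list(survival_path = survival_path, counts_path = counts_path,
         metadata_path = metadata_path, pathway_gmt = pathway_gmt,
         assays = assays, alpha = alpha, fdr = fdr,
         correlation_method = match.arg(correlation_method),
         correlation_criterion = match.arg(correlation_criterion),
         summary_mode = match.arg(summary_mode),
         universe = universe,
         resistance_policy = match.arg(resistance_policy),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

write_tsv6 <- function(df, path) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- signif(df[[col]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stress-resistance / longevity pipeline
#'
#' Orchestrates every stage on the supplied inputs: strain phenotype table
#' (endpoints, direction calls, combined score, resistance count),
#' phenotype-lifespan regressions, per-strain differential expression with
#' batch adjustment, stress-pathway target enrichment of upregulated genes,
#' per-stressor gene-phenotype correlation (positive and negative significant
#' sets, exported as GMT), multi-stressor membership counts, and the overlap
#' of stress-correlated with lifespan-correlated genes. All tables are
#' written tab-delimited under `config$out_dir` together with a
#' machine-readable `summary.json` and a run log; a rerun with the same
#' config and inputs reproduces the summary byte for byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every stage's result (`phenotypes`,
#'   `regressions`, `de`, `pathway_enrichment`, `correlations`,
#'   `correlated_sets`, `multiplicity`, `stress_lifespan_overlap`,
#'   `universe`, `files`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  note("stresspan %s | R %s | seed %d",
       as.character(utils::packageVersion("stresspan")),
       paste(R.version$major, R.version$minor, sep = "."), config$seed)

  inputs <- stage("read_inputs", {
    survival <- read_survival(config$survival_path)
    cm <- read_counts(config$counts_path, config$metadata_path)
    pathways <- if (!is.null(config$pathway_gmt)) read_gmt(config$pathway_gmt)
    list(survival = survival, counts = cm$counts, metadata = cm$metadata,
         pathways = pathways)
  })
  note("inputs: %d survival records, %d genes x %d samples",
       nrow(inputs$survival), nrow(inputs$counts), ncol(inputs$counts))

  phenotypes <- stage("phenotypes",
    phenotype_table(inputs$survival, config$assays, alpha = config$alpha,
                    resistance_policy = config$resistance_policy))
  regressions <- stage("regressions",
    phenotype_lifespan_correlations(phenotypes))

  control_map <- vapply(
    split(inputs$survival$control_group, inputs$survival$strain),
    function(x) unique(x)[1], character(1))
  mutants <- phenotypes$strains$strain

  universe <- stage("universe", {
    if (is.null(config$universe)) {
      expression_universe(inputs$counts, inputs$metadata)
    } else if (length(config$universe) == 1 && file.exists(config$universe)) {
      readLines(config$universe)
    } else as.character(config$universe)
  })
  note("gene universe: %d genes", length(universe))

  de <- stage("differential_expression", {
    res <- lapply(mutants, function(s)
      de_test(inputs$counts, inputs$metadata, s, control_map[[s]],
              batch = TRUE, fdr = config$fdr))
    names(res) <- mutants
    res
  })
  for (s in mutants) {
    sets <- de_direction_sets(de[[s]])
    note("DE %s: %d up, %d down (FDR %g)", s, length(sets$up),
         length(sets$down), config$fdr)
  }

  pathway_enrichment <- if (!is.null(inputs$pathways)) {
    stage("pathway_enrichment", {
      up_sets <- lapply(de, function(d)
        intersect(de_direction_sets(d)$up, universe))
      pathway_target_enrichment(up_sets, inputs$pathways, universe)
    })
  }

  summaries <- stage("expression_summaries",
    strain_expression_summary(inputs$counts, inputs$metadata,
                              mode = config$summary_mode,
                              control_map = control_map))
  summaries <- summaries[intersect(rownames(summaries), universe), ,
                         drop = FALSE]

  stress_assays <- setdiff(unique(phenotypes$calls$assay), "lifespan")
  phen_vectors <- c(
    stats::setNames(lapply(stress_assays, function(aid) {
      sub <- phenotypes$calls[phenotypes$calls$assay == aid, ]
      stats::setNames(sub$endpoint, sub$strain)
    }), stress_assays),
    list(lifespan = stats::setNames(
      phenotypes$strains$lifespan_extension_pct, phenotypes$strains$strain))
  )
  correlations <- stage("gene_phenotype_correlation", {
    lapply(phen_vectors, function(v)
      suppressWarnings(gene_phenotype_correlation(
        summaries, v, method = config$correlation_method,
        alpha = config$alpha, criterion = config$correlation_criterion)))
  })
  correlated_sets <- list()
  for (ph in names(correlations)) {
    tab <- correlations[[ph]]
    correlated_sets[[paste0(ph, "_pos")]] <-
      tab$gene[tab$significant & tab$direction == "positive"]
    correlated_sets[[paste0(ph, "_neg")]] <-
      tab$gene[tab$significant & tab$direction == "negative"]
    note("correlated with %s: %d positive, %d negative", ph,
         length(correlated_sets[[paste0(ph, "_pos")]]),
         length(correlated_sets[[paste0(ph, "_neg")]]))
  }

  multiplicity <- stage("multiplicity",
    multiplicity_counts(correlated_sets[paste0(stress_assays, "_pos")]))

  overlap <- stage("stress_lifespan_overlap", {
    life_pos <- correlated_sets[["lifespan_pos"]]
    rows <- lapply(stress_assays, function(aid) {
      ov <- overlap_stats(correlated_sets[[paste0(aid, "_pos")]],
                          life_pos, universe)
      data.frame(stressor = aid, n_stress = ov$n_a, n_lifespan = ov$n_b,
                 observed = ov$observed, expected = ov$expected,
                 ratio = ov$ratio, p_value = ov$p_value,
                 percent_overlap = ov$percent_overlap)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  files <- c(
    phenotypes = write_tsv6(phenotypes$strains,
                            file.path(config$out_dir, "phenotypes.tsv")),
    calls = write_tsv6(phenotypes$calls,
                       file.path(config$out_dir, "phenotype_calls.tsv")),
    regressions = write_tsv6(regressions,
                             file.path(config$out_dir, "regressions.tsv")),
    multiplicity = write_tsv6(multiplicity,
                              file.path(config$out_dir, "multiplicity.tsv")),
    overlap = write_tsv6(overlap,
                         file.path(config$out_dir,
                                   "stress_lifespan_overlap.tsv")),
    correlated_sets = write_gmt(correlated_sets,
                                file.path(config$out_dir,
                                          "correlated_sets.gmt"))
  )
  for (s in mutants) {
    files[[paste0("de_", s)]] <-
      write_tsv6(de[[s]], file.path(config$out_dir,
                                    sprintf("de_%s.tsv", s)))
  }
  for (ph in names(correlations)) {
    files[[paste0("corr_", ph)]] <-
      write_tsv6(correlations[[ph]],
                 file.path(config$out_dir, sprintf("correlated_%s.tsv", ph)))
  }
  if (!is.null(pathway_enrichment)) {
    files[["pathway_enrichment"]] <-
      write_tsv6(pathway_enrichment,
                 file.path(config$out_dir, "pathway_enrichment.tsv"))
  }

  summary <- list(
    package = as.character(utils::packageVersion("stresspan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = list(
      survival_path = config$survival_path,
      counts_path = config$counts_path,
      metadata_path = config$metadata_path,
      pathway_gmt = config$pathway_gmt,
      alpha = config$alpha, fdr = config$fdr,
      correlation_method = config$correlation_method,
      correlation_criterion = config$correlation_criterion,
      summary_mode = config$summary_mode,
      resistance_policy = config$resistance_policy
    ),
    n_strains = length(mutants),
    n_genes_universe = length(universe),
    phenotypes = phenotypes$strains,
    regressions = regressions,
    n_correlated = lapply(correlated_sets, length),
    multiplicity = multiplicity,
    stress_lifespan_overlap = overlap
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, digits = NA, auto_unbox = TRUE)
  files[["summary"]] <- summary_path
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  files[["log"]] <- file.path(config$out_dir, "run.log")
  note("run complete: %d output files in %s", length(files), config$out_dir)

  invisible(list(phenotypes = phenotypes, regressions = regressions, de = de,
                 pathway_enrichment = pathway_enrichment,
                 correlations = correlations,
                 correlated_sets = correlated_sets,
                 multiplicity = multiplicity,
                 stress_lifespan_overlap = overlap,
                 universe = universe, files = files))
}
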