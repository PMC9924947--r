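#' Simple linear regression with R-squared and slope test
#'
#' Ordinary least squares of `y` on `x`; the two-sided slope p-value comes
#' from the t distribution on n - 2 degrees of freedom. A constant response
#' yields slope 0, R-squared 0 and p = 1 (no evidence of association).
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must vary.
#' @return object of class `regression_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1, R^2 = 1
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("linear_fit needs at least 3 complete pairs")
  if (stats::var(x) == 0) stopf("'x' is constant; slope undefined")
  if (stats::var(y) == 0) {
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, n = n), class = "regression_fit"))
  }
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  se <- sqrt(sse / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope %.4g, intercept %.4g, R^2 %.4f, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regress lifespan extension on each stress phenotype across strains
#'
#' One simple linear regression per phenotype -- every stress-assay endpoint,
#' every relative score, the combined stress score and the resistance count --
#' with lifespan extension (%) as the response. Phenotypes with fewer than 3
#' complete strain pairs are skipped with a warning.
#'
#' @param phenotypes a [phenotype_table()] result, or a data.frame with a
#'   `lifespan_extension_pct` column plus phenotype columns.
#' @param phenotype_cols for the data.frame form, which columns to regress
#'   (default: all numeric columns except the lifespan ones).
#' @return data.frame: phenotype, slope, intercept, r_squared, p_value, n.
#' @export
phenotype_lifespan_correlations <- function(phenotypes,
                                            phenotype_cols = NULL) {
  if (inherits(phenotypes, "strain_phenotypes")) {
    wide <- phenotypes$strains[, c("strain", "lifespan_extension_pct",
                                   "combined_score", "resistance_count")]
    for (aid in setdiff(unique(phenotypes$calls$assay), "lifespan")) {
      sub <- phenotypes$calls[phenotypes$calls$assay == aid, ]
      wide[[paste0("endpoint_", aid)]] <-
        sub$endpoint[match(wide$strain, sub$strain)]
    }
    df <- wide
    phenotype_cols <- setdiff(names(df), c("strain", "lifespan_extension_pct"))
  } else {
    df <- as.data.frame(phenotypes)
    if (!"lifespan_extension_pct" %in% names(df))
      stopf("phenotype table lacks 'lifespan_extension_pct'")
    phenotype_cols <- phenotype_cols %||%
      setdiff(names(df)[vapply(df, is.numeric, logical(1))],
              "lifespan_extension_pct")
  }
  out <- lapply(phenotype_cols, function(col) {
    x <- df[[col]]
    y <- df$lifespan_extension_pct
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warnf("phenotype '%s': fewer than 3 complete pairs; skipped", col)
      return(NULL)
    }
    fit <- linear_fit(x[ok], y[ok])
    data.frame(phenotype = col, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-strain expression summaries for cross-strain correlation
#'
#' Either the per-strain mean of `log2(normalized count + 1)` over replicates
#' (`"log2_mean"`), or that summary minus the matched control's summary
#' (`"lfc"`, the default), which respects strains measured against an
#' alternate-temperature control. Counts are normalized by median-of-ratios
#' size factors unless factors are supplied.
#'
#' @param counts gene x sample count matrix.
#' @param metadata data.frame with `sample`, `strain` columns covering every
#'   count column.
#' @param mode `"lfc"` or `"log2_mean"`.
#' @param control_map named character vector strain -> control strain;
#'   required for `"lfc"`.
#' @param sf optional per-sample size factors (named by sample).
#' @param pseudocount added before log2.
#' @return gene x strain matrix of expression summaries (mutant strains only
#'   in `"lfc"` mode).
#' @export
strain_expression_summary <- function(counts, metadata,
                                      mode = c("lfc", "log2_mean"),
                                      control_map = NULL, sf = NULL,
                                      pseudocount = 1) {
  mode <- match.arg(mode)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  logn <- log2(norm + pseudocount)
  strains <- unique(metadata$strain)
  summ <- vapply(strains, function(s) {
    cols <- metadata$sample[metadata$strain == s]
    rowMeans(logn[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  colnames(summ) <- strains
  if (mode == "log2_mean") return(summ)
  if (is.null(control_map))
    stopf("mode 'lfc' requires a strain -> control map")
  mutants <- setdiff(strains, unique(unname(control_map)))
  lfc <- vapply(mutants, function(s) {
    ctl <- control_map[[s]]
    if (is.null(ctl) || !ctl %in% colnames(summ))
      stopf("no control summary for strain '%s'", s)
    summ[, s] - summ[, ctl]
  }, numeric(nrow(counts)))
  colnames(lfc) <- mutants
  lfc
}

#' Correlate each gene's expression summary with a phenotype across strains
#'
#' Pearson (default) or Spearman correlation of one expression summary per
#' strain against a strain-level phenotype, with two-sided p-values from the
#' t distribution on n - 2 degrees of freedom and Benjamini-Hochberg q-values
#' across genes. Genes with zero expression variance across strains are
#' excluded and reported in the `excluded` attribute.
#'
#' @param expr gene x strain matrix of expression summaries.
#' @param phenotype named numeric vector of strain phenotype values; names
#'   must match `colnames(expr)` (order-free).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance threshold.
#' @param criterion gate significance on raw `"p"` (default; appropriate when
#'   downstream analyses consume the correlated-gene lists as broad sets) or
#'   on BH `"q"`.
#' @return data.frame (gene, r, r_squared, p, q, direction, significant) with
#'   attribute `excluded` (zero-variance gene ids).
#' @export
gene_phenotype_correlation <- function(expr, phenotype,
                                       method = c("pearson", "spearman"),
                                       alpha = 0.05,
                                       criterion = c("p", "q")) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  assert_number(alpha, "alpha", min = 1e-300, max = 1 - 1e-12)
  if (is.null(names(phenotype)) || is.null(colnames(expr)))
    stopf("both 'expr' columns and 'phenotype' must be named by strain")
  common <- intersect(colnames(expr), names(phenotype))
  if (length(common) < 4)
    stopf("need at least 4 strains with both expression and phenotype")
  x <- expr[, common, drop = FALSE]
  y <- phenotype[common]
  if (stats::var(y) == 0) stopf("phenotype is constant across strains")
  if (method == "spearman") {
    x <- t(apply(x, 1, rank))
    y <- rank(y)
  }
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  ssx <- rowSums(xc^2)
  excluded <- rownames(x)[ssx == 0]
  keep <- ssx > 0
  r <- as.vector(xc[keep, , drop = FALSE] %*% yc) /
    sqrt(ssx[keep] * sum(yc^2))
  r <- pmin(pmax(r, -1), 1)
  n <- length(common)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = rownames(x)[keep], r = r, r_squared = r^2, p = p, q = q,
    direction = ifelse(r >= 0, "positive", "negative"),
    significant = (if (criterion == "p") p else q) < alpha,
    row.names = NULL
  )
  attr(out, "excluded") <- excluded
  attr(out, "n_strains") <- n
  if (length(excluded))
    warnf("%d gene(s) with zero variance across strains excluded",
          length(excluded))
  out
}

#' How many genes belong to exactly k of the supplied sets
#'
#' Decomposes a collection of gene sets (e.g. genes significantly correlated
#' with each stressor) into exact-multiplicity counts: how many genes appear
#' in exactly one set, exactly two, and so on. Counts sum to the size of the
#' union.
#'
#' @param sets named list of character vectors.
#' @return data.frame with columns `k` and `n_genes`, one row per observed
#'   multiplicity; attribute `members` holds the gene -> k map.
#' @examples
#' multiplicity_counts(list(a = c("g1", "g2"), b = "g2"))
#' @export
multiplicity_counts <- function(sets) {
  if (length(sets) == 0)
    return(data.frame(k = integer(0), n_genes = integer(0)))
  members <- table(unlist(lapply(sets, unique)))
  tab <- table(factor(as.vector(members), levels = seq_len(length(sets))))
  out <- data.frame(k = as.integer(names(tab)), n_genes = as.integer(tab))
  out <- out[out$n_genes > 0 | out$k <= length(sets), , drop = FALSE]
  attr(out, "members") <- members
  out
}
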