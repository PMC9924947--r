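#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples, using only genes with nonzero counts
#' in every sample. Multiplying one sample's counts by a constant multiplies
#' its factor by the same constant. When no gene is nonzero everywhere the
#' function falls back to upper-quartile normalization with a warning.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return named positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    warnf("no gene has nonzero counts in all samples; using upper-quartile normalization")
    uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75))
    if (any(!is.finite(uq)) || any(uq <= 0))
      stopf("cannot compute size factors: empty samples")
    return(uq / exp(mean(log(uq))))
  }
  log_geo <- rowMeans(log(counts[all_nonzero, , drop = FALSE]))
  sf <- apply(counts[all_nonzero, , drop = FALSE], 2, function(x)
    exp(stats::median(log(x) - log_geo)))
  sf
}

#' Normalize counts by size factors
#'
#' @param counts gene x sample matrix.
#' @param sf size factors (default: [size_factors()] of `counts`).
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Default expression universe: genes passing the detection filter
#'
#' A gene is kept when its mean normalized count is at least `min_mean` in at
#' least one strain. The resulting gene list is the default universe for the
#' overlap-enrichment stage.
#'
#' @param counts gene x sample count matrix.
#' @param metadata sample metadata with `sample` and `strain`.
#' @param min_mean detection threshold on the normalized scale.
#' @return character vector of detected gene ids.
#' @export
expression_universe <- function(counts, metadata, min_mean = 1) {
  norm <- normalize_counts(counts)
  strains <- unique(metadata$strain)
  strain_means <- vapply(strains, function(s) {
    cols <- metadata$sample[metadata$strain == s]
    rowMeans(norm[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(counts)[apply(strain_means, 1, max) >= min_mean]
}

# Vectorized Welch t across the rows of two matrices.
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(t), df = df)
  zero <- se2 == 0
  p[zero & ma == mb] <- 1
  p[zero & ma != mb] <- 0
  list(lfc = ma - mb, t = t, p = p)
}

#' Differential expression between a mutant and its matched control
#'
#' A deliberately simple per-gene test on `log2(normalized count +
#' pseudocount)`: Welch's t-test between the two strains, or -- with the
#' batch flag -- the strain coefficient of an additive linear model
#' `expression ~ strain + batch`, fitted to all genes at once through a
#' single QR decomposition. On the linear-model path, residual variances are
#' shrunk toward a common prior by empirical Bayes (limma's `squeezeVar`),
#' the standard stabilization for a handful of replicates; set
#' `moderate = FALSE` for ordinary per-gene statistics. Benjamini-Hochberg
#' q-values across genes; significance is gated on q alone at the configured
#' FDR (no fold-change cutoff). This stage does not attempt
#' negative-binomial shrinkage; use [import_external_de()] to substitute
#' output from a dedicated count-model tool when available.
#'
#' @param counts gene x sample count matrix.
#' @param metadata sample metadata with `sample`, `strain`, `batch`.
#' @param strain mutant strain id.
#' @param control control strain id.
#' @param batch adjust for batch as an additive covariate (default `TRUE`;
#'   ignored with a message when the selected samples share one batch).
#' @param fdr significance threshold on q (default 0.01).
#' @param pseudocount added on the normalized scale before log2.
#' @param moderate empirical-Bayes variance moderation on the linear-model
#'   path (default `TRUE`; the Welch path is always unmoderated).
#' @return data.frame of class `de_result`: gene, log2fc (mutant vs
#'   control), p, q, significant.
#' @export
de_test <- function(counts, metadata, strain, control, batch = TRUE,
                    fdr = 0.01, pseudocount = 1, moderate = TRUE) {
  assert_number(fdr, "fdr", min = 1e-12, max = 1 - 1e-12)
  sel <- metadata$strain %in% c(strain, control)
  meta <- metadata[sel, , drop = FALSE]
  if (!strain %in% meta$strain || !control %in% meta$strain)
    stopf("strain '%s' or control '%s' absent from metadata", strain, control)
  if (min(table(meta$strain)) < 2)
    stopf("need at least 2 replicates per arm")
  sf <- size_factors(counts)
  logn <- log2(sweep(counts[, meta$sample, drop = FALSE], 2,
                     sf[meta$sample], "/") + pseudocount)
  is_mut <- meta$strain == strain

  if (batch && length(unique(meta$batch)) < 2) {
    message("de_test: only one batch present; batch covariate dropped")
    batch <- FALSE
  }
  if (!batch) {
    res <- welch_rows(logn[, is_mut, drop = FALSE],
                      logn[, !is_mut, drop = FALSE])
    lfc <- res$lfc; p <- res$p
  } else {
    design <- stats::model.matrix(~ mut + bat, data.frame(
      mut = as.integer(is_mut), bat = factor(meta$batch)))
    qr_d <- qr(design)
    coefs <- t(qr.coef(qr_d, t(logn)))
    fitted <- coefs %*% t(design)
    rss <- rowSums((logn - fitted)^2)
    df_res <- nrow(design) - qr_d$rank
    xtx_inv <- chol2inv(qr.R(qr_d))
    s2 <- rss / df_res
    df_t <- df_res
    if (moderate) {
      sq <- limma::squeezeVar(s2, df_res)
      s2 <- sq$var.post
      df_t <- df_res + min(sq$df.prior, 1e6)
    }
    se <- sqrt(s2 * xtx_inv[2, 2])
    lfc <- coefs[, "mut"]
    t <- lfc / se
    p <- 2 * stats::pt(-abs(t), df = df_t)
    p[se == 0 & lfc == 0] <- 1
    p[se == 0 & lfc != 0] <- 0
  }
  q <- bh_adjust(p)
  out <- data.frame(gene = rownames(counts), log2fc = unname(lfc),
                    p = unname(p), q = unname(q),
                    significant = unname(q < fdr), row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  attr(out, "fdr") <- fdr
  out
}

#' Split a DE table into up- and downregulated significant gene sets
#'
#' @param de a [de_test()] or [import_external_de()] result.
#' @return list with `up` and `down` character vectors.
#' @export
de_direction_sets <- function(de) {
  list(up = de$gene[de$significant & de$log2fc > 0],
       down = de$gene[de$significant & de$log2fc < 0])
}

#' Import an externally computed differential-expression table
#'
#' Reads a delimited DE table (e.g. from a dedicated negative-binomial count
#' model) and validates it into the same structure [de_test()] emits. When
#' only raw p-values are present, q-values are recomputed by
#' Benjamini-Hochberg.
#'
#' @param path tab-delimited file with a header row.
#' @param columns named mapping from required fields (`gene`, `lfc`, and `p`
#'   and/or `q`) to column names in the file.
#' @param fdr significance threshold applied to q.
#' @return a `de_result` data.frame (gene, log2fc, p, q, significant).
#' @export
import_external_de <- function(path,
                               columns = c(gene = "gene", lfc = "log2fc",
                                           p = "p", q = "q"),
                               fdr = 0.01) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "lfc")
  missing_map <- setdiff(need, names(columns))
  if (length(missing_map))
    stopf("column mapping lacks: %s", paste(missing_map, collapse = ", "))
  have <- intersect(names(columns), names(columns)[columns %in% names(tab)])
  absent <- setdiff(columns[need], names(tab))
  if (length(absent))
    stopf("DE table lacks column(s): %s", paste(absent, collapse = ", "))
  if (!any(c("p", "q") %in% have))
    stopf("DE table needs a '%s' or '%s' column",
          columns[["p"]] %||% "p", columns[["q"]] %||% "q")
  get_num <- function(field) {
    raw <- tab[[columns[[field]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stopf("malformed numeric in column '%s', row(s): %s",
            columns[[field]], paste(utils::head(bad, 5), collapse = ", "))
    val
  }
  lfc <- get_num("lfc")
  p <- if ("p" %in% have) get_num("p") else rep(NA_real_, nrow(tab))
  q <- if ("q" %in% have) get_num("q") else bh_adjust(p)
  out <- data.frame(gene = as.character(tab[[columns[["gene"]]]]),
                    log2fc = lfc, p = p, q = q,
                    significant = q < fdr, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  attr(out, "fdr") <- fdr
  out
}

#' Write a DE table to tab-delimited text
#'
#' @param de a `de_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
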