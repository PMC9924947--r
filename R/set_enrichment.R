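#' Expected overlap of two random gene sets
#'
#' If two sets of sizes `nA` and `nB` are drawn at random from a universe of
#' `N` genes, the expected number of shared genes is `nA * nB / N`.
#'
#' @param n_a,n_b set sizes.
#' @param n_universe universe size (> 0).
#' @return expected overlap (real).
#' @examples
#' expected_overlap(10, 20, 100)  # 2
#' @export
expected_overlap <- function(n_a, n_b, n_universe) {
  n_universe <- assert_count(n_universe, "n_universe")
  n_a <- assert_count(n_a, "n_a", min = 0L)
  n_b <- assert_count(n_b, "n_b", min = 0L)
  if (n_a > n_universe || n_b > n_universe)
    stopf("set sizes cannot exceed the universe size")
  n_a * n_b / n_universe
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` shared genes between a set of size
#' `n_k` and a set of size `n_draw` drawn from a universe of `n_universe`
#' genes. Computed through the hypergeometric distribution function, which
#' works in log space internally and is stable for universes of 2e4 genes and
#' far beyond. `k = 0` gives 1; `k` above `min(n_k, n_draw)` is an impossible
#' event with probability 0.
#'
#' @param k observed overlap.
#' @param n_universe universe size N.
#' @param n_k size of the first set (successes in the universe).
#' @param n_draw size of the second set (draws).
#' @return `P(X >= k)`.
#' @examples
#' hypergeom_pvalue(5, 10, 5, 5)  # 1/252
#' @export
hypergeom_pvalue <- function(k, n_universe, n_k, n_draw) {
  n_universe <- assert_count(n_universe, "n_universe")
  k <- assert_count(k, "k", min = 0L)
  n_k <- assert_count(n_k, "n_k", min = 0L)
  n_draw <- assert_count(n_draw, "n_draw", min = 0L)
  if (n_k > n_universe || n_draw > n_universe)
    stopf("inconsistent parameters: set sizes exceed universe")
  if (k > min(n_k, n_draw)) return(0)
  if (k == 0) return(1)
  stats::phyper(k - 1, n_k, n_universe - n_k, n_draw, lower.tail = FALSE)
}

#' Observed/expected overlap statistics for two gene sets
#'
#' The workhorse of overlap enrichment: observed overlap, the overlap
#' expected for random sets of the same sizes, their ratio (fold
#' enrichment), the upper-tail hypergeometric p-value, and percent overlap.
#' Percent overlap uses set `a` as the reference denominator
#' (`100 * k / |a|`); all other fields are symmetric in the two sets.
#'
#' @param a,b character vectors of gene ids (the reference set first).
#' @param universe character vector of all eligible genes; both sets must be
#'   contained in it.
#' @return object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_universe`, `observed`, `expected`, `ratio`, `p_value`,
#'   `percent_overlap`.
#' @export
overlap_stats <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  out_a <- setdiff(a, universe)
  out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b))
    stopf("set members outside the universe: %s",
          paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  k <- length(intersect(a, b))
  exp_k <- expected_overlap(length(a), length(b), length(universe))
  structure(
    list(n_a = length(a), n_b = length(b), n_universe = length(universe),
         observed = k, expected = exp_k,
         ratio = if (exp_k > 0) k / exp_k else NA_real_,
         p_value = hypergeom_pvalue(k, length(universe), length(a),
                                    length(b)),
         percent_overlap = if (length(a) > 0) 100 * k / length(a)
                           else NA_real_),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d observed vs %.2f expected (O/E %.2f, %s%.4g), %.1f%% of reference\n",
    x$observed, x$expected, x$ratio, "p = ", x$p_value, x$percent_overlap))
  invisible(x)
}

#' Stress-response pathway target enrichment per strain
#'
#' For every (strain, pathway) pair, compares a strain's differentially
#' expressed genes (of one direction of change) against the pathway's target
#' gene set: observed and expected overlap, observed/expected fold
#' enrichment, hypergeometric p-value, and significance stars at 0.05 / 0.01
#' / 0.001. Rows with an empty DE set are kept but flagged (`ratio` NA).
#'
#' @param de_sets named list: strain -> character vector of DE gene ids
#'   (same direction across the table, typically upregulated).
#' @param pathway_sets named list: pathway -> target gene ids.
#' @param universe character vector of all detected genes.
#' @return data.frame with one row per strain x pathway.
#' @export
pathway_target_enrichment <- function(de_sets, pathway_sets, universe) {
  if (length(pathway_sets) == 0 || length(de_sets) == 0)
    return(data.frame())
  rows <- list()
  for (s in names(de_sets)) {
    for (pw in names(pathway_sets)) {
      de <- intersect(de_sets[[s]], universe)
      if (length(de) == 0) {
        rows[[paste(s, pw)]] <- data.frame(
          strain = s, pathway = pw, n_de = 0L,
          n_pathway = length(intersect(pathway_sets[[pw]], universe)),
          observed = NA_integer_, expected = NA_real_, ratio = NA_real_,
          p_value = NA_real_, stars = NA_character_, flag = "empty_de_set")
        next
      }
      ov <- overlap_stats(de, intersect(pathway_sets[[pw]], universe),
                          universe)
      rows[[paste(s, pw)]] <- data.frame(
        strain = s, pathway = pw, n_de = ov$n_a, n_pathway = ov$n_b,
        observed = ov$observed, expected = ov$expected, ratio = ov$ratio,
        p_value = ov$p_value, stars = p_stars(ov$p_value), flag = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Over-representation analysis of a query set against a term map
#'
#' Flat ORA: for each term, the one-sided hypergeometric p-value of the
#' query/term overlap (identical to the one-sided Fisher exact tail),
#' Benjamini-Hochberg q-values across terms, and observed/expected fold
#' enrichment. Term members outside the universe are ignored; no term
#' hierarchy is used.
#'
#' @param term_map named list: term -> member gene ids.
#' @param query character vector of query gene ids, contained in `universe`.
#' @param universe character vector of all eligible genes.
#' @param depletion test the lower tail (under-representation) instead.
#' @return data.frame (term, n_term, observed, expected, ratio, p, q) sorted
#'   by p; empty for an empty term map.
#' @export
ora <- function(term_map, query, universe, depletion = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stopf("query genes outside the universe")
  if (length(term_map) == 0)
    return(data.frame(term = character(0), n_term = integer(0),
                      observed = integer(0), expected = numeric(0),
                      ratio = numeric(0), p = numeric(0), q = numeric(0)))
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(unique(term_map[[tm]]), universe)
    k <- length(intersect(members, query))
    exp_k <- expected_overlap(length(members), length(query),
                              length(universe))
    p <- if (depletion) {
      stats::phyper(k, length(members), length(universe) - length(members),
                    length(query))
    } else {
      hypergeom_pvalue(k, length(universe), length(members), length(query))
    }
    data.frame(term = tm, n_term = length(members), observed = k,
               expected = exp_k,
               ratio = if (exp_k > 0) k / exp_k else NA_real_, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving and never below
#' the raw p-value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
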