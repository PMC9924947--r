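#' Percent lifespan extension of a mutant over its control
#'
#' @param mutant_mean mutant mean lifespan.
#' @param control_mean control mean lifespan (> 0).
#' @return `100 * (mutant_mean - control_mean) / control_mean`.
#' @examples
#' lifespan_extension(47.68, 20)  # 138.4
#' @export
lifespan_extension <- function(mutant_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0))
    stopf("control mean lifespan must be positive")
  100 * (mutant_mean - control_mean) / control_mean
}

#' Classify a strain's response to one assay
#'
#' `increased` iff the mutant endpoint exceeds the control endpoint with
#' p below `alpha`; `decreased` for the significant opposite direction;
#' `unchanged` otherwise.
#'
#' @param endpoint_mutant,endpoint_control endpoint values.
#' @param p comparison p-value.
#' @param alpha significance level in (0, 1); default 0.05, matching the
#'   convention that figure asterisks start at p < 0.05.
#' @return character vector in `{"increased", "decreased", "unchanged"}`.
#' @export
direction_call <- function(endpoint_mutant, endpoint_control, p,
                           alpha = 0.05) {
  assert_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  out <- rep("unchanged", length(endpoint_mutant))
  sig <- !is.na(p) & p < alpha
  out[sig & endpoint_mutant > endpoint_control] <- "increased"
  out[sig & endpoint_mutant < endpoint_control] <- "decreased"
  out
}

#' Normalize one assay's endpoints to percent of the best strain
#'
#' The most resistant strain is set to 100% and every other strain is
#' expressed as a percentage of that maximum, making assays with different
#' units (hours survived, fraction alive) commensurable. Scale-invariant:
#' multiplying all endpoints by a positive constant leaves scores unchanged.
#'
#' @param values per-strain endpoint values for one assay.
#' @return percent-of-maximum scores (max = 100).
#' @examples
#' relative_score(c(5, 10, 20))  # 25 50 100
#' @export
relative_score <- function(values) {
  if (length(values) == 0 || all(is.na(values)))
    stopf("no endpoint values supplied")
  mx <- max(values, na.rm = TRUE)
  if (mx <= 0) stopf("relative score undefined: no strictly positive endpoint")
  100 * values / mx
}

#' Combined stress survival score
#'
#' Equal-weight mean of a strain's per-assay relative scores, keeping the
#' result on the 0-100 scale (the mean ranks strains identically to the sum).
#' Missing assays are excluded with a warning, never imputed.
#'
#' @param scores per-assay relative scores (percent) for one strain.
#' @return combined score in `[0, 100]`.
#' @export
combined_score <- function(scores) {
  if (length(scores) == 0) stopf("no assay scores supplied")
  if (anyNA(scores)) {
    warnf("combined score: %d missing assay score(s) excluded",
          sum(is.na(scores)))
    scores <- scores[!is.na(scores)]
    if (length(scores) == 0) stopf("no non-missing assay scores")
  }
  mean(scores)
}

#' Number of stressors with significantly increased survival
#'
#' Counts the stressors for which a strain's direction call is `increased`.
#' When several assays probe one stressor at different severities (e.g. two
#' NaCl concentrations), supply `stressors` to collapse them: with
#' `policy = "any"` (default) one `increased` level suffices, with `"both"`
#' every level of the stressor must be `increased`.
#'
#' @param calls character vector of direction calls.
#' @param stressors optional stressor label per call (default: each call is
#'   its own stressor).
#' @param policy `"any"` or `"both"`.
#' @return integer count of resistant stressors.
#' @export
resistance_count <- function(calls, stressors = NULL,
                             policy = c("any", "both")) {
  policy <- match.arg(policy)
  if (length(calls) == 0) return(0L)
  bad <- setdiff(calls, c("increased", "decreased", "unchanged"))
  if (length(bad)) stopf("unknown direction call: %s", bad[1])
  if (is.null(stressors)) stressors <- as.character(seq_along(calls))
  inc <- tapply(calls == "increased", stressors,
                if (policy == "any") any else all)
  sum(inc)
}

endpoint_value <- function(time, event, spec) {
  if (spec$endpoint == "fraction_alive")
    fraction_alive(time, event, spec$time)
  else mean_survival(time, event)
}

replicate_endpoints <- function(df, spec) {
  vapply(split(df, df$replicate),
         function(d) endpoint_value(d$time, d$event, spec), numeric(1))
}

#' Endpoint and significance for one strain in one assay
#'
#' Computes the assay endpoint for a mutant arm and its control arm and
#' attaches the comparison prescribed by the assay spec: log-rank or
#' Gehan-Breslow-Wilcoxon on the survival records, or a replicate-level
#' comparison (Dunnett with a single group, i.e. a t-test-like contrast, or
#' Student's t) for fixed-time proportion endpoints. Panel-wide analyses
#' should prefer [phenotype_table()], which runs Dunnett jointly across all
#' strains sharing a control.
#'
#' @param records survival records (data.frame with `strain`, `replicate`,
#'   `time`, `event`) containing both arms.
#' @param spec the [assay_spec()].
#' @param strain mutant strain id.
#' @param control control strain id.
#' @return list with `endpoint`, `control_endpoint`, `p`, `test`.
#' @export
assay_endpoint <- function(records, spec, strain, control) {
  stopifnot(inherits(spec, "assay_spec"))
  mut <- records[records$strain == strain, , drop = FALSE]
  ctl <- records[records$strain == control, , drop = FALSE]
  if (nrow(mut) == 0) stopf("no records for strain '%s'", strain)
  if (nrow(ctl) == 0)
    stopf("missing control arm '%s' for strain '%s'", control, strain)
  ep <- endpoint_value(mut$time, mut$event, spec)
  ep_ctl <- endpoint_value(ctl$time, ctl$event, spec)
  res <- switch(spec$test,
    logrank = logrank_test(mut$time, mut$event, ctl$time, ctl$event),
    gehan = gehan_wilcoxon_test(mut$time, mut$event, ctl$time, ctl$event),
    anova_dunnett = {
      fit <- anova_dunnett(replicate_endpoints(ctl, spec),
                           list(replicate_endpoints(mut, spec)))
      test_result(fit$comparisons$t[1], fit$comparisons$p_adj[1],
                  "anova_dunnett", df = fit$df[2])
    },
    t_test = students_t(replicate_endpoints(mut, spec),
                        replicate_endpoints(ctl, spec))
  )
  list(endpoint = ep, control_endpoint = ep_ctl,
       p = res$p_value, test = res)
}

#' Strain-level phenotype table for a survival study
#'
#' Turns individual-level survival records for the lifespan assay and a panel
#' of stress assays into the per-strain phenotype summary: mean lifespan and
#' percent extension over the matched control, per-assay resistance endpoints
#' with direction calls, percent-of-maximum relative scores (over mutant
#' strains), the equal-weight combined stress score, and the resistance
#' count. Fixed-time proportion assays are tested by one-way ANOVA with
#' Dunnett's comparison over replicate proportions, jointly across all
#' strains sharing the standard control; strains matched to an
#' alternate-temperature control are compared to it by Student's t-test.
#' Survival-curve assays are tested per strain by the assay's configured
#' log-rank or Gehan test against the matched control.
#'
#' @param survival data.frame with columns `strain`, `assay`, `replicate`,
#'   `time`, `event`, `control_group` (the control strain each record's
#'   strain is matched to).
#' @param assays assay panel (list of [assay_spec()] including `lifespan`).
#' @param alpha significance level for direction calls.
#' @param resistance_policy passed to [resistance_count()].
#' @return an object of class `strain_phenotypes`: list with `calls` (long
#'   per strain x assay: endpoint, control endpoint, p, call, relative
#'   score), `strains` (wide per-strain table with lifespan extension,
#'   combined score, resistance count) and `alpha`.
#' @export
phenotype_table <- function(survival, assays, alpha = 0.05,
                            resistance_policy = c("any", "both")) {
  resistance_policy <- match.arg(resistance_policy)
  needed <- c("strain", "assay", "replicate", "time", "event", "control_group")
  missing_cols <- setdiff(needed, names(survival))
  if (length(missing_cols))
    stopf("survival table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  assay_ids <- vapply(assays, `[[`, character(1), "id")
  names(assays) <- assay_ids
  if (!"lifespan" %in% assay_ids) stopf("assay panel must include 'lifespan'")

  control_map <- vapply(split(survival$control_group, survival$strain),
                        function(x) unique(x)[1], character(1))
  controls <- unique(unname(control_map))
  mutants <- setdiff(names(control_map), controls)
  for (s in mutants) {
    if (!control_map[[s]] %in% names(control_map))
      stopf("missing control arm '%s' for strain '%s'", control_map[[s]], s)
  }
  default_control <- names(which.max(table(control_map[mutants])))

  calls <- list()
  for (aid in assay_ids) {
    spec <- assays[[aid]]
    rec <- survival[survival$assay == aid, , drop = FALSE]
    if (nrow(rec) == 0) {
      warnf("assay '%s' has no records and is skipped", aid)
      next
    }
    by_strain <- split(rec, rec$strain)
    for (s in mutants) {
      if (is.null(by_strain[[s]]))
        stopf("assay '%s': no records for strain '%s'", aid, s)
      if (is.null(by_strain[[control_map[[s]]]]))
        stopf("assay '%s': missing control arm '%s' for strain '%s'",
              aid, control_map[[s]], s)
    }
    ep <- vapply(by_strain, function(d)
      endpoint_value(d$time, d$event, spec), numeric(1))

    pvals <- stats::setNames(rep(NA_real_, length(mutants)), mutants)
    stat <- pvals
    if (spec$test == "anova_dunnett") {
      joint <- mutants[control_map[mutants] == default_control]
      if (length(joint)) {
        fit <- anova_dunnett(
          replicate_endpoints(by_strain[[default_control]], spec),
          stats::setNames(lapply(joint, function(s)
            replicate_endpoints(by_strain[[s]], spec)), joint)
        )
        pvals[joint] <- fit$comparisons$p_adj
        stat[joint] <- fit$comparisons$t
      }
      for (s in setdiff(mutants, joint)) {
        res <- students_t(replicate_endpoints(by_strain[[s]], spec),
                          replicate_endpoints(by_strain[[control_map[[s]]]],
                                              spec))
        pvals[s] <- res$p_value
        stat[s] <- res$statistic
      }
    } else {
      for (s in mutants) {
        mut <- by_strain[[s]]
        ctl <- by_strain[[control_map[[s]]]]
        res <- switch(spec$test,
          logrank = logrank_test(mut$time, mut$event, ctl$time, ctl$event),
          gehan = gehan_wilcoxon_test(mut$time, mut$event,
                                      ctl$time, ctl$event),
          t_test = students_t(replicate_endpoints(mut, spec),
                              replicate_endpoints(ctl, spec))
        )
        pvals[s] <- res$p_value
        stat[s] <- res$statistic
      }
    }

    calls[[aid]] <- data.frame(
      strain = mutants, assay = aid, stressor = spec$stressor,
      endpoint = unname(ep[mutants]),
      control_endpoint = unname(ep[control_map[mutants]]),
      statistic = unname(stat), p = unname(pvals),
      call = direction_call(ep[mutants], ep[control_map[mutants]],
                            pvals, alpha),
      row.names = NULL
    )
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  stress_ids <- setdiff(unique(calls$assay), "lifespan")
  calls$relative_score <- NA_real_
  for (aid in stress_ids) {
    sel <- calls$assay == aid
    calls$relative_score[sel] <- relative_score(calls$endpoint[sel])
  }
  calls$relative_score[calls$assay == "lifespan"] <- NA_real_

  life <- calls[calls$assay == "lifespan", , drop = FALSE]
  strains <- data.frame(
    strain = life$strain,
    lifespan_mean = life$endpoint,
    control_lifespan_mean = life$control_endpoint,
    lifespan_extension_pct = lifespan_extension(life$endpoint,
                                                life$control_endpoint),
    lifespan_p = life$p,
    row.names = NULL
  )
  strains$combined_score <- vapply(strains$strain, function(s)
    combined_score(calls$relative_score[calls$strain == s &
                                          calls$assay %in% stress_ids]),
    numeric(1))
  strains$resistance_count <- vapply(strains$strain, function(s) {
    sel <- calls$strain == s & calls$assay %in% stress_ids
    resistance_count(calls$call[sel], calls$stressor[sel],
                     policy = resistance_policy)
  }, numeric(1))

  structure(list(calls = calls, strains = strains, alpha = alpha),
            class = "strain_phenotypes")
}

#' @export
print.strain_phenotypes <- function(x, ...) {
  cat(sprintf("Strain phenotypes (%d strains, %d assays, alpha = %g)\n",
              nrow(x$strains), length(unique(x$calls$assay)), x$alpha))
  print(x$strains[, c("strain", "lifespan_extension_pct",
                      "combined_score", "resistance_count")], ...)
  invisible(x)
}
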