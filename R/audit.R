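# Cohort-level audit: diagnostic rate, syndromic vs non-syndromic comparison
# with a one-tailed Fisher exact test, missed-diagnosis classification
# (number-letter codes), and loss attribution.

#' Classify why a diagnosis was missed by the clinical pipeline
#'
#' Number-letter code: the number gives the loss mechanism (1 =
#' filtered/calling defect in a panel gene, 2 = gene not diagnostic-grade on
#' the applied panels, 3 = untiered SV/CNV, 4 = research/novel gene), the
#' letter the inheritance (A = de novo, B = biallelic, C = parents
#' unavailable, D = dominant inherited, E = discordant de novo within a
#' multiplex sibship). Precedence reconstructed from the audited codes:
#' SV/CNV class first, then research gene, then non-Green gene, then legacy
#' filtering.
#'
#' @param case one fixture row; must not be a baseline-found case.
#' @return Code string such as `"1B"`.
#' @export
classify_missed <- function(case) {
  if (case$found_by_gmc) stop_audit("case ", case$case_id, " was found by the clinical pipeline")
  reason <- if (case$variant_class %in% c("cnv", "sv")) {
    3L
  } else if (!case$known_dd_gene) {
    4L
  } else if (!case$green_original) {
    2L
  } else if (case$legacy_filter_dropped) {
    1L
  } else {
    2L
  }
  letter <- if (case$discordant_sibship) "E" else switch(case$inheritance,
    de_novo = , de_novo_mosaic_parent = "A",
    biallelic = "B",
    parents_unavailable = "C",
    dominant = "D",
    stop_audit("unknown inheritance: ", case$inheritance)
  )
  paste0(reason, letter)
}

#' Missed-diagnosis classification table
#'
#' @param cases fixture-style case tibble.
#' @return Named character vector, code per missed case (including VUS rows,
#'   which carry codes in the audited table).
#' @export
box2_table <- function(cases) {
  missed <- cases[!cases$found_by_gmc, ]
  setNames(
    vapply(seq_len(nrow(missed)), function(i) classify_missed(missed[i, ]), ""),
    missed$case_id
  )
}

#' Overall diagnostic rate
#'
#' @param cases fixture-style case tibble.
#' @param totals cohort totals, see [cohort_totals()].
#' @return Percent of families with a confirmed (non-VUS) diagnosis, one
#'   decimal, rounded half away from zero.
#' @export
diagnostic_rate <- function(cases, totals) {
  stopifnot(totals$n_families > 0)
  round_half_up(100 * nrow(confirmed(cases)) / totals$n_families, 1)
}

audit_pct <- function(x) if (x < 10) round_half_up(x, 2) else round_half_up(x, 1)

#' Diagnostic rate split by syndromic presentation
#'
#' @param cases fixture-style case tibble.
#' @param totals cohort totals.
#' @return List: `syndromic_pct`, `nonsyndromic_pct` (one decimal, two for
#'   values below 10) and the 2x2 `contingency` matrix
#'   (rows syndromic/non-syndromic, columns diagnosed/undiagnosed).
#' @export
syndromic_split <- function(cases, totals) {
  d <- confirmed(cases)
  ds <- sum(d$syndromic)
  dn <- nrow(d) - ds
  n_non <- totals$n_families - totals$n_syndromic
  tab <- matrix(c(ds, totals$n_syndromic - ds, dn, n_non - dn), nrow = 2, byrow = TRUE,
                dimnames = list(c("syndromic", "nonsyndromic"), c("diagnosed", "undiagnosed")))
  list(
    syndromic_pct = audit_pct(100 * ds / totals$n_syndromic),
    nonsyndromic_pct = audit_pct(100 * dn / n_non),
    contingency = tab
  )
}

#' One-tailed Fisher exact test on a 2x2 table
#'
#' Hypergeometric tail probability of tables at least as extreme as the
#' observed one, with margins fixed, in the direction of the observed
#' association (here: the first row diagnosed more often).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = strata,
#'   columns = outcome).
#' @return The one-tailed p-value.
#' @export
fisher_exact_one_tailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) stop_audit("counts must be non-negative integers")
  x <- tab[1, 1]
  m <- sum(tab[1, ])   # stratum 1 size
  n <- sum(tab[2, ])   # stratum 2 size
  k <- sum(tab[, 1])   # outcome-positive total
  expected <- m * k / (m + n)
  if (x >= expected) {
    sum(dhyper(seq(x, min(m, k)), m, n, k))
  } else {
    sum(dhyper(seq(max(0, k - n), x), m, n, k))
  }
}

#' Loss attribution
#'
#' Counts confirmed diagnoses lost to small-variant calling/filtering
#' defects and to CNV/SV prioritization failures, respectively.
#'
#' @param cases fixture-style case tibble.
#' @return Named integer vector `c(loss_filtering=, loss_cnv_sv=)`.
#' @export
loss_attribution <- function(cases) {
  d <- confirmed(cases)
  c(
    loss_filtering = sum(d$variant_class %in% c("snv", "indel") & d$legacy_filter_dropped),
    loss_cnv_sv = sum(d$variant_class %in% c("cnv", "sv") & !d$found_by_gmc)
  )
}

#' Run the full cohort audit
#'
#' Computes the per-strategy sensitivity decomposition, the named combined
#' strategies, the overall diagnostic rate, the syndromic comparison with
#' its one-tailed Fisher exact p-value, the loss attribution and the
#' missed-diagnosis classification.
#'
#' @param fixture list with `cases` and `totals`, default [crs_fixture()].
#' @param strategies strategies to evaluate singly; default all of
#'   [STRATEGIES].
#' @return A `crs_audit_report` list.
#' @export
audit_cohort <- function(fixture = crs_fixture(), strategies = STRATEGIES) {
  cases <- fixture$cases
  totals <- fixture$totals
  total <- nrow(confirmed(cases))
  base <- found_set("baseline_gmc", cases)
  split <- syndromic_split(cases, totals)
  loss <- loss_attribution(cases)
  combos <- list(
    baseline = combine_strategies("baseline_gmc", cases),
    dnm = combine_strategies("dnm_scrutiny", cases),
    optimal_panel = combine_strategies(c("updated_panels", "improved_calling"), cases),
    ddg2p_wide = combine_strategies("ddg2p_wide", cases),
    nhse_combined = combine_strategies("nhse_combined", cases)
  )
  structure(list(
    n_confirmed = total,
    baseline_sensitivity_pct = sensitivity_pct(length(base), total),
    strategies = if (length(strategies)) strategy_table(cases)[
      match(strategies, STRATEGIES), , drop = FALSE] else NULL,
    combined = combos,
    diagnostic_rate_pct = diagnostic_rate(cases, totals),
    syndromic_rate_pct = split$syndromic_pct,
    nonsyndromic_rate_pct = split$nonsyndromic_pct,
    contingency = split$contingency,
    fisher_p_one_tailed = fisher_exact_one_tailed(split$contingency),
    loss_filtering = unname(loss["loss_filtering"]),
    loss_cnv_sv = unname(loss["loss_cnv_sv"]),
    loss_combined_pct = sensitivity_pct(sum(loss), total),
    box2_table = box2_table(cases)
  ), class = "crs_audit_report")
}

#' Render an audit report
#'
#' Deterministic JSON (and a human-readable summary via [print()]); re-runs
#' on identical input are byte-identical.
#'
#' @param report a `crs_audit_report`.
#' @param json_path optional path; when given, the JSON document is written
#'   there.
#' @return The JSON string, invisibly.
#' @export
render_report <- function(report, json_path = NULL) {
  x <- unclass(report)
  x$contingency <- list(
    diagnosed = as.integer(x$contingency[, "diagnosed"]),
    undiagnosed = as.integer(x$contingency[, "undiagnosed"])
  )
  x$box2_table <- as.list(x$box2_table)
  if (!is.null(x$strategies)) {
    x$strategies$found_case_ids <- lapply(x$strategies$found_case_ids, as.integer)
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(json_path)) writeLines(json, json_path)
  invisible(json)
}

#' @export
print.crs_audit_report <- function(x, ...) {
  cat("Cohort audit (", x$n_confirmed, " confirmed diagnoses)\n", sep = "")
  cat("  overall diagnostic rate: ", x$diagnostic_rate_pct, "%\n", sep = "")
  cat("  baseline pipeline sensitivity: ", x$baseline_sensitivity_pct, "%\n", sep = "")
  for (nm in names(x$combined)) {
    c_ <- x$combined[[nm]]
    cat(sprintf("  %-14s %2d/%d = %d%% (%+d pts)\n", nm, c_$n_found, c_$total,
                c_$sensitivity_pct, c_$increment_pts))
  }
  cat("  syndromic ", x$syndromic_rate_pct, "% vs non-syndromic ",
      x$nonsyndromic_rate_pct, "% (one-tailed Fisher p = ",
      signif(x$fisher_p_one_tailed, 2), ")\n", sep = "")
  cat("  losses: filtering ", x$loss_filtering, ", CNV/SV ", x$loss_cnv_sv,
      " (", x$loss_combined_pct, "% of diagnoses)\n", sep = "")
  invisible(x)
}
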