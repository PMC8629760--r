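# Detection strategies and the sensitivity decomposition: which confirmed
# diagnoses each strategy finds, each strategy's sensitivity over all
# confirmed diagnoses, and its increment in percentage points over the
# baseline clinical pipeline.

#' Strategy identifiers
#'
#' * `baseline_gmc` — diagnoses autonomously confirmed by the clinical
#'   review of pipeline-prioritized variants;
#' * `updated_panels` — rare segregating variants in genes upgraded to
#'   diagnostic-grade on current panel versions;
#' * `improved_calling` — variants in already diagnostic-grade genes lost to
#'   calling/filtering defects or to the copy-number path;
#' * `dnm_scrutiny` — systematic review of de novo small variants;
#' * `exomiser_top3` — review of the top 3 phenotype-driven ranks;
#' * `cnv_comprehensive` — comprehensive CNV/SV analysis over validated
#'   developmental-disorder genes;
#' * `ddg2p_wide` — all validated developmental-disorder genes as candidates;
#' * `nhse_combined` — the combined national-guidance strategy (flag-driven:
#'   the identifiability column is itself part of the audited data).
#' @export
STRATEGIES <- c("baseline_gmc", "updated_panels", "improved_calling", "dnm_scrutiny",
                "exomiser_top3", "cnv_comprehensive", "ddg2p_wide", "nhse_combined")

confirmed <- function(cases) cases[cases$pathogenicity != "vus", ]

#' Found-set of a detection strategy
#'
#' Applies the strategy's predicate to the confirmed (non-VUS) diagnoses.
#' All non-baseline strategies describe *additional* detection routes, so
#' their sets exclude baseline-found cases; union with the baseline via
#' [combine_strategies()] before computing a combined sensitivity.
#'
#' @param strategy one of [STRATEGIES].
#' @param cases fixture-style case tibble (see [crs_fixture()]).
#' @return Sorted integer vector of case ids.
#' @export
found_set <- function(strategy, cases) {
  cases <- confirmed(cases)
  sel <- switch(match.arg(strategy, STRATEGIES),
    baseline_gmc = cases$found_by_gmc,
    updated_panels = !cases$found_by_gmc & cases$green_updated & !cases$green_original,
    improved_calling = !cases$found_by_gmc & cases$green_original &
      (cases$legacy_filter_dropped | cases$variant_class %in% c("cnv", "sv")),
    dnm_scrutiny = !cases$found_by_gmc & cases$inheritance == "de_novo" &
      cases$variant_class %in% c("snv", "indel"),
    exomiser_top3 = !cases$found_by_gmc &
      vapply(cases$exomiser_rank, exomiser_rank_review, TRUE, k = 3L),
    cnv_comprehensive = !cases$found_by_gmc & cases$variant_class %in% c("cnv", "sv") &
      cases$known_dd_gene,
    ddg2p_wide = !cases$found_by_gmc & cases$known_dd_gene,
    nhse_combined = cases$nhse_identifiable %in% TRUE
  )
  sort(cases$case_id[sel])
}

#' Diagnostic sensitivity as a nearest-integer percent
#'
#' Rounds half away from zero — the single rounding rule that reproduces
#' every published percentage.
#'
#' @param found number of diagnoses found.
#' @param total total confirmed diagnoses.
#' @return Integer percent.
#' @export
sensitivity_pct <- function(found, total) {
  stopifnot(total > 0)
  as.integer(round_half_up(100 * found / total))
}

#' Evaluate one or more strategies combined with the baseline
#'
#' The baseline found-set is always included in the union; the increment is
#' the combined sensitivity minus the baseline sensitivity, in integer
#' percentage points.
#'
#' @param strategies character vector from [STRATEGIES].
#' @param cases fixture-style case tibble.
#' @return List: `strategy_ids`, `found_case_ids` (the union), `n_found`,
#'   `total`, `sensitivity_pct`, `increment_pts`.
#' @export
combine_strategies <- function(strategies, cases) {
  if (!length(strategies)) stop_audit("strategy list must be non-empty")
  total <- nrow(confirmed(cases))
  base <- found_set("baseline_gmc", cases)
  found <- sort(unique(c(base, unlist(lapply(strategies, found_set, cases = cases)))))
  sens <- sensitivity_pct(length(found), total)
  list(
    strategy_ids = unique(c("baseline_gmc", strategies)),
    found_case_ids = found,
    n_found = length(found),
    total = total,
    sensitivity_pct = sens,
    increment_pts = sens - sensitivity_pct(length(base), total)
  )
}

#' Per-strategy sensitivity decomposition
#'
#' Evaluates every strategy alone against the baseline. Found-sets overlap
#' (a de novo variant in a newly Green gene is caught by panel updates, DNM
#' scrutiny and top-rank review alike), so the single-strategy increments
#' need not sum to any combined increment.
#'
#' @param cases fixture-style case tibble.
#' @return Tibble: `strategy_id`, `n_found` (cases unique to the strategy's
#'   own predicate), `found_case_ids` (list), `sensitivity_pct` (of the
#'   union with baseline), `increment_pts`.
#' @export
strategy_table <- function(cases) {
  rows <- lapply(STRATEGIES, function(s) {
    own <- found_set(s, cases)
    comb <- combine_strategies(s, cases)
    tibble::tibble(
      strategy_id = s,
      n_found = length(own),
      found_case_ids = list(own),
      sensitivity_pct = comb$sensitivity_pct,
      increment_pts = comb$increment_pts
    )
  })
  do.call(rbind, rows)
}
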