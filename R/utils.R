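#' Tier labels used throughout the package
#'
#' Small variants are prioritized into `TIER1` (highest), `TIER2`, `TIER3`
#' (discretionary review) or `TIER_NULL` (not reported). Copy-number calls are
#' either `TIER_A` (reportable, overlapping a diagnostic-grade gene) or
#' `TIER_NULL`.
#'
#' @format Character vectors of valid labels.
#' @name tier-labels
NULL

#' @rdname tier-labels
#' @export
SMALL_TIERS <- c("TIER1", "TIER2", "TIER3", "TIER_NULL")

#' @rdname tier-labels
#' @export
CNV_TIERS <- c("TIER_A", "TIER_NULL")

#' Rank of a tier label (higher = more strongly prioritized)
#'
#' Used by monotonicity checks: relaxing the tiering configuration must never
#' decrease a variant's rank. `TIER_A` ranks with `TIER1`.
#'
#' @param tier character vector of tier labels.
#' @return integer vector; `TIER_NULL` is 0.
#' @export
tier_rank <- function(tier) {
  unname(c(TIER1 = 3L, TIER_A = 3L, TIER2 = 2L, TIER3 = 1L, TIER_NULL = 0L)[tier])
}

#' Round half away from zero
#'
#' Commercial rounding, the single rounding rule used for every percentage the
#' audit reports (base [round()] rounds halves to even, which would not
#' reproduce the printed figures).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_audit <- function(...) stop(..., call. = FALSE)
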