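# CNV reporting and Tier A assignment, with the production path's known
# blind spots reproduced mechanically: balanced inversions yield no
# copy-number call at all, and CNVs touching only non-Green genes stay
# Tier null. sv_breakpoint_review() models the researcher-grade,
# breakpoint-aware analysis (intersected caller outputs) that catches them.

#' Is a copy-number call reportable?
#'
#' The production rule: CNV calls longer than 10 kb with a call quality
#' score above 10 (both strict inequalities).
#'
#' @param call one SV row (`sv_type` DEL or DUP).
#' @return Logical flag.
#' @export
cnv_reportable <- function(call) {
  if (call$sv_type == "INV") {
    stop_audit("INV is not a copy-number call; use sv_breakpoint_review()")
  }
  sv_length(call) > 10000 && call$qual_score > 10
}

overlapping_genes <- function(chrom, start, end, spans) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, spans_granges(spans))
  spans$gene[S4Vectors::subjectHits(hits)]
}

#' Assign the CNV tier of a reportable call
#'
#' Tier A iff the call interval intersects (by at least one base) the coding
#' span of a gene that is diagnostic-grade (Green) on a panel applied to the
#' case. Mode of inheritance is deliberately not considered — a heterozygous
#' CNV over a biallelic gene is still tiered. Green genes with no known span
#' are skipped with a warning.
#'
#' @param call one SV row; must satisfy [cnv_reportable()].
#' @param registry a `crs_panel_registry`.
#' @param panel_ids panels applied to the case.
#' @param panel_version `"original"` or `"updated"`.
#' @param gene_spans tibble of gene spans (1-based inclusive), e.g. from
#'   [gene_universe()] or [read_gene_spans()].
#' @return `"TIER_A"` or `"TIER_NULL"`.
#' @export
assign_cnv_tier <- function(call, registry, panel_ids, panel_version, gene_spans) {
  if (!cnv_reportable(call)) {
    stop_audit("assign_cnv_tier() requires a reportable call; see cnv_reportable()")
  }
  genes <- overlapping_genes(call$chrom, call$start, call$end, gene_spans)
  green <- green_genes_of(registry, panel_ids, panel_version, gene_spans)
  if (any(genes %in% green)) "TIER_A" else "TIER_NULL"
}

green_genes_of <- function(registry, panel_ids, panel_version, gene_spans) {
  green <- unique(unlist(lapply(panel_ids, function(pid) {
    p <- resolve_panel(registry, pid, panel_version)
    p$entries$gene[p$entries$rating == "green"]
  })))
  missing <- setdiff(green, gene_spans$gene)
  if (length(missing)) {
    warning("no span for green gene(s), skipped: ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  intersect(green, gene_spans$gene)
}

#' Breakpoint-aware structural-variant review
#'
#' Flags any rearrangement whose full interval — between the outermost
#' breakpoints — contains or intersects a Green-gene span on an applied
#' panel. Unlike the production copy-number path, this catches balanced
#' inversions whose breakpoints flank a gene without changing its copy
#' number, and applies regardless of call length or quality. It models
#' researcher-grade review of intersected caller outputs, not the clinical
#' pipeline.
#'
#' @inheritParams assign_cnv_tier
#' @param call any SV row (DEL, DUP or INV).
#' @return Logical flag.
#' @export
sv_breakpoint_review <- function(call, registry, panel_ids, panel_version, gene_spans) {
  genes <- overlapping_genes(call$chrom, call$start, call$end, gene_spans)
  green <- suppressWarnings(green_genes_of(registry, panel_ids, panel_version, gene_spans))
  any(genes %in% green)
}

#' Tier every structural call of a family (production path)
#'
#' Applies the production rules: inversions produce no copy-number call,
#' calls at or below 10 kb or quality 10 are not reported, and the remainder
#' go through [assign_cnv_tier()]. A `breakpoint_review` column records what
#' the researcher-grade review would have flagged.
#'
#' @inheritParams assign_cnv_tier
#' @param calls SV tibble for one family.
#' @param family_id family identifier for the output.
#' @return Tibble: `family_id`, `variant_key`, `sv_type`, `tier`,
#'   `breakpoint_review`.
#' @export
tier_sv_family <- function(calls, family_id, registry, panel_ids, panel_version, gene_spans) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    tier <- if (call$sv_type == "INV" || !cnv_reportable(call)) {
      "TIER_NULL"
    } else {
      assign_cnv_tier(call, registry, panel_ids, panel_version, gene_spans)
    }
    tibble::tibble(
      family_id = family_id,
      variant_key = paste(call$chrom, call$start, call$end, call$sv_type, sep = ":"),
      sv_type = call$sv_type,
      tier = tier,
      breakpoint_review = sv_breakpoint_review(call, registry, panel_ids, panel_version,
                                               gene_spans)
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(family_id = character(), variant_key = character(),
                          sv_type = character(), tier = character(),
                          breakpoint_review = logical()))
  }
  do.call(rbind, rows)
}
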