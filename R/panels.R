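# Versioned virtual gene panels (PanelApp-style): gene -> confidence rating
# (green/amber/red) + mode of inheritance, at two version snapshots
# ("original" = panels as applied when the case was analysed, "updated" =
# current panels). Multiple panels applied to a case are merged by maximum
# rating, so a gene counts as diagnostic-grade if it is Green on at least one
# relevant panel.

RATINGS <- c("green", "amber", "red", "not_listed")
MOIS <- c("monoallelic", "biallelic", "x_linked", "both")
VERSION_TAGS <- c("original", "updated")

#' Build a panel object
#'
#' @param panel_id panel identifier.
#' @param version_tag `"original"` or `"updated"`.
#' @param entries tibble/data.frame with columns `gene`, `rating`
#'   (green/amber/red) and `moi` (monoallelic/biallelic/x_linked/both).
#' @return A `crs_panel` list.
#' @export
panel <- function(panel_id, version_tag, entries) {
  version_tag <- match.arg(version_tag, VERSION_TAGS)
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("gene", "rating", "moi") %in% names(entries)))
  if (anyDuplicated(entries$gene)) {
    stop_audit("panel ", panel_id, " (", version_tag, "): duplicate gene entries")
  }
  if (!all(entries$rating %in% RATINGS[1:3])) stop_audit("invalid rating in panel ", panel_id)
  if (!all(entries$moi %in% MOIS)) stop_audit("invalid moi in panel ", panel_id)
  structure(list(panel_id = panel_id, version_tag = version_tag, entries = entries),
            class = "crs_panel")
}

#' Read a panel document
#'
#' Panel files are YAML, one document per panel version, with top-level keys
#' `panel_id`, `version_tag` and `entries` (list of `gene`/`rating`/`moi`
#' maps). A machine-readable description of the layout ships in
#' `inst/extdata/panel-schema.json`.
#'
#' @param path path to a panel YAML file.
#' @return A `crs_panel`.
#' @export
read_panel <- function(path) {
  doc <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(doc$entries, function(e) {
    tibble::tibble(gene = e$gene, rating = e$rating, moi = e$moi)
  }))
  panel(doc$panel_id, doc$version_tag, entries)
}

#' Write a panel document
#'
#' @param p a `crs_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  doc <- list(
    panel_id = p$panel_id, version_tag = p$version_tag,
    entries = lapply(seq_len(nrow(p$entries)), function(i) {
      as.list(p$entries[i, c("gene", "rating", "moi")])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Assemble a panel registry
#'
#' @param panels list of `crs_panel` objects (typically both version snapshots
#'   of each panel).
#' @return A `crs_panel_registry`, keyed by panel id and version tag.
#' @export
panel_registry <- function(panels) {
  keys <- vapply(panels, function(p) paste(p$panel_id, p$version_tag, sep = "@"), "")
  if (anyDuplicated(keys)) stop_audit("duplicate panel/version: ", keys[duplicated(keys)][1])
  structure(setNames(panels, keys), class = "crs_panel_registry")
}

resolve_panel <- function(registry, panel_id, version_tag) {
  p <- registry[[paste(panel_id, version_tag, sep = "@")]]
  if (is.null(p)) stop_audit("unknown panel '", panel_id, "' at version '", version_tag, "'")
  p
}

#' Confidence rating of a gene across the panels applied to a case
#'
#' Returns the maximum rating of `gene` across all applied panels at the
#' requested version snapshot (green > amber > red > not_listed), mirroring
#' review practice where a variant is prioritized if its gene is
#' diagnostic-grade on at least one relevant panel.
#'
#' @param registry a `crs_panel_registry`.
#' @param panel_ids character vector: the panels applied to the case.
#' @param version_tag `"original"` or `"updated"`.
#' @param gene gene symbol.
#' @return One of `"green"`, `"amber"`, `"red"`, `"not_listed"`.
#' @export
gene_status <- function(registry, panel_ids, version_tag, gene) {
  if (!length(panel_ids)) stop_audit("no panels applied")
  if (!nzchar(gene)) stop_audit("empty gene symbol")
  version_tag <- match.arg(version_tag, VERSION_TAGS)
  ratings <- vapply(panel_ids, function(pid) {
    p <- resolve_panel(registry, pid, version_tag)
    hit <- p$entries$rating[p$entries$gene == gene]
    if (length(hit)) hit else "not_listed"
  }, "")
  RATINGS[min(match(ratings, RATINGS))]
}

#' Is a gene diagnostic-grade (Green) for a case?
#'
#' @inheritParams gene_status
#' @return `TRUE` iff [gene_status()] is `"green"`.
#' @export
is_diagnostic_grade <- function(registry, panel_ids, version_tag, gene) {
  identical(gene_status(registry, panel_ids, version_tag, gene), "green")
}

#' Modes of inheritance under which a gene is Green for a case
#'
#' Collects the `moi` annotations of green entries of `gene` across the
#' applied panels; used by the tiering engine for moi-compatible panel
#' intersection.
#'
#' @inheritParams gene_status
#' @return Character vector of modes (possibly empty), from
#'   `c("monoallelic", "biallelic", "x_linked", "both")`.
#' @export
green_mois <- function(registry, panel_ids, version_tag, gene) {
  version_tag <- match.arg(version_tag, VERSION_TAGS)
  mois <- unlist(lapply(panel_ids, function(pid) {
    p <- resolve_panel(registry, pid, version_tag)
    p$entries$moi[p$entries$gene == gene & p$entries$rating == "green"]
  }))
  unique(mois)
}
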