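# Synthetic trio-cohort generator: families with the audited cohort's
# composition, planted causal-variant archetypes (one per diagnosed
# family) reproducing each audited success/failure mechanism, and rare
# benign background variation — plus a truth table, so every pipeline stage
# is testable without any data download.

ARCHETYPE_IDS <- c(
  "green_gene_denovo_lof", "green_gene_biallelic", "nonpanel_denovo",
  "updated_panel_denovo", "filtered_indel_compound_het", "parental_read_denovo",
  "discordant_sibship_denovo", "green_cnv_del", "flanking_inversion",
  "nonpanel_dup_mosaic", "noncoding_duplication", "parents_unavailable_lof"
)

#' Archetype rule table
#'
#' One row per planted causal-variant archetype: the family structure it
#' needs, the gene it uses, the tier an ideal implementation of the stated
#' rules must produce under each operating mode, and the detection
#' strategies (beyond the baseline) that would catch it. This table is the
#' independent oracle for the tiering engine — a direct lookup, not a call
#' into it.
#'
#' @return Tibble with columns `archetype_id`, `family_type`, `variant_type`,
#'   `gene`, `expected_tier_legacy`, `expected_tier_improved`,
#'   `detected_by`.
#' @export
archetype_table <- function() {
  tibble::tibble(
    archetype_id = ARCHETYPE_IDS,
    family_type = c("trio", "trio", "trio", "trio", "trio", "trio",
                    "multiplex", "trio", "trio", "trio", "trio", "singleton"),
    variant_type = c(rep("small", 7), rep("sv", 4), "small"),
    gene = c("TCF12", "MAN2B1", "KMT5B", "SMAD6", "MEGF8", "ARID1B",
             "TCF12", "ERF", "TWIST1", "HOXC12", NA, "SOX6"),
    expected_tier_legacy = c("TIER1", "TIER1", "TIER3", "TIER3", "TIER_NULL",
                             "TIER_NULL", "TIER_NULL", "TIER_A", "TIER_NULL",
                             "TIER_NULL", "TIER_NULL", "TIER3"),
    expected_tier_improved = c("TIER1", "TIER1", "TIER3", "TIER1", "TIER1",
                               "TIER1", "TIER1", "TIER_A", "TIER_NULL",
                               "TIER_NULL", "TIER_NULL", "TIER3"),
    detected_by = c("", "", "dnm_scrutiny,ddg2p_wide",
                    "updated_panels,dnm_scrutiny", "improved_calling",
                    "improved_calling,dnm_scrutiny",
                    "improved_calling,dnm_scrutiny", "",
                    "cnv_comprehensive", "", "", "")
  )
}

#' Oracle tier of a planted archetype
#'
#' Direct rule-table lookup (see [archetype_table()]); for compound
#' heterozygous archetypes it describes the primary (indel/loss-of-function)
#' allele.
#'
#' @param archetype one of the archetype identifiers.
#' @param mode `"legacy"` or `"improved"`.
#' @return A tier label.
#' @export
expected_tier <- function(archetype, mode = c("legacy", "improved")) {
  mode <- match.arg(mode)
  tab <- archetype_table()
  if (!archetype %in% tab$archetype_id) stop_audit("unknown archetype: ", archetype)
  col <- paste0("expected_tier_", mode)
  tab[[col]][tab$archetype_id == archetype]
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the audited cohort's composition: 114 families, 72
#' proband-parent trios, 15 multiplex families (the remainder duos and
#' singletons pro rata), 72% syndromic probands, one planted archetype of
#' each kind, and 50 rare background variants per genome (the desk-scale
#' stand-in for the filter-surviving candidate burden of a real genome).
#'
#' @param n_families total families.
#' @param n_trios proband-parent trios among them.
#' @param n_multiplex families with more than one affected individual.
#' @param syndromic_fraction probability a proband is syndromic.
#' @param archetype_counts named integer vector over the archetype ids.
#' @param background_per_genome benign variants planted per family.
#' @param seed integer seed; the generator is byte-deterministic given it.
#' @return A `crs_cohort_config` list.
#' @export
cohort_config <- function(n_families = 114, n_trios = 72, n_multiplex = 15,
                          syndromic_fraction = 82 / 114,
                          archetype_counts = setNames(rep(1L, length(ARCHETYPE_IDS)),
                                                      ARCHETYPE_IDS),
                          background_per_genome = 50, seed = 1) {
  if (n_trios + n_multiplex > n_families) {
    stop_audit("n_trios + n_multiplex exceeds n_families")
  }
  unknown <- setdiff(names(archetype_counts), ARCHETYPE_IDS)
  if (length(unknown)) stop_audit("unknown archetype(s): ", paste(unknown, collapse = ", "))
  tab <- archetype_table()
  need <- function(type) {
    ids <- tab$archetype_id[tab$family_type == type]
    sum(archetype_counts[intersect(names(archetype_counts), ids)])
  }
  n_rest <- n_families - n_trios - n_multiplex
  n_singletons <- n_rest %/% 2
  if (need("trio") > n_trios) stop_audit("more trio archetypes than trios")
  if (need("multiplex") > n_multiplex) stop_audit("more multiplex archetypes than multiplex families")
  if (need("singleton") > n_singletons) stop_audit("more singleton archetypes than singleton families")
  if (sum(archetype_counts) > n_families) stop_audit("more archetypes than families")
  structure(list(
    n_families = as.integer(n_families), n_trios = as.integer(n_trios),
    n_multiplex = as.integer(n_multiplex), syndromic_fraction = syndromic_fraction,
    archetype_counts = archetype_counts,
    background_per_genome = as.integer(background_per_genome), seed = as.integer(seed)
  ), class = "crs_cohort_config")
}

#' Bundled synthetic panels
#'
#' Two snapshots of a craniosynostosis panel: the "original" version (as
#' applied when cases were analysed) and the "updated" version, which adds
#' the genes later upgraded to diagnostic-grade and lists some others at
#' lower confidence. Synthetic stand-ins built to reproduce the audited
#' green/not-green outcomes; updated green membership is a superset of
#' original.
#'
#' @return A `crs_panel_registry` holding `CRS@original` and `CRS@updated`.
#' @export
bundled_panels <- function() {
  original <- tibble::tibble(
    gene = c("TCF12", "TWIST1", "ERF", "ARID1B", "FGFR2", "FGFR3", "EFNB1",
             "MAN2B1", "MEGF8", "MMP21"),
    rating = "green",
    moi = c("monoallelic", "monoallelic", "monoallelic", "monoallelic",
            "monoallelic", "monoallelic", "x_linked",
            "biallelic", "biallelic", "biallelic")
  )
  updated <- rbind(
    original,
    tibble::tibble(
      gene = c("SMAD6", "HNRNPK", "FBXO11", "TRAF7", "OGT"),
      rating = "green",
      moi = c("monoallelic", "monoallelic", "monoallelic", "monoallelic", "x_linked")
    ),
    tibble::tibble(
      gene = c("SOX6", "PTCH1", "GPC3"),
      rating = "amber",
      moi = c("monoallelic", "monoallelic", "x_linked")
    )
  )
  panel_registry(list(
    panel("CRS", "original", original),
    panel("CRS", "updated", updated)
  ))
}

# -- family builders ---------------------------------------------------------

ped_member <- function(family_id, sample_id, father_id = NA_character_,
                       mother_id = NA_character_, sex, affected, is_proband = FALSE) {
  tibble::tibble(family_id = family_id, sample_id = sample_id,
                 father_id = as.character(father_id), mother_id = as.character(mother_id),
                 sex = sex, affected = affected, is_proband = is_proband)
}

make_family <- function(fid, type, n_sibs = 2) {
  pro <- paste0(fid, "_p1")
  fa <- paste0(fid, "_fa")
  mo <- paste0(fid, "_mo")
  switch(type,
    trio = rbind(
      ped_member(fid, pro, fa, mo, sample(c("male", "female"), 1), "affected", TRUE),
      ped_member(fid, fa, sex = "male", affected = "unaffected"),
      ped_member(fid, mo, sex = "female", affected = "unaffected")
    ),
    multiplex = rbind(
      do.call(rbind, lapply(seq_len(n_sibs), function(k) {
        ped_member(fid, paste0(fid, "_p", k), fa, mo,
                   if (n_sibs >= 3) "male" else sample(c("male", "female"), 1),
                   "affected", k == 1)
      })),
      ped_member(fid, fa, sex = "male", affected = "unaffected"),
      ped_member(fid, mo, sex = "female", affected = "unaffected")
    ),
    duo = rbind(
      ped_member(fid, pro, NA, mo, sample(c("male", "female"), 1), "affected", TRUE),
      ped_member(fid, mo, sex = "female", affected = "unaffected")
    ),
    singleton = ped_member(fid, pro, sex = sample(c("male", "female"), 1),
                           affected = "affected", is_proband = TRUE)
  )
}

gcall <- function(ac, dp = 30L, alt = NULL) {
  list(allele_count = as.integer(ac),
       total_reads = as.integer(dp),
       alt_reads = as.integer(alt %||% if (ac > 0) dp %/% 2L else 0L))
}

family_gts <- function(pedigree, acs, overrides = list()) {
  geno <- lapply(pedigree$sample_id, function(s) {
    if (!is.null(overrides[[s]])) overrides[[s]] else gcall(acs[[s]] %||% 0L)
  })
  setNames(geno, pedigree$sample_id)
}

random_base <- function(n = 1, not = NULL) {
  pool <- setdiff(c("A", "C", "G", "T"), not)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

small_row <- function(spans, gene, consequence, pedigree, acs, overrides = list(),
                      pop_af = 0, low_complexity = FALSE, ref = NULL, alt = NULL) {
  sp <- spans[spans$gene == gene, ]
  pos <- as.integer(floor(runif(1, sp$start, sp$end - 20)))
  if (is.null(ref)) ref <- random_base()
  if (is.null(alt)) alt <- random_base(not = ref)
  tibble::tibble(
    chrom = sp$chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = consequence, pop_af = pop_af,
    qual = round(runif(1, 40, 90), 1), low_complexity = low_complexity,
    genotypes = list(family_gts(pedigree, acs, overrides))
  )
}

sv_row <- function(chrom, start, end, sv_type, qual, carriers, mosaic = character()) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 sv_type = sv_type, qual_score = qual,
                 carriers = list(sort(carriers)), mosaic_carriers = list(sort(mosaic)),
                 breakpoints_only = sv_type == "INV")
}

plant_archetype <- function(archetype_id, pedigree, spans) {
  pro <- pedigree$sample_id[pedigree$is_proband]
  fa <- pedigree$father_id[pedigree$is_proband]
  mo <- pedigree$mother_id[pedigree$is_proband]
  acs1 <- setNames(list(1L), pro)   # heterozygous proband, others reference
  small <- empty_small_variants()
  sv <- empty_sv_calls()
  roles <- character()

  if (archetype_id == "green_gene_denovo_lof") {
    small <- small_row(spans, "TCF12", "lof", pedigree, acs1)
  } else if (archetype_id == "green_gene_biallelic") {
    small <- rbind(
      small_row(spans, "MAN2B1", "lof", pedigree, setNames(list(1L, 1L), c(pro, fa))),
      small_row(spans, "MAN2B1", "missense", pedigree, setNames(list(1L, 1L), c(pro, mo)))
    )
    roles <- c("primary", "partner")
  } else if (archetype_id == "nonpanel_denovo") {
    small <- small_row(spans, "KMT5B", "lof", pedigree, acs1)
  } else if (archetype_id == "updated_panel_denovo") {
    small <- small_row(spans, "SMAD6", "missense", pedigree, acs1)
  } else if (archetype_id == "filtered_indel_compound_het") {
    anchor <- random_base()
    small <- rbind(
      small_row(spans, "MEGF8", "lof", pedigree, setNames(list(1L, 1L), c(pro, fa)),
                low_complexity = TRUE,
                ref = paste0(anchor, random_base(14)), alt = anchor),
      small_row(spans, "MEGF8", "missense", pedigree, setNames(list(1L, 1L), c(pro, mo)))
    )
    roles <- c("primary", "partner")
  } else if (archetype_id == "parental_read_denovo") {
    small <- small_row(spans, "ARID1B", "missense", pedigree, acs1,
                       overrides = setNames(list(gcall(0L, dp = 32L, alt = 1L)), mo))
  } else if (archetype_id == "discordant_sibship_denovo") {
    small <- small_row(spans, "TCF12", "lof", pedigree, acs1)
  } else if (archetype_id == "parents_unavailable_lof") {
    small <- small_row(spans, "SOX6", "lof", pedigree, acs1)
  } else if (archetype_id == "green_cnv_del") {
    sv <- sv_row("chr19", 42600001, 42914000, "DEL", 50, pro, mosaic = fa)
  } else if (archetype_id == "flanking_inversion") {
    sv <- sv_row("chr7", 12000001, 25400000, "INV", 45, pro)
  } else if (archetype_id == "nonpanel_dup_mosaic") {
    sv <- sv_row("chr12", 54200001, 54485000, "DUP", 40, pro, mosaic = fa)
  } else if (archetype_id == "noncoding_duplication") {
    sv <- sv_row("chr1", 150000001, 150011500, "DUP", 30, pro)
  } else {
    stop_audit("unknown archetype: ", archetype_id)
  }
  if (!length(roles)) roles <- rep("primary", nrow(small) + nrow(sv))
  list(small = small, sv = sv, roles = roles)
}

background_variants <- function(pedigree, spans, n) {
  if (n == 0) return(empty_small_variants())
  filler <- spans[grepl("^FILLER", spans$gene), ]
  pro <- pedigree$sample_id[pedigree$is_proband]
  fa <- pedigree$father_id[pedigree$is_proband]
  mo <- pedigree$mother_id[pedigree$is_proband]
  parents <- c(fa, mo)
  parents <- parents[!is.na(parents)]
  rows <- lapply(seq_len(n), function(i) {
    gene <- sample(filler$gene, 1)
    csq <- sample(c("missense", "lof", "synonymous", "noncoding"), 1,
                  prob = c(0.3, 0.05, 0.3, 0.35))
    af <- if (runif(1) < 0.7) runif(1, 0, 8e-4) else runif(1, 0.02, 0.2)
    acs <- setNames(list(1L), pro)
    if (length(parents)) acs[[sample(parents, 1)]] <- 1L
    small_row(spans, gene, csq, pedigree, acs, pop_af = round(af, 6))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort
#'
#' Builds the configured family structures, plants one causal archetype in
#' each hosting family (trio archetypes in trios, the discordant-sibship
#' archetype in a three-affected-male multiplex family, the
#' parents-unavailable archetype in a singleton), adds benign background
#' variation, and writes everything in the package's file dialects: a PED
#' file, one small-variant VCF per family, SV VCFs for families carrying
#' structural calls, both panel snapshots, a gene-span BED and a truth TSV.
#' Byte-deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return List: `paths` (ped, small_vcfs, sv_vcfs, panels, spans, truth),
#'   `pedigrees`, `small_variants`, `sv_calls` (named by family),
#'   `truth` (tibble: family, archetype, variant key, role, expected tier
#'   per mode, detection strategies, syndromic flag), `registry`,
#'   `gene_spans` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = tempfile("crs_cohort_")) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "small"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "sv"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "panels"), showWarnings = FALSE)

  spans <- gene_universe()
  registry <- bundled_panels()
  tab <- archetype_table()

  n_rest <- config$n_families - config$n_trios - config$n_multiplex
  n_singletons <- n_rest %/% 2
  n_duos <- n_rest - n_singletons
  types <- c(rep("trio", config$n_trios), rep("multiplex", config$n_multiplex),
             rep("duo", n_duos), rep("singleton", n_singletons))
  fids <- sprintf("fam%03d", seq_len(config$n_families))

  # archetype -> hosting family, deterministically: instances fill the first
  # families of the compatible structure type
  instances <- rep(names(config$archetype_counts), config$archetype_counts)
  hosts <- setNames(character(length(instances)), NULL)
  used <- character()
  for (i in seq_along(instances)) {
    ftype <- tab$family_type[tab$archetype_id == instances[i]]
    cand <- setdiff(fids[types == ftype], used)
    hosts[i] <- cand[1]
    used <- c(used, cand[1])
  }

  pedigrees <- list()
  small <- list()
  svs <- list()
  truth_rows <- list()

  for (j in seq_along(fids)) {
    fid <- fids[j]
    planted <- instances[hosts == fid]
    n_sibs <- if (length(planted) && planted[1] == "discordant_sibship_denovo") 3 else 2
    ped <- make_family(fid, types[j], n_sibs = n_sibs)
    syndromic <- runif(1) < config$syndromic_fraction
    fam_small <- background_variants(ped, spans, config$background_per_genome)
    fam_sv <- empty_sv_calls()
    for (a in planted) {
      pl <- plant_archetype(a, ped, spans)
      fam_small <- rbind(fam_small, pl$small)
      fam_sv <- rbind(fam_sv, pl$sv)
      keys <- c(if (nrow(pl$small)) variant_key(pl$small),
                if (nrow(pl$sv)) paste(pl$sv$chrom, pl$sv$start, pl$sv$end, pl$sv$sv_type,
                                       sep = ":"))
      arow <- tab[tab$archetype_id == a, ]
      partner_legacy <- switch(a, green_gene_biallelic = "TIER2",
                               filtered_indel_compound_het = "TIER3", NA_character_)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        family_id = fid, archetype_id = a, variant_key = keys, role = pl$roles,
        expected_tier_legacy = ifelse(pl$roles == "partner", partner_legacy,
                                      arow$expected_tier_legacy),
        expected_tier_improved = ifelse(pl$roles == "partner", "TIER2",
                                        arow$expected_tier_improved),
        detected_by = arow$detected_by, syndromic = syndromic
      )
    }
    if (!length(planted)) {
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        family_id = fid, archetype_id = "none", variant_key = NA_character_,
        role = NA_character_, expected_tier_legacy = NA_character_,
        expected_tier_improved = NA_character_, detected_by = "", syndromic = syndromic
      )
    }
    fam_small <- fam_small[order(fam_small$chrom, fam_small$pos, fam_small$alt), ]
    pedigrees[[fid]] <- ped
    small[[fid]] <- fam_small
    if (nrow(fam_sv)) svs[[fid]] <- fam_sv
  }

  truth <- do.call(rbind, truth_rows)

  ped_path <- file.path(out_dir, "cohort.ped")
  write_ped(pedigrees, ped_path)
  small_paths <- setNames(vapply(fids, function(fid) {
    write_small_vcf(small[[fid]], file.path(out_dir, "small", paste0(fid, ".vcf")),
                    samples = pedigrees[[fid]]$sample_id)
  }, ""), fids)
  sv_paths <- setNames(vapply(names(svs), function(fid) {
    write_sv_vcf(svs[[fid]], file.path(out_dir, "sv", paste0(fid, ".vcf")),
                 samples = pedigrees[[fid]]$sample_id)
  }, ""), names(svs))
  panel_paths <- c(
    write_panel(registry[["CRS@original"]], file.path(out_dir, "panels", "crs_original.yaml")),
    write_panel(registry[["CRS@updated"]], file.path(out_dir, "panels", "crs_updated.yaml"))
  )
  spans_path <- write_gene_spans(spans, file.path(out_dir, "spans.bed"))
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  list(
    paths = list(ped = ped_path, small_vcfs = small_paths, sv_vcfs = sv_paths,
                 panels = panel_paths, spans = spans_path, truth = truth_path),
    pedigrees = pedigrees, small_variants = small, sv_calls = svs,
    truth = truth, registry = registry, gene_spans = spans, config = config
  )
}

#' Tier every variant of a synthetic cohort
#'
#' Runs the small-variant engine and the production CNV path over all
#' families under one operating mode (legacy = original panels + legacy
#' filters; improved = updated panels + remediated filters).
#'
#' @param cohort result of [simulate_cohort()].
#' @param mode `"legacy"` or `"improved"`.
#' @return List of two tibbles, `small` and `sv` (see [tier_family()] and
#'   [tier_sv_family()]).
#' @export
tier_cohort <- function(cohort, mode = c("legacy", "improved")) {
  mode <- match.arg(mode)
  config <- mode_config(mode)
  version <- mode_panel_version(mode)
  small <- do.call(rbind, lapply(names(cohort$pedigrees), function(fid) {
    tier_family(cohort$small_variants[[fid]], cohort$pedigrees[[fid]],
                cohort$registry, "CRS", version, config)
  }))
  sv <- do.call(rbind, lapply(names(cohort$sv_calls), function(fid) {
    tier_sv_family(cohort$sv_calls[[fid]], fid, cohort$registry, "CRS", version,
                   cohort$gene_spans)
  }))
  list(small = small, sv = sv %||% empty_sv_tiers())
}

empty_sv_tiers <- function() {
  tibble::tibble(family_id = character(), variant_key = character(),
                 sv_type = character(), tier = character(), breakpoint_review = logical())
}
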