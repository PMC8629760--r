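# Small-variant tiering: frequency, consequence, trio segregation under a
# penetrance mode, legacy quality filters, and virtual-panel intersection,
# producing TIER1/TIER2/TIER3/TIER_NULL per variant allele.
#
# Two operating points matter for the audit:
#   * legacy   — the production behaviour being audited: zero-tolerance
#                parental reads for de novo acceptance, the multinucleotide
#                indel quality filter active, and the shared-variant sibship
#                model for multiplex families;
#   * improved — the remediated behaviour: parental reads tolerated up to a
#                small allele fraction, no indel quality filter, and each
#                affected individual analysed on their own merits.

#' Tiering engine configuration
#'
#' @param penetrance `"complete"` (dominant variants may not be carried by
#'   unaffected members) or `"incomplete"` (unaffected carriers permitted).
#' @param af_max_monoallelic population-frequency ceiling for monoallelic and
#'   X-linked candidates (default 0.001).
#' @param af_max_biallelic ceiling for biallelic candidates (default 0.01).
#' @param legacy_mode emulate the original pipeline filters (see above).
#' @param parental_alt_fraction_max in improved mode, the maximum fraction of
#'   parental reads supporting the allele that is still compatible with a
#'   de novo call (default 0.05, so a single mis-called read out of ~30 does
#'   not veto the variant).
#' @param sibship_model `"shared_variant"` (all affected siblings must share
#'   the causal variant) or `"per_individual"`.
#' @return A `crs_tier_config` list.
#' @export
tier_config <- function(penetrance = c("complete", "incomplete"),
                        af_max_monoallelic = 0.001,
                        af_max_biallelic = 0.01,
                        legacy_mode = TRUE,
                        parental_alt_fraction_max = 0.05,
                        sibship_model = c("shared_variant", "per_individual")) {
  structure(list(
    penetrance = match.arg(penetrance),
    af_max_monoallelic = af_max_monoallelic,
    af_max_biallelic = af_max_biallelic,
    legacy_mode = legacy_mode,
    parental_alt_fraction_max = parental_alt_fraction_max,
    sibship_model = match.arg(sibship_model)
  ), class = "crs_tier_config")
}

#' Canonical legacy / improved configurations
#'
#' @param mode `"legacy"` or `"improved"`.
#' @return A `crs_tier_config`. The panel version snapshot conventionally
#'   paired with each mode is `"original"` for legacy and `"updated"` for
#'   improved (see [tier_family()]).
#' @export
mode_config <- function(mode = c("legacy", "improved")) {
  mode <- match.arg(mode)
  if (mode == "legacy") {
    tier_config(legacy_mode = TRUE, sibship_model = "shared_variant")
  } else {
    tier_config(legacy_mode = FALSE, sibship_model = "per_individual")
  }
}

mode_panel_version <- function(mode) {
  c(legacy = "original", improved = "updated")[[match.arg(mode, c("legacy", "improved"))]]
}

#' Consequence class of a variant
#'
#' @param record one small-variant row.
#' @return `"high_impact"` (loss of function), `"moderate_impact"` (missense,
#'   in-frame indel) or `"other"` (synonymous, non-coding, remainder).
#' @export
consequence_class <- function(record) {
  switch(record$consequence,
    lof = "high_impact",
    missense = ,
    inframe_indel = "moderate_impact",
    "other"
  )
}

#' Population-frequency filter
#'
#' @param record one small-variant row.
#' @param moi mode of inheritance under evaluation (`monoallelic`,
#'   `x_linked`, `biallelic` or `both`; `both` is given the permissive
#'   biallelic ceiling).
#' @param config a `crs_tier_config`.
#' @return `TRUE` iff `pop_af` does not exceed the ceiling for `moi`.
#' @export
frequency_pass <- function(record, moi, config) {
  ceiling_af <- if (moi %in% c("biallelic", "both")) config$af_max_biallelic
                else config$af_max_monoallelic
  record$pop_af <= ceiling_af
}

#' Parental read support check for de novo acceptance
#'
#' In legacy mode any alternate-allele read in a parent vetoes the de novo
#' call (the behaviour that discarded a causal variant over one mis-called
#' read among 32 in a mother). In improved mode a parent may carry up to
#' `parental_alt_fraction_max` of supporting reads.
#'
#' @param child_call genotype list for the child (unused beyond interface
#'   symmetry; the decision rests on parental evidence).
#' @param parent_calls list of genotype lists for the available parents.
#' @param config a `crs_tier_config`.
#' @return Logical flag; when `FALSE`, a `"reason"` attribute carries
#'   `"parental_support"` or `"no_parental_coverage"`.
#' @export
parental_support_check <- function(child_call, parent_calls, config) {
  for (p in parent_calls) {
    if (is.na(p$total_reads) || p$total_reads == 0) {
      return(structure(FALSE, reason = "no_parental_coverage"))
    }
    ok <- if (config$legacy_mode) {
      p$alt_reads == 0
    } else {
      p$alt_reads / p$total_reads <= config$parental_alt_fraction_max
    }
    if (!ok) return(structure(FALSE, reason = "parental_support"))
  }
  TRUE
}

#' Legacy indel quality filter
#'
#' Models the production-era quality settings that silently removed
#' multinucleotide indel calls: in legacy mode, an indel changing length by
#' three or more bases, or a delins (both alleles longer than one base), is
#' dropped when it lies in a flagged low-complexity region. SNVs always pass;
#' in improved mode everything is kept.
#'
#' @param record one small-variant row.
#' @param config a `crs_tier_config`.
#' @return `"keep"` or `"drop"`.
#' @export
legacy_quality_filter <- function(record, config) {
  if (!config$legacy_mode) return("keep")
  len_change <- abs(nchar(record$ref) - nchar(record$alt))
  delins <- nchar(record$ref) > 1 && nchar(record$alt) > 1
  if ((len_change >= 3 || delins) && isTRUE(record$low_complexity)) "drop" else "keep"
}

is_x_chrom <- function(chrom) chrom %in% c("X", "chrX")

ac_of <- function(genotypes, sample_id) {
  g <- genotypes[[sample_id]]
  if (is.null(g)) NA_integer_ else g$allele_count
}

#' Family segregation pattern of a variant
#'
#' Interrogates the family unit: de novo status (subject to
#' [parental_support_check()]), dominant inheritance under the configured
#' penetrance, biallelic genotypes (homozygous, or heterozygous candidates in
#' genes with a biallelic mode of inheritance), X-linked hemizygosity in
#' affected males, and the multiplex sibship model. Under the
#' `shared_variant` model, a variant absent from any affected sibling fails
#' segregation regardless of its merit in the carrier.
#'
#' @param record one small-variant row.
#' @param pedigree single-family pedigree tibble.
#' @param config a `crs_tier_config`.
#' @param gene_mois modes of inheritance under which the gene is
#'   diagnostic-grade on an applied panel (from [green_mois()]); used to keep
#'   unpaired heterozygotes in biallelic genes alive as recessive candidates.
#' @param comphet_partner `TRUE` when another surviving protein-altering
#'   variant in the same gene was inherited from the other parent (set by
#'   [tier_family()]).
#' @return List with `pattern` (one of `de_novo`, `dominant_inherited`,
#'   `biallelic`, `x_linked`, `parents_unavailable`, `fails_segregation`) and
#'   a character vector `reasons`.
#' @export
segregation_pattern <- function(record, pedigree, config,
                                gene_mois = character(), comphet_partner = FALSE) {
  geno <- record$genotypes[[1]]
  missing_members <- setdiff(pedigree$sample_id, names(geno))
  if (length(missing_members)) {
    stop_audit("no genotype for pedigree member(s): ", paste(missing_members, collapse = ", "))
  }
  pro <- pedigree[pedigree$is_proband, ]
  pro_ac <- ac_of(geno, pro$sample_id)
  out <- function(pattern, reasons = character()) list(pattern = pattern, reasons = reasons)

  if (pro_ac == 0) return(out("fails_segregation", "proband_noncarrier"))

  affected <- pedigree$sample_id[pedigree$affected == "affected"]
  if (config$sibship_model == "shared_variant" && length(affected) > 1) {
    acs <- vapply(affected, function(s) ac_of(geno, s), 0L)
    if (any(acs == 0)) return(out("fails_segregation", "discordant_sibship"))
  }

  father <- pro$father_id
  mother <- pro$mother_id
  have_father <- !is.na(father)
  have_mother <- !is.na(mother)
  if (!have_father && !have_mother) return(out("parents_unavailable"))

  f_ac <- if (have_father) ac_of(geno, father) else 0L
  m_ac <- if (have_mother) ac_of(geno, mother) else 0L

  # De novo: absent from parental genotypes, and parental reads do not
  # contradict (both parents must be available to call a variant de novo).
  if (have_father && have_mother && f_ac == 0 && m_ac == 0) {
    psc <- parental_support_check(geno[[pro$sample_id]], list(geno[[father]], geno[[mother]]),
                                  config)
    if (isTRUE(psc)) return(out("de_novo"))
    return(out("fails_segregation", attr(psc, "reason")))
  }

  # X-linked: hemizygous affected male, allele absent from the father and at
  # most heterozygous (carrier) in the unaffected mother.
  if (is_x_chrom(record$chrom) && pro$sex == "male" && pro_ac >= 1 &&
      f_ac == 0 && m_ac <= 1) {
    return(out("x_linked"))
  }

  # Confirmed biallelic: homozygous with carrier parents, or the compound-
  # heterozygous partner context established by tier_family().
  if (pro_ac == 2 && f_ac >= 1 && m_ac >= 1) return(out("biallelic"))
  if (comphet_partner) return(out("biallelic"))

  carrier_parents <- c(if (have_father && f_ac >= 1) father,
                       if (have_mother && m_ac >= 1) mother)
  carrier_affected <- pedigree$affected[match(carrier_parents, pedigree$sample_id)] == "affected"

  # Dominant: every affected member carries it; under complete penetrance no
  # unaffected member may carry it.
  acs_aff <- vapply(affected, function(s) ac_of(geno, s), 0L)
  unaffected <- pedigree$sample_id[pedigree$affected == "unaffected"]
  unaff_carrier <- any(vapply(unaffected, function(s) ac_of(geno, s), 0L) >= 1)
  if (all(acs_aff >= 1)) {
    if (!unaff_carrier || config$penetrance == "incomplete") {
      return(out("dominant_inherited"))
    }
  }
  if (length(carrier_parents) && any(carrier_affected)) {
    # An affected carrier parent transmits dominantly even if e.g. an
    # unaffected sibling's genotype is unavailable.
    return(out("dominant_inherited"))
  }

  # Heterozygote inherited from an unaffected carrier parent: dead as a
  # dominant candidate under complete penetrance, but still a recessive
  # candidate when the gene is diagnostic-grade with a biallelic mode.
  if (pro_ac == 1 && any(c("biallelic", "both") %in% gene_mois)) {
    return(out("biallelic", "unpaired_het"))
  }
  out("fails_segregation", "unaffected_carrier")
}

moi_compatible <- function(pattern, moi) {
  switch(pattern,
    de_novo = ,
    dominant_inherited = moi %in% c("monoallelic", "both"),
    biallelic = moi %in% c("biallelic", "both"),
    x_linked = moi %in% c("x_linked", "both"),
    parents_unavailable = TRUE,
    FALSE
  )
}

#' Assign a small-variant tier
#'
#' The full rule chain for one variant allele in one family: legacy quality
#' filter, consequence class, segregation, frequency, then panel
#' intersection. A variant in a diagnostic-grade (Green) gene with a
#' compatible mode of inheritance is Tier 1 when high-impact or a de novo
#' protein-altering change, Tier 2 when an inherited moderate-impact change.
#' A variant that survives frequency, consequence and segregation but whose
#' gene is not Green (or whose mode is incompatible) is Tier 3. An unpaired
#' heterozygote in a Green biallelic gene is at best Tier 3 until a partner
#' allele is established. Everything else is Tier null.
#'
#' @param record one small-variant row.
#' @param pedigree single-family pedigree tibble.
#' @param registry a `crs_panel_registry`.
#' @param panel_ids panels applied to the case.
#' @param panel_version `"original"` or `"updated"`.
#' @param config a `crs_tier_config`.
#' @param comphet_partner see [segregation_pattern()].
#' @return List with `tier` (one of [SMALL_TIERS]) and `reasons`, the rule
#'   identifiers fired on the way to the decision.
#' @export
assign_small_tier <- function(record, pedigree, registry, panel_ids, panel_version,
                              config, comphet_partner = FALSE) {
  reasons <- character()
  res <- function(tier) list(tier = tier, reasons = reasons)

  if (legacy_quality_filter(record, config) == "drop") {
    reasons <- c(reasons, "legacy_quality_filter")
    return(res("TIER_NULL"))
  }
  cls <- consequence_class(record)
  if (cls == "other") {
    reasons <- c(reasons, "consequence_other")
    return(res("TIER_NULL"))
  }

  gene_mois <- green_mois(registry, panel_ids, panel_version, record$gene)
  seg <- segregation_pattern(record, pedigree, config, gene_mois, comphet_partner)
  reasons <- c(reasons, paste0("segregation_", seg$pattern), seg$reasons)
  if (seg$pattern == "fails_segregation") return(res("TIER_NULL"))

  freq_moi <- switch(seg$pattern,
    biallelic = "biallelic",
    x_linked = "x_linked",
    "monoallelic"
  )
  if (!frequency_pass(record, freq_moi, config)) {
    reasons <- c(reasons, "frequency")
    return(res("TIER_NULL"))
  }

  green <- length(gene_mois) > 0
  compatible <- green && any(vapply(gene_mois, function(m) moi_compatible(seg$pattern, m), TRUE))
  if (green && compatible) {
    if ("unpaired_het" %in% seg$reasons) {
      reasons <- c(reasons, "unpaired_biallelic_candidate")
      return(res("TIER3"))
    }
    if (cls == "high_impact" || seg$pattern == "de_novo") {
      reasons <- c(reasons, "green_gene", if (cls == "high_impact") "high_impact" else "de_novo_protein_altering")
      return(res("TIER1"))
    }
    reasons <- c(reasons, "green_gene", "moderate_impact_inherited")
    return(res("TIER2"))
  }
  reasons <- c(reasons, if (!green) "gene_not_green" else "moi_incompatible")
  res("TIER3")
}

#' Would a top-k review of phenotype-driven ranks catch this case?
#'
#' @param case_rank integer rank assigned by the phenotype-driven
#'   prioritizer, or `NA` when unranked.
#' @param k review depth (e.g. 3 for a Top-3 policy).
#' @return `TRUE` iff ranked and `case_rank <= k`.
#' @export
exomiser_rank_review <- function(case_rank, k) {
  if (k < 1) stop_audit("k must be >= 1")
  !is.na(case_rank) && case_rank <= k
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

comphet_flags <- function(records, pedigree, config) {
  flags <- rep(FALSE, nrow(records))
  if (!nrow(records)) return(flags)
  pro <- pedigree[pedigree$is_proband, ]
  if (is.na(pro$father_id) || is.na(pro$mother_id)) return(flags)
  surviving <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    legacy_quality_filter(r, config) == "keep" &&
      consequence_class(r) != "other" &&
      frequency_pass(r, "biallelic", config) &&
      ac_of(r$genotypes[[1]], pro$sample_id) == 1
  }, TRUE)
  for (g in unique(records$gene[surviving])) {
    idx <- which(surviving & records$gene == g)
    if (length(idx) < 2) next
    origin <- vapply(idx, function(i) {
      geno <- records$genotypes[[i]]
      f <- ac_of(geno, pro$father_id)
      m <- ac_of(geno, pro$mother_id)
      if (f >= 1 && m == 0) "paternal" else if (m >= 1 && f == 0) "maternal" else "other"
    }, "")
    if (all(c("paternal", "maternal") %in% origin)) {
      flags[idx[origin %in% c("paternal", "maternal")]] <- TRUE
    }
  }
  flags
}

#' Tier every small variant of a family
#'
#' Orchestrates [assign_small_tier()] over a family's variant set, first
#' establishing compound-heterozygous partner context: two surviving
#' protein-altering heterozygotes in the same gene, one inherited from each
#' parent. Compound heterozygosity requires both alleles to survive the
#' filters — when one partner is removed (e.g. by the legacy indel filter)
#' the survivor is evaluated as an unpaired candidate.
#'
#' @param records small-variant tibble for one family.
#' @param pedigree single-family pedigree tibble.
#' @param registry a `crs_panel_registry`.
#' @param panel_ids panels applied to the case.
#' @param panel_version `"original"` or `"updated"`.
#' @param config a `crs_tier_config`.
#' @return Tibble: `family_id`, `variant_key`, `gene`, `tier`, `reasons`
#'   (semicolon-joined rule identifiers).
#' @export
tier_family <- function(records, pedigree, registry, panel_ids, panel_version, config) {
  ch <- comphet_flags(records, pedigree, config)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- assign_small_tier(records[i, ], pedigree, registry, panel_ids, panel_version,
                           config, comphet_partner = ch[i])
    tibble::tibble(
      family_id = pedigree$family_id[1],
      variant_key = variant_key(records[i, ]),
      gene = records$gene[i],
      tier = r$tier,
      reasons = paste(r$reasons, collapse = ";")
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(family_id = character(), variant_key = character(),
                          gene = character(), tier = character(), reasons = character()))
  }
  do.call(rbind, rows)
}
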