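# Independent oracles, kept deliberately naive.
#
# naive_small_tier(): a brute-force rule evaluator for small-variant
# prioritization — every rule is evaluated as an explicit boolean and the
# tier read off a flat decision list. Shares no code with the engine.
#
# fisher_enum(): exhaustive enumeration of all 2x2 tables with the observed
# margins; the one-tailed p is the summed probability of tables with a
# first-cell count at least as extreme as observed.

naive_small_tier <- function(record, ped, registry, panel_ids, version, config,
                             partnered = FALSE) {
  geno <- record$genotypes[[1]]
  ac <- function(s) geno[[s]]$allele_count
  pro <- ped$sample_id[ped$is_proband]
  dad <- ped$father_id[ped$is_proband]
  mum <- ped$mother_id[ped$is_proband]
  affected <- ped$sample_id[ped$affected == "affected"]
  unaffected <- ped$sample_id[ped$affected == "unaffected"]

  green <- is_diagnostic_grade(registry, panel_ids, version, record$gene)
  mois <- green_mois(registry, panel_ids, version, record$gene)

  # rule booleans
  indel_len <- abs(nchar(record$ref) - nchar(record$alt))
  dropped <- config$legacy_mode && record$low_complexity &&
    (indel_len >= 3 || (nchar(record$ref) > 1 && nchar(record$alt) > 1))
  protein <- record$consequence %in% c("lof", "missense", "inframe_indel")
  high <- record$consequence == "lof"

  have_parents <- !is.na(dad) || !is.na(mum)
  both_parents_ref <- !is.na(dad) && !is.na(mum) && ac(dad) == 0 && ac(mum) == 0
  support_ok <- both_parents_ref && all(vapply(c(dad, mum), function(p) {
    g <- geno[[p]]
    if (is.na(g$total_reads) || g$total_reads == 0) return(FALSE)
    if (config$legacy_mode) g$alt_reads == 0
    else g$alt_reads / g$total_reads <= config$parental_alt_fraction_max
  }, TRUE))
  discordant <- config$sibship_model == "shared_variant" && length(affected) > 1 &&
    any(vapply(affected, ac, 0L) == 0)
  hom_from_carriers <- !is.na(dad) && !is.na(mum) && ac(pro) == 2 &&
    ac(dad) >= 1 && ac(mum) >= 1
  x_hemi <- record$chrom %in% c("X", "chrX") &&
    ped$sex[ped$is_proband] == "male" && ac(pro) >= 1 &&
    (is.na(dad) || ac(dad) == 0) && (is.na(mum) || ac(mum) <= 1) && have_parents
  unaff_carrier <- any(vapply(unaffected, ac, 0L) >= 1)
  all_affected_carry <- all(vapply(affected, ac, 0L) >= 1)
  carrier_parent_affected <- any(vapply(c(dad, mum)[!is.na(c(dad, mum))], function(p) {
    ac(p) >= 1 && ped$affected[ped$sample_id == p] == "affected"
  }, TRUE))
  biallelic_moi_green <- any(mois %in% c("biallelic", "both"))

  if (dropped) return("TIER_NULL")
  if (!protein) return("TIER_NULL")
  if (ac(pro) == 0) return("TIER_NULL")
  if (discordant) return("TIER_NULL")

  pattern <- if (!have_parents) {
    "parents_unavailable"
  } else if (both_parents_ref) {
    if (support_ok) "de_novo" else "fail"
  } else if (x_hemi) {
    "x_linked"
  } else if (hom_from_carriers || partnered) {
    "biallelic"
  } else if (all_affected_carry && (!unaff_carrier || config$penetrance == "incomplete")) {
    "dominant"
  } else if (carrier_parent_affected) {
    "dominant"
  } else if (ac(pro) == 1 && biallelic_moi_green) {
    "candidate_recessive"
  } else {
    "fail"
  }
  if (pattern == "fail") return("TIER_NULL")

  af_ok <- if (pattern %in% c("biallelic", "candidate_recessive")) {
    record$pop_af <= config$af_max_biallelic
  } else if (pattern == "x_linked") {
    record$pop_af <= config$af_max_monoallelic
  } else {
    record$pop_af <= config$af_max_monoallelic
  }
  if (!af_ok) return("TIER_NULL")

  moi_ok <- switch(pattern,
    de_novo = any(mois %in% c("monoallelic", "both")),
    dominant = any(mois %in% c("monoallelic", "both")),
    biallelic = any(mois %in% c("biallelic", "both")),
    candidate_recessive = any(mois %in% c("biallelic", "both")),
    x_linked = any(mois %in% c("x_linked", "both")),
    parents_unavailable = green,
    FALSE
  )
  if (green && moi_ok) {
    if (pattern == "candidate_recessive") return("TIER3")
    if (high || pattern == "de_novo") return("TIER1")
    return("TIER2")
  }
  "TIER3"
}

# Compound-het partner context, recomputed naively: proband-heterozygous,
# protein-altering, filter-surviving variants of the same gene inherited one
# from each parent.
naive_partnered <- function(records, ped, config) {
  geno_ac <- function(i, s) records$genotypes[[i]][[s]]$allele_count
  pro <- ped$sample_id[ped$is_proband]
  dad <- ped$father_id[ped$is_proband]
  mum <- ped$mother_id[ped$is_proband]
  flags <- rep(FALSE, nrow(records))
  if (is.na(dad) || is.na(mum)) return(flags)
  ok <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    alive <- !(config$legacy_mode && r$low_complexity &&
               (abs(nchar(r$ref) - nchar(r$alt)) >= 3 ||
                (nchar(r$ref) > 1 && nchar(r$alt) > 1)))
    alive && r$consequence %in% c("lof", "missense", "inframe_indel") &&
      r$pop_af <= config$af_max_biallelic && geno_ac(i, pro) == 1
  }, TRUE)
  for (g in unique(records$gene)) {
    idx <- which(ok & records$gene == g)
    pat <- idx[vapply(idx, function(i) geno_ac(i, dad) >= 1 && geno_ac(i, mum) == 0, TRUE)]
    mat <- idx[vapply(idx, function(i) geno_ac(i, mum) >= 1 && geno_ac(i, dad) == 0, TRUE)]
    if (length(pat) && length(mat)) flags[c(pat, mat)] <- TRUE
  }
  flags
}

fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  }, 0)
  x0 <- tab[1, 1]
  if (x0 >= r1 * c1 / N) sum(probs[xs >= x0]) else sum(probs[xs <= x0])
}
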