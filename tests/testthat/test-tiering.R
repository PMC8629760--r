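legacy <- mode_config("legacy")
improved <- mode_config("improved")

test_that("consequence and frequency rules behave as configured", {
  stopgain <- mk_rec(consequence = "lof", genotypes = trio_gts())
  missense <- mk_rec(consequence = "missense", genotypes = trio_gts())
  noncoding <- mk_rec(consequence = "noncoding", genotypes = trio_gts())
  expect_equal(consequence_class(stopgain), "high_impact")
  expect_equal(consequence_class(missense), "moderate_impact")
  expect_equal(consequence_class(noncoding), "other")

  rare <- mk_rec(pop_af = 0, genotypes = trio_gts())
  mid <- mk_rec(pop_af = 0.005, genotypes = trio_gts())
  expect_true(frequency_pass(rare, "monoallelic", legacy))
  expect_false(frequency_pass(mid, "monoallelic", legacy))
  expect_true(frequency_pass(mid, "biallelic", legacy))
})

test_that("parental read support separates legacy and improved de novo acceptance", {
  clean <- list(gt(0L), gt(0L))
  one_read <- list(gt(0L), gt(0L, dp = 32L, alt = 1L))
  expect_true(parental_support_check(gt(1L), clean, legacy))
  expect_true(parental_support_check(gt(1L), clean, improved))
  # one mis-called read among 32 maternal reads vetoes the legacy call only
  res <- parental_support_check(gt(1L), one_read, legacy)
  expect_false(res)
  expect_equal(attr(res, "reason"), "parental_support")
  expect_true(parental_support_check(gt(1L), one_read, improved))
  no_cov <- parental_support_check(gt(1L), list(gt(0L, dp = 0L, alt = 0L)), improved)
  expect_false(no_cov)
  expect_equal(attr(no_cov, "reason"), "no_parental_coverage")
})

test_that("the legacy quality filter drops flagged multinucleotide indels only", {
  del14 <- mk_rec(ref = "ATTTTTTTTTTTTTT", alt = "A", consequence = "lof",
                  low_complexity = TRUE, genotypes = trio_gts())
  delins <- mk_rec(ref = "AG", alt = "CCCCCA", consequence = "lof",
                   low_complexity = TRUE, genotypes = trio_gts())
  snv <- mk_rec(ref = "A", alt = "G", low_complexity = TRUE, genotypes = trio_gts())
  unflagged <- mk_rec(ref = "ATTTTTTTTTTTTTT", alt = "A", genotypes = trio_gts())
  expect_equal(legacy_quality_filter(del14, legacy), "drop")
  expect_equal(legacy_quality_filter(delins, legacy), "drop")
  expect_equal(legacy_quality_filter(snv, legacy), "keep")
  expect_equal(legacy_quality_filter(unflagged, legacy), "keep")
  expect_equal(legacy_quality_filter(del14, improved), "keep")
})

test_that("segregation patterns cover trio, sibship and missing-parent cases", {
  ped <- trio_ped()
  dn <- segregation_pattern(mk_rec(genotypes = trio_gts(1L, 0L, 0L)), ped, legacy)
  expect_equal(dn$pattern, "de_novo")

  sib <- sibship_ped()
  discord_gts <- list(sib1 = gt(1L), sib2 = gt(0L), sib3 = gt(0L),
                      dad = gt(0L), mum = gt(0L))
  discord <- segregation_pattern(mk_rec(genotypes = discord_gts), sib, legacy)
  expect_equal(discord$pattern, "fails_segregation")
  expect_true("discordant_sibship" %in% discord$reasons)
  # the same variant under per-individual analysis is an ordinary de novo
  per_ind <- segregation_pattern(mk_rec(genotypes = discord_gts), sib, improved)
  expect_equal(per_ind$pattern, "de_novo")

  single <- segregation_pattern(
    mk_rec(genotypes = list(child = gt(1L))), singleton_ped(), legacy)
  expect_equal(single$pattern, "parents_unavailable")

  # inherited het from an unaffected parent dies under complete penetrance...
  inh <- segregation_pattern(mk_rec(genotypes = trio_gts(1L, 1L, 0L)), ped, legacy)
  expect_equal(inh$pattern, "fails_segregation")
  # ...but survives as a recessive candidate when the gene is green biallelic
  cand <- segregation_pattern(mk_rec(genotypes = trio_gts(1L, 1L, 0L)), ped, legacy,
                              gene_mois = "biallelic")
  expect_equal(cand$pattern, "biallelic")
  expect_true("unpaired_het" %in% cand$reasons)
  # ...or under incomplete penetrance as a dominant
  incomplete <- tier_config(penetrance = "incomplete")
  dom <- segregation_pattern(mk_rec(genotypes = trio_gts(1L, 1L, 0L)), ped, incomplete)
  expect_equal(dom$pattern, "dominant_inherited")
})

test_that("tiering reproduces the audited small-variant outcomes", {
  ped <- trio_ped()
  reg <- test_registry

  # biallelic splice + missense in a green recessive gene: Tier 1 and Tier 2
  biallelic <- rbind(
    mk_rec(gene = "MAN2B1", chrom = "chr19", pos = 12750100L, consequence = "lof",
           genotypes = trio_gts(1L, 1L, 0L)),
    mk_rec(gene = "MAN2B1", chrom = "chr19", pos = 12750900L, consequence = "missense",
           genotypes = trio_gts(1L, 0L, 1L))
  )
  tiers <- tier_family(biallelic, ped, reg, "CRS", "original", legacy)
  expect_equal(tiers$tier, c("TIER1", "TIER2"))

  # de novo stop-gain in a non-panel gene: Tier 3 only
  t3 <- assign_small_tier(
    mk_rec(gene = "KMT5B", chrom = "chr11", pos = 68150100L, consequence = "lof",
           genotypes = trio_gts(1L, 0L, 0L)),
    ped, reg, "CRS", "original", legacy)
  expect_equal(t3$tier, "TIER3")
  expect_true("gene_not_green" %in% t3$reasons)

  # de novo missense with one supporting maternal read: untiered in legacy,
  # Tier 1 on the updated panels with tolerant parental support
  traf7 <- mk_rec(gene = "TRAF7", chrom = "chr16", pos = 2150100L,
                  consequence = "missense",
                  genotypes = trio_gts(1L, 0L, 0L, mum_call = gt(0L, dp = 32L, alt = 1L)))
  null_res <- assign_small_tier(traf7, ped, reg, "CRS", "original", legacy)
  expect_equal(null_res$tier, "TIER_NULL")
  expect_true("parental_support" %in% null_res$reasons)
  t1 <- assign_small_tier(traf7, ped, reg, "CRS", "updated", improved)
  expect_equal(t1$tier, "TIER1")

  # filtered indel partner: the surviving missense is at best Tier 3
  comphet <- rbind(
    mk_rec(gene = "MEGF8", chrom = "chr19", pos = 42350100L, ref = "ATTTTTTTTTTTTTT",
           alt = "A", consequence = "lof", low_complexity = TRUE,
           genotypes = trio_gts(1L, 1L, 0L)),
    mk_rec(gene = "MEGF8", chrom = "chr19", pos = 42350900L, consequence = "missense",
           genotypes = trio_gts(1L, 0L, 1L))
  )
  leg <- tier_family(comphet, ped, reg, "CRS", "original", legacy)
  expect_equal(leg$tier, c("TIER_NULL", "TIER3"))
  expect_true(grepl("legacy_quality_filter", leg$reasons[1]))
  imp <- tier_family(comphet, ped, reg, "CRS", "updated", improved)
  expect_equal(imp$tier, c("TIER1", "TIER2"))
})

test_that("top-k rank review accepts ranked hits only", {
  expect_true(exomiser_rank_review(1L, 3L))
  expect_false(exomiser_rank_review(63L, 3L))
  expect_false(exomiser_rank_review(NA_integer_, 3L))
  expect_error(exomiser_rank_review(1L, 0L), "k must be")
})

test_that("relaxing the configuration never demotes a tier", {
  co <- simulate_cohort(cohort_config(
    n_families = 14, n_trios = 10, n_multiplex = 2, background_per_genome = 8, seed = 3
  ), out_dir = withr::local_tempdir())
  leg <- tier_cohort(co, "legacy")
  imp <- tier_cohort(co, "improved")
  stopifnot(identical(leg$small$variant_key, imp$small$variant_key))
  expect_true(all(tier_rank(imp$small$tier) >= tier_rank(leg$small$tier)))
  expect_true(all(tier_rank(imp$sv$tier) >= tier_rank(leg$sv$tier)))
})

test_that("the engine agrees with the brute-force rule evaluator", {
  for (seed in c(5, 17)) {
    co <- simulate_cohort(cohort_config(
      n_families = 14, n_trios = 10, n_multiplex = 2, background_per_genome = 3,
      seed = seed
    ), out_dir = withr::local_tempdir())
    for (mode in c("legacy", "improved")) {
      cfg <- mode_config(mode)
      version <- if (mode == "legacy") "original" else "updated"
      for (fid in names(co$pedigrees)) {
        recs <- co$small_variants[[fid]]
        ped <- co$pedigrees[[fid]]
        got <- tier_family(recs, ped, co$registry, "CRS", version, cfg)$tier
        partnered <- naive_partnered(recs, ped, cfg)
        want <- vapply(seq_len(nrow(recs)), function(i) {
          naive_small_tier(recs[i, ], ped, co$registry, "CRS", version, cfg,
                           partnered = partnered[i])
        }, "")
        expect_equal(got, want, info = paste(mode, fid, "seed", seed))
      }
    }
  }
})
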