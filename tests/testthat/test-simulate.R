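small_cfg <- function(seed, bg = 5) {
  cohort_config(n_families = 14, n_trios = 10, n_multiplex = 2,
                background_per_genome = bg, seed = seed)
}

test_that("the default configuration reproduces the cohort composition", {
  cfg <- cohort_config(seed = 7)
  co <- simulate_cohort(cfg, out_dir = withr::local_tempdir())
  expect_length(co$pedigrees, 114)
  sizes <- vapply(co$pedigrees, nrow, 0L)
  types <- vapply(co$pedigrees, function(p) {
    if (sum(p$affected == "affected") > 1) "multiplex"
    else if (nrow(p) == 3) "trio"
    else if (nrow(p) == 2) "duo" else "singleton"
  }, "")
  expect_equal(sum(types == "trio"), 72)
  expect_equal(sum(types == "multiplex"), 15)
  expect_equal(sum(types %in% c("duo", "singleton")), 27)
  # one proband per family and parent links internal to the family
  for (p in co$pedigrees) expect_equal(sum(p$is_proband), 1)
})

test_that("generation is byte-deterministic given the seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(small_cfg(21), out_dir = d1)
  co2 <- simulate_cohort(small_cfg(21), out_dir = d2)
  files1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files1, sort(list.files(d2, recursive = TRUE)))
  for (f in files1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  co3 <- simulate_cohort(small_cfg(22), out_dir = withr::local_tempdir())
  expect_false(identical(co1$small_variants, co3$small_variants))
})

test_that("planted archetypes carry the annotations their mechanism needs", {
  co <- simulate_cohort(small_cfg(7), out_dir = withr::local_tempdir())
  truth <- co$truth
  find_rec <- function(aid, role = "primary") {
    row <- truth[truth$archetype_id == aid & truth$role %in% role, ]
    recs <- co$small_variants[[row$family_id]]
    recs[variant_key_of(recs) == row$variant_key, ]
  }
  variant_key_of <- function(r) paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")

  # parental-read archetype: mother shows 1 supporting read out of 32
  pr <- find_rec("parental_read_denovo")
  ped <- co$pedigrees[[truth$family_id[truth$archetype_id == "parental_read_denovo"]]]
  mum <- ped$mother_id[ped$is_proband]
  expect_equal(pr$genotypes[[1]][[mum]][c("total_reads", "alt_reads")],
               list(total_reads = 32L, alt_reads = 1L))

  # filtered indel: low-complexity flag and a >=3 nt length change
  fi <- find_rec("filtered_indel_compound_het")
  expect_true(fi$low_complexity)
  expect_gte(abs(nchar(fi$ref) - nchar(fi$alt)), 3)

  # discordant sibship: hosted by a family of three affected male siblings
  ds_fam <- truth$family_id[truth$archetype_id == "discordant_sibship_denovo"]
  ds_ped <- co$pedigrees[[ds_fam]]
  expect_equal(sum(ds_ped$affected == "affected" & ds_ped$sex == "male"), 3)

  # mosaic duplication: father flagged as mosaic carrier
  dup_row <- truth[truth$archetype_id == "nonpanel_dup_mosaic", ]
  dup <- co$sv_calls[[dup_row$family_id]]
  dup <- dup[dup$sv_type == "DUP", ]
  fa <- co$pedigrees[[dup_row$family_id]]$father_id[co$pedigrees[[dup_row$family_id]]$is_proband]
  expect_true(fa %in% dup$mosaic_carriers[[1]])

  # background variants never touch panel or archetype genes
  panel_genes <- unique(c(test_registry[["CRS@original"]]$entries$gene,
                          test_registry[["CRS@updated"]]$entries$gene,
                          archetype_table()$gene))
  for (fid in names(co$small_variants)) {
    recs <- co$small_variants[[fid]]
    bg <- recs[!(variant_key_of(recs) %in% truth$variant_key), ]
    expect_false(any(bg$gene %in% panel_genes))
  }
})

test_that("impossible configurations are rejected", {
  expect_error(cohort_config(n_families = 10, n_trios = 8, n_multiplex = 5),
               "exceeds n_families")
  expect_error(cohort_config(n_families = 5, n_trios = 3, n_multiplex = 1),
               "trio archetypes")
  expect_error(
    cohort_config(archetype_counts = c(bogus_archetype = 1L)),
    "unknown archetype"
  )
})

test_that("the archetype oracle is a plain rule-table lookup", {
  expect_equal(expected_tier("nonpanel_denovo", "legacy"), "TIER3")
  expect_equal(expected_tier("filtered_indel_compound_het", "legacy"), "TIER_NULL")
  expect_equal(expected_tier("filtered_indel_compound_het", "improved"), "TIER1")
  expect_equal(expected_tier("green_gene_denovo_lof", "legacy"), "TIER1")
  expect_equal(expected_tier("green_cnv_del", "improved"), "TIER_A")
  expect_error(expected_tier("not_a_thing"), "unknown archetype")
})

test_that("tiering recovers every planted archetype across seeds and modes", {
  for (seed in 1:5) {
    co <- simulate_cohort(small_cfg(seed, bg = 3), out_dir = withr::local_tempdir())
    planted <- co$truth[!is.na(co$truth$variant_key), ]
    for (mode in c("legacy", "improved")) {
      tiers <- tier_cohort(co, mode)
      combined <- rbind(tiers$small[, c("family_id", "variant_key", "tier")],
                        tiers$sv[, c("family_id", "variant_key", "tier")])
      m <- merge(planted, combined, by = c("family_id", "variant_key"))
      expect_equal(nrow(m), nrow(planted))
      want <- if (mode == "legacy") m$expected_tier_legacy else m$expected_tier_improved
      expect_equal(m$tier, want, info = paste("seed", seed, mode))
    }
  }
})

test_that("common background variants are never prioritized (type-I control)", {
  co <- simulate_cohort(small_cfg(13, bg = 25), out_dir = withr::local_tempdir())
  for (mode in c("legacy", "improved")) {
    cfg <- mode_config(mode)
    tiers <- tier_cohort(co, mode)$small
    planted_keys <- co$truth$variant_key[!is.na(co$truth$variant_key)]
    bg <- tiers[!(tiers$variant_key %in% planted_keys), ]
    expect_false(any(bg$tier %in% c("TIER1", "TIER2")))
    # and specifically nothing above the monoallelic ceiling can reach Tier 1/2
    for (fid in names(co$small_variants)) {
      recs <- co$small_variants[[fid]]
      common <- recs[recs$pop_af > cfg$af_max_monoallelic, ]
      if (!nrow(common)) next
      keys <- paste(common$chrom, common$pos, common$ref, common$alt, sep = ":")
      expect_false(any(tiers$tier[tiers$family_id == fid &
                                    tiers$variant_key %in% keys] %in%
                         c("TIER1", "TIER2")))
    }
  }
})

test_that("syndromic fractions stay inside binomial 99% bounds", {
  hits <- 0; n <- 0
  for (seed in 1:3) {
    co <- simulate_cohort(small_cfg(seed, bg = 0), out_dir = withr::local_tempdir())
    fam_synd <- unique(co$truth[, c("family_id", "syndromic")])
    hits <- hits + sum(fam_synd$syndromic)
    n <- n + nrow(fam_synd)
  }
  p <- 82 / 114
  bounds <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})
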