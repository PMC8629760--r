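test_that("PED parsing builds validated families and infers the proband", {
  path <- withr::local_tempfile(lines = c(
    "famA\tchild\tdad\tmum\t2\t2",
    "famA\tdad\t0\t0\t1\t1",
    "famA\tmum\t0\t0\t2\t1"
  ))
  peds <- parse_ped(path)
  expect_length(peds, 1)
  ped <- peds$famA
  expect_equal(nrow(ped), 3)
  expect_equal(ped$sample_id[ped$is_proband], "child")
  expect_equal(ped$affected, c("affected", "unaffected", "unaffected"))
})

test_that("a multiplex sibship of three affected brothers parses", {
  path <- withr::local_tempfile(lines = c(
    "famS sib1 dad mum 1 2 1",
    "famS sib2 dad mum 1 2 0",
    "famS sib3 dad mum 1 2 0",
    "famS dad 0 0 1 1 0",
    "famS mum 0 0 2 1 0"
  ))
  ped <- parse_ped(path)$famS
  expect_equal(nrow(ped), 5)
  expect_equal(sum(ped$affected == "affected"), 3)
  expect_equal(sum(ped$is_proband), 1)
})

test_that("malformed or invalid pedigrees are rejected with informative errors", {
  five_cols <- withr::local_tempfile(lines = "famA child dad mum 2")
  expect_error(parse_ped(five_cols), "line 1")
  no_affected <- withr::local_tempfile(lines = c(
    "famA child dad mum 2 1", "famA dad 0 0 1 1", "famA mum 0 0 2 1"
  ))
  expect_error(parse_ped(no_affected), "no affected")
  bad_parent <- withr::local_tempfile(lines = "famA child ghost 0 2 2")
  expect_error(parse_ped(bad_parent), "not a member")
})

write_test_vcf <- function(lines) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="c">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="af">',
    '##INFO=<ID=LCR,Number=0,Type=Flag,Description="lcr">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tchild\tdad\tmum"
  )
  withr::local_tempfile(lines = c(header, lines), fileext = ".vcf",
                        .local_envir = parent.frame())
}

test_that("small-variant parsing populates trio genotypes and read evidence", {
  path <- write_test_vcf(c(
    paste0("chr15\t100\t.\tA\tG\t60\tPASS\tGENE=TCF12;CSQCLASS=missense;POPAF=0\t",
           "GT:DP:AD\t0/1:22:10,12\t0/0:30:30,0\t0/0:32:31,1")
  ))
  recs <- parse_small_vcf(path, trio_ped())
  expect_equal(nrow(recs), 1)
  g <- recs$genotypes[[1]]
  expect_equal(g$child$allele_count, 1L)
  expect_equal(g$child$alt_reads, 12L)
  expect_equal(g$dad$allele_count, 0L)
  # the single mis-called maternal read: 1 of 32 reads matches the variant
  expect_equal(g$mum[c("allele_count", "total_reads", "alt_reads")],
               list(allele_count = 0L, total_reads = 32L, alt_reads = 1L))
})

test_that("multi-allelic sites decompose into one record per ALT allele", {
  path <- write_test_vcf(c(
    paste0("chr15\t200\t.\tA\tG,T\t50\tPASS\tGENE=TCF12;CSQCLASS=missense\t",
           "GT:DP:AD\t1/2:30:5,12,13\t0/1:28:14,14,0\t0/2:25:13,0,12")
  ))
  recs <- parse_small_vcf(path, trio_ped())
  expect_equal(nrow(recs), 2)
  expect_equal(recs$pos, c(200L, 200L))
  expect_equal(recs$alt, c("G", "T"))
  expect_equal(recs$genotypes[[1]]$child$allele_count, 1L)
  expect_equal(recs$genotypes[[2]]$child$allele_count, 1L)
  expect_equal(recs$genotypes[[1]]$child$alt_reads, 12L)
  expect_equal(recs$genotypes[[2]]$dad$alt_reads, 0L)
  # missing POPAF reads as 0 so novel alleles are never frequency-filtered
  expect_equal(recs$pop_af, c(0, 0))
})

test_that("sample mismatches with the pedigree are errors", {
  path <- write_test_vcf(
    "chr1\t5\t.\tA\tG\t50\tPASS\tGENE=X;CSQCLASS=missense;POPAF=0\tGT:DP:AD\t0/1:9:5,4\t0/0:9:9,0\t0/0:9:9,0"
  )
  ped2 <- trio_ped()[1:2, ]  # VCF has an extra sample relative to this pedigree
  expect_error(parse_small_vcf(path, ped2), "not in pedigree")
  ped4 <- rbind(trio_ped(), tibble::tibble(
    family_id = "famT", sample_id = "gran", father_id = NA, mother_id = NA,
    sex = "female", affected = "unaffected", is_proband = FALSE
  ))
  expect_error(parse_small_vcf(path, ped4), "missing from VCF")
})

test_that("small-variant records round-trip bit-exactly through the writer", {
  ped <- trio_ped()
  recs <- rbind(
    mk_rec(genotypes = trio_gts(1L, 0L, 0L), pop_af = 0.000123),
    mk_rec(gene = "MEGF8", chrom = "chr19", pos = 42350100L, ref = "ATTTTTTTTTTTTTT",
           alt = "A", consequence = "lof", low_complexity = TRUE,
           genotypes = trio_gts(1L, 1L, 0L)),
    mk_rec(gene = "ARID1B", chrom = "chr6", pos = 156800500L,
           genotypes = trio_gts(1L, 0L, 0L, mum_call = gt(0L, dp = 32L, alt = 1L)))
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_small_vcf(recs, path, samples = ped$sample_id)
  back <- parse_small_vcf(path, ped)
  expect_equal(back, recs)
})

test_that("an empty record set writes a valid header-only VCF", {
  ped <- trio_ped()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_small_vcf(empty_small_variants(), path, samples = ped$sample_id)
  back <- parse_small_vcf(path, ped)
  expect_equal(nrow(back), 0)
  sv_path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(empty_sv_calls(), sv_path, samples = ped$sample_id)
  expect_equal(nrow(parse_sv_vcf(sv_path, ped)), 0)
})

test_that("SV parsing captures type, span, carriers and mosaic evidence", {
  ped <- trio_ped()
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=QS,Number=1,Type=Float,Description="q">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=MOSAIC,Number=1,Type=Float,Description="m">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tchild\tdad\tmum"
  )
  path <- withr::local_tempfile(lines = c(header,
    "chr19\t42600001\t.\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=42914000;QS=50\tGT:MOSAIC\t0/1:0\t0/0:0\t0/0:0",
    "chr7\t12000001\t.\tN\t<INV>\t45\tPASS\tSVTYPE=INV;END=25400000;QS=45\tGT:MOSAIC\t0/1:0\t0/0:0\t0/0:0",
    "chr12\t54200001\t.\tN\t<DUP>\t40\tPASS\tSVTYPE=DUP;END=54485000;QS=40\tGT:MOSAIC\t0/1:0\t0/0:0.12\t0/0:0"
  ), fileext = ".vcf")
  calls <- parse_sv_vcf(path, ped)
  expect_equal(nrow(calls), 3)
  del <- calls[calls$sv_type == "DEL", ]
  expect_equal(sv_length(del), 314000L)
  expect_equal(del$carriers[[1]], "child")
  expect_true(calls$breakpoints_only[calls$sv_type == "INV"])
  dup <- calls[calls$sv_type == "DUP", ]
  expect_equal(dup$mosaic_carriers[[1]], "dad")
})

test_that("SV records with missing END or alien SVTYPE are handled", {
  ped <- trio_ped()
  header <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tchild\tdad\tmum"
  )
  no_end <- withr::local_tempfile(lines = c(header,
    "chr1\t100\t.\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL\tGT\t0/1\t0/0\t0/0"), fileext = ".vcf")
  expect_error(parse_sv_vcf(no_end, ped), "END")
  alien <- withr::local_tempfile(lines = c(header,
    "chr1\t100\t.\tN\t<BND>\t50\tPASS\tSVTYPE=BND;END=200\tGT\t0/1\t0/0\t0/0"),
    fileext = ".vcf")
  expect_warning(calls <- parse_sv_vcf(alien, ped), "SVTYPE")
  expect_equal(nrow(calls), 0)
})

test_that("generator outputs round-trip through all three readers", {
  co <- simulate_cohort(cohort_config(
    n_families = 14, n_trios = 10, n_multiplex = 2, background_per_genome = 4, seed = 11
  ), out_dir = withr::local_tempdir())
  peds <- parse_ped(co$paths$ped)
  expect_equal(peds[names(co$pedigrees)], co$pedigrees, ignore_attr = TRUE)
  for (fid in names(co$pedigrees)) {
    expect_equal(parse_small_vcf(co$paths$small_vcfs[[fid]], co$pedigrees[[fid]]),
                 co$small_variants[[fid]])
  }
  for (fid in names(co$sv_calls)) {
    expect_equal(parse_sv_vcf(co$paths$sv_vcfs[[fid]], co$pedigrees[[fid]]),
                 co$sv_calls[[fid]])
  }
})
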