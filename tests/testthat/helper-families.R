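# In-code fixtures: minimal pedigrees and variant records.

trio_ped <- function(fid = "famT", sex = "female") {
  tibble::tibble(
    family_id = fid,
    sample_id = c("child", "dad", "mum"),
    father_id = c("dad", NA, NA),
    mother_id = c("mum", NA, NA),
    sex = c(sex, "male", "female"),
    affected = c("affected", "unaffected", "unaffected"),
    is_proband = c(TRUE, FALSE, FALSE)
  )
}

sibship_ped <- function(fid = "famS", n_sibs = 3) {
  rbind(
    tibble::tibble(
      family_id = fid, sample_id = paste0("sib", seq_len(n_sibs)),
      father_id = "dad", mother_id = "mum", sex = "male", affected = "affected",
      is_proband = seq_len(n_sibs) == 1
    ),
    tibble::tibble(
      family_id = fid, sample_id = c("dad", "mum"), father_id = NA, mother_id = NA,
      sex = c("male", "female"), affected = "unaffected", is_proband = FALSE
    )
  )
}

singleton_ped <- function(fid = "fam1") {
  tibble::tibble(family_id = fid, sample_id = "child", father_id = NA, mother_id = NA,
                 sex = "male", affected = "affected", is_proband = TRUE)
}

gt <- function(ac, dp = 30L, alt = NULL) {
  list(allele_count = as.integer(ac), total_reads = as.integer(dp),
       alt_reads = as.integer(if (is.null(alt)) (if (ac > 0) 15L else 0L) else alt))
}

mk_rec <- function(gene = "TCF12", consequence = "missense", chrom = "chr15",
                   pos = 57200100L, ref = "A", alt = "G", pop_af = 0, qual = 60,
                   low_complexity = FALSE, genotypes) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, consequence = consequence, pop_af = pop_af, qual = qual,
                 low_complexity = low_complexity, genotypes = list(genotypes))
}

trio_gts <- function(child = 1L, dad = 0L, mum = 0L, mum_call = NULL, dad_call = NULL) {
  list(child = gt(child), dad = dad_call %||% gt(dad), mum = mum_call %||% gt(mum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_registry <- bundled_panels()
test_spans <- gene_universe()
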