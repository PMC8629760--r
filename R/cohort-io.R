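# Family-aware I/O: PED pedigrees, small-variant VCF, SV VCF.
#
# Coordinates are 1-based inclusive in all files and in the internal model;
# interval arithmetic against 0-based half-open BED happens only at the
# gene-span boundary (see read_gene_spans()).

PED_SEX <- c("1" = "male", "2" = "female")
PED_AFF <- c("1" = "unaffected", "2" = "affected")

#' Parse a PED pedigree file
#'
#' Reads the classical 6-column whitespace-separated pedigree dialect
#' (family, individual, father, mother, sex, affection; `0` or `-9` = missing).
#' An optional 7th column marks the proband explicitly (`1` = proband);
#' without it, the first affected member of each family is taken as proband.
#'
#' @param path path to a PED file.
#' @return A named list of pedigrees, one per family. Each pedigree is a
#'   tibble with columns `family_id`, `sample_id`, `father_id`, `mother_id`
#'   (`NA` when missing), `sex` (`male`/`female`/`unknown`), `affected`
#'   (`affected`/`unaffected`/`unknown`) and logical `is_proband`.
#' @details Validated invariants: parent identifiers refer to members of the
#'   same family; every family has at least one affected member and exactly
#'   one proband.
#' @export
parse_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  n <- lengths(fields)
  bad <- which(n != 6L & n != 7L)
  if (length(bad)) {
    stop_audit("PED parse error at line ", bad[1], ": expected 6 or 7 columns, found ", n[bad[1]])
  }
  m <- do.call(rbind, lapply(fields, function(f) c(f, rep(NA, 7 - length(f)))))
  ped <- tibble::tibble(
    family_id = m[, 1],
    sample_id = m[, 2],
    father_id = ifelse(m[, 3] %in% c("0", "-9"), NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] %in% c("0", "-9"), NA_character_, m[, 4]),
    sex       = unname(ifelse(m[, 5] %in% names(PED_SEX), PED_SEX[m[, 5]], "unknown")),
    affected  = unname(ifelse(m[, 6] %in% names(PED_AFF), PED_AFF[m[, 6]], "unknown")),
    is_proband = !is.na(m[, 7]) & m[, 7] == "1"
  )
  out <- lapply(split(ped, factor(ped$family_id, levels = unique(ped$family_id))), validate_pedigree)
  out
}

validate_pedigree <- function(ped) {
  fam <- ped$family_id[1]
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    missing_ref <- setdiff(ref[!is.na(ref)], ped$sample_id)
    if (length(missing_ref)) {
      stop_audit("family ", fam, ": ", col, " '", missing_ref[1], "' is not a member of the family")
    }
  }
  if (!any(ped$affected == "affected")) {
    stop_audit("family ", fam, ": no affected members")
  }
  if (!any(ped$is_proband)) {
    ped$is_proband[which(ped$affected == "affected")[1]] <- TRUE
  }
  if (sum(ped$is_proband) != 1L) {
    stop_audit("family ", fam, ": expected exactly one proband, found ", sum(ped$is_proband))
  }
  ped
}

#' Write pedigrees back to PED
#'
#' Emits the 7-column dialect (proband flag in column 7). `parse_ped()` on the
#' output reproduces the input exactly.
#'
#' @param pedigrees a single pedigree tibble or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigrees, path) {
  if (is.data.frame(pedigrees)) pedigrees <- list(pedigrees)
  ped <- do.call(rbind, pedigrees)
  sex_code <- c(male = "1", female = "2", unknown = "0")
  aff_code <- c(unaffected = "1", affected = "2", unknown = "0")
  lines <- paste(
    ped$family_id, ped$sample_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex_code[ped$sex], aff_code[ped$affected],
    ifelse(ped$is_proband, "1", "0"),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

proband_id <- function(pedigree) pedigree$sample_id[pedigree$is_proband][1]

# ---------------------------------------------------------------------------
# Small-variant VCF

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info, perl = TRUE))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|$)"), info)
}

vcf_body <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = length(fix) > 0, dimnames = list(NULL, names(fix)))
  list(fix = fix, gt = gt)
}

check_samples <- function(vcf_samples, pedigree) {
  extra <- setdiff(vcf_samples, pedigree$sample_id)
  missing <- setdiff(pedigree$sample_id, vcf_samples)
  if (length(extra)) stop_audit("VCF sample(s) not in pedigree: ", paste(extra, collapse = ", "))
  if (length(missing)) stop_audit("pedigree member(s) missing from VCF: ", paste(missing, collapse = ", "))
}

CONSEQUENCES <- c("lof", "missense", "inframe_indel", "synonymous", "noncoding", "other")

#' Parse a small-variant VCF into per-allele records
#'
#' Reads a VCF v4.2 file (dialect: INFO keys `GENE`, `CSQCLASS`, `POPAF`,
#' optional flag `LCR`; FORMAT `GT:DP:AD`) and decomposes multi-allelic sites
#' so that each returned row describes exactly one ALT allele. Genotypes are
#' populated for every pedigree member; VCF samples must match the pedigree
#' exactly.
#'
#' @param path path to the VCF (plain or bgzip).
#' @param pedigree a single-family pedigree tibble from [parse_ped()].
#' @return Tibble with one row per variant allele: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene`, `consequence`, `pop_af` (missing AF is read as 0 so
#'   novel variants are never frequency-filtered), `qual`, `low_complexity`
#'   and a `genotypes` list-column of per-sample calls, each a list with
#'   `allele_count` (0/1/2 copies of this ALT), `total_reads` and `alt_reads`.
#' @export
parse_small_vcf <- function(path, pedigree) {
  b <- vcf_body(path)
  fix <- b$fix
  gt <- b$gt
  samples <- if (is.null(gt)) character() else colnames(gt)[-1]
  check_samples(samples, pedigree)
  if (nrow(fix) == 0) return(empty_small_variants())

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- unname(fix[i, "INFO"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    calls <- strsplit(gt[i, samples], ":", fixed = TRUE)
    af <- suppressWarnings(as.numeric(info_field(info, "POPAF")))
    if (is.na(af)) af <- 0
    for (k in seq_along(alts)) {
      geno <- lapply(calls, function(f) {
        f <- setNames(as.list(f), fmt[seq_along(f)])
        alleles <- strsplit(f$GT, "[/|]")[[1]]
        ad <- as.integer(strsplit(f$AD %||% NA_character_, ",", fixed = TRUE)[[1]])
        list(
          allele_count = sum(alleles == as.character(k)),
          total_reads = as.integer(f$DP %||% NA),
          alt_reads = if (length(ad) > k) ad[k + 1L] else NA_integer_
        )
      })
      names(geno) <- samples
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = unname(fix[i, "CHROM"]),
        pos = as.integer(unname(fix[i, "POS"])),
        ref = unname(fix[i, "REF"]),
        alt = alts[k],
        gene = info_field(info, "GENE"),
        consequence = match.arg(info_field(info, "CSQCLASS"), CONSEQUENCES),
        pop_af = af,
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        low_complexity = info_flag(info, "LCR"),
        genotypes = list(geno)
      )
    }
  }
  do.call(rbind, rows)
}

#' Empty record containers
#'
#' Zero-row tibbles with the small-variant / structural-call schemas; useful
#' as rbind seeds and for writing header-only files.
#'
#' @return A zero-row tibble.
#' @export
empty_small_variants <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(), pop_af = numeric(),
    qual = numeric(), low_complexity = logical(), genotypes = list()
  )
}

vcf_header <- function(samples, sv = FALSE) {
  info <- if (sv) {
    c(
      '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
      '##INFO=<ID=QS,Number=1,Type=Float,Description="Call quality score">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=MOSAIC,Number=1,Type=Float,Description="Mosaic allele fraction (0 = constitutional)">'
    )
  } else {
    c(
      '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
      '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
      '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
      '##INFO=<ID=LCR,Number=0,Type=Flag,Description="Low-complexity region">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'
    )
  }
  c(
    "##fileformat=VCFv4.2",
    info,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
}

gt_string <- function(allele_count) c("0/0", "0/1", "1/1")[allele_count + 1L]

fmt_num <- function(x) {
  ifelse(is.na(x), ".", vapply(x, format, "", digits = 17, scientific = FALSE, trim = TRUE))
}

#' Write small-variant records as VCF
#'
#' Serializes records from [parse_small_vcf()] (or the cohort generator) back
#' to the documented VCF dialect. Parsing the output reproduces the input
#' exactly (positions, alleles and genotypes bit-for-bit).
#'
#' @param records small-variant tibble.
#' @param path output path.
#' @param samples sample order for the genotype columns; defaults to the order
#'   in the first record. Required when `records` is empty.
#' @return `path`, invisibly.
#' @export
write_small_vcf <- function(records, path, samples = NULL) {
  if (is.null(samples)) {
    if (nrow(records) == 0) stop_audit("samples must be given for an empty record set")
    samples <- names(records$genotypes[[1]])
  }
  lines <- vcf_header(samples)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    info <- paste0("GENE=", r$gene, ";CSQCLASS=", r$consequence, ";POPAF=", fmt_num(r$pop_af))
    if (r$low_complexity) info <- paste0(info, ";LCR")
    geno <- r$genotypes[[1]][samples]
    cols <- vapply(geno, function(g) {
      paste(gt_string(g$allele_count), g$total_reads,
            paste(g$total_reads - g$alt_reads, g$alt_reads, sep = ","), sep = ":")
    }, "")
    lines <- c(lines, paste(c(r$chrom, r$pos, ".", r$ref, r$alt, fmt_num(r$qual), "PASS",
                              info, "GT:DP:AD", cols), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SV VCF

SV_TYPES <- c("DEL", "DUP", "INV")

#' Parse a structural-variant VCF
#'
#' Reads SV records (INFO `SVTYPE`, `END`; quality from `QUAL`, falling back
#' to INFO `QS`). Carriers are the samples with a non-reference genotype;
#' mosaic carriers are flagged through the `MOSAIC` FORMAT key (a mosaic
#' allele fraction; ordinary VCF genotypes cannot express mosaicism).
#' Balanced inversions carry no copy-number change, so `INV` records are
#' breakpoint-only by construction.
#'
#' @param path path to the SV VCF.
#' @param pedigree single-family pedigree tibble.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `sv_type`, `qual_score`, list-columns `carriers` and `mosaic_carriers`,
#'   and `breakpoints_only`. Records with an unsupported SVTYPE are skipped
#'   with a warning; DEL/DUP without END is an error.
#' @export
parse_sv_vcf <- function(path, pedigree) {
  b <- vcf_body(path)
  fix <- b$fix
  gt <- b$gt
  samples <- if (is.null(gt)) character() else colnames(gt)[-1]
  check_samples(samples, pedigree)
  if (nrow(fix) == 0) return(empty_sv_calls())

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- unname(fix[i, "INFO"])
    svtype <- info_field(info, "SVTYPE")
    if (is.na(svtype) || !svtype %in% SV_TYPES) {
      warning("skipping SV record with unsupported SVTYPE: ", svtype, call. = FALSE)
      next
    }
    end <- suppressWarnings(as.integer(info_field(info, "END")))
    if (is.na(end)) stop_audit("SV record at ", fix[i, "CHROM"], ":", fix[i, "POS"], " lacks END")
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    if (is.na(qual)) qual <- suppressWarnings(as.numeric(info_field(info, "QS")))
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    calls <- strsplit(gt[i, samples], ":", fixed = TRUE)
    carrier <- vapply(calls, function(f) {
      g <- setNames(as.list(f), fmt[seq_along(f)])$GT
      any(strsplit(g, "[/|]")[[1]] == "1")
    }, TRUE)
    mosaic <- vapply(calls, function(f) {
      mf <- suppressWarnings(as.numeric(setNames(as.list(f), fmt[seq_along(f)])$MOSAIC %||% "0"))
      !is.na(mf) && mf > 0
    }, TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = unname(fix[i, "CHROM"]),
      start = as.integer(unname(fix[i, "POS"])),
      end = end,
      sv_type = svtype,
      qual_score = qual,
      carriers = list(sort(samples[carrier])),
      mosaic_carriers = list(sort(samples[mosaic])),
      breakpoints_only = svtype == "INV"
    )
  }
  if (!length(rows)) return(empty_sv_calls())
  out <- do.call(rbind, rows)
  stopifnot(all(out$end >= out$start))
  out
}

#' @rdname empty_small_variants
#' @export
empty_sv_calls <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(), sv_type = character(),
    qual_score = numeric(), carriers = list(), mosaic_carriers = list(),
    breakpoints_only = logical()
  )
}

#' Write structural calls as VCF
#'
#' Inverse of [parse_sv_vcf()]; round-trips all supported fields.
#'
#' @inheritParams write_small_vcf
#' @param records SV tibble.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, samples = NULL) {
  if (is.null(samples)) {
    if (nrow(records) == 0) stop_audit("samples must be given for an empty record set")
    samples <- sort(unique(unlist(c(records$carriers, records$mosaic_carriers))))
  }
  lines <- vcf_header(samples, sv = TRUE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    info <- paste0("SVTYPE=", r$sv_type, ";END=", r$end, ";QS=", fmt_num(r$qual_score))
    cols <- vapply(samples, function(s) {
      gt <- if (s %in% r$carriers[[1]]) "0/1" else "0/0"
      mf <- if (s %in% r$mosaic_carriers[[1]]) "0.1" else "0"
      paste(gt, mf, sep = ":")
    }, "")
    lines <- c(lines, paste(c(r$chrom, r$start, ".", "N", paste0("<", r$sv_type, ">"),
                              fmt_num(r$qual_score), "PASS", info, "GT:MOSAIC", cols),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Length of a structural call in bases
#'
#' 1-based inclusive: `end - start + 1`.
#'
#' @param call one row of an SV tibble (or a vectorized pair of columns).
#' @return integer length(s).
#' @export
sv_length <- function(call) call$end - call$start + 1L
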