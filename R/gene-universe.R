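# A bundled synthetic gene table: coding spans for the genes named in the
# audited cohort plus invented filler genes, on toy contigs with plausible
# scale. Built in code (no reference download); coordinates are 1-based
# inclusive and entirely synthetic.

ARCHETYPE_GENES <- tibble::tibble(
  gene  = c("TCF12", "MAN2B1", "MEGF8",  "ARID1B", "MMP21",
            "SMAD6", "HNRNPK", "FBXO11", "TRAF7",  "OGT",
            "KMT5B", "SOX6",   "BRWD3",  "CDK13",  "PTCH1",
            "SMAD2", "ALX1",   "TWIST1", "ERF",    "HOXC12",
            "GPC3",  "ZBTB20", "FGFR2",  "FGFR3",  "EFNB1"),
  chrom = c("chr15", "chr19", "chr19", "chr6",  "chr10",
            "chr15", "chr9",  "chr2",  "chr16", "chrX",
            "chr11", "chr11", "chrX",  "chr7",  "chr9",
            "chr18", "chr12", "chr7",  "chr19", "chr12",
            "chrX",  "chr3",  "chr10", "chr4",  "chrX"),
  start = c(57200000L, 12750000L, 42350000L, 156800000L, 127450000L,
            66700000L, 86580000L, 47800000L,  2150000L, 70750000L,
            68150000L, 16020000L, 79900000L, 40050000L, 98200000L,
            45350000L, 85670000L, 19150000L, 42750000L, 54340000L,
            132670000L, 114050000L, 123230000L, 1790000L, 68050000L),
  width = c(350000L, 15000L, 110000L, 430000L, 45000L,
            75000L, 12000L, 120000L, 22000L, 40000L,
            40000L, 600000L, 140000L, 150000L, 70000L,
            95000L, 8000L, 2200L, 7500L, 5000L,
            450000L, 600000L, 120000L, 15000L, 13000L)
)

#' Synthetic gene universe
#'
#' Deterministic table of ~200 gene coding spans: the genes named in the
#' audited cohort (placed on their customary chromosomes, with synthetic
#' coordinates) plus invented filler genes used for benign background
#' variation. The filler pool never overlaps the named genes.
#'
#' @param n_filler number of filler genes (default 180).
#' @return Tibble with `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
gene_universe <- function(n_filler = 180) {
  named <- tibble::tibble(
    gene = ARCHETYPE_GENES$gene,
    chrom = ARCHETYPE_GENES$chrom,
    start = ARCHETYPE_GENES$start,
    end = ARCHETYPE_GENES$start + ARCHETYPE_GENES$width - 1L
  )
  contigs <- paste0("chr", c(1:22, "X"))
  i <- seq_len(n_filler)
  filler <- tibble::tibble(
    gene = sprintf("FILLER%03d", i),
    chrom = contigs[(i - 1L) %% length(contigs) + 1L],
    # deterministic lattice: 300 kb stride, 40 kb genes, offset away from
    # the named spans (which all sit above 1.7 Mb)
    start = 200000L + ((i - 1L) %/% length(contigs)) * 300000L,
    end = 200000L + ((i - 1L) %/% length(contigs)) * 300000L + 39999L
  )
  rbind(named, filler)
}

#' Write gene spans as BED
#'
#' BED is 0-based half-open; conversion from the internal 1-based inclusive
#' spans happens here.
#'
#' @param spans tibble from [gene_universe()] or [read_gene_spans()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_spans <- function(spans, path) {
  bed <- data.frame(chrom = spans$chrom, start = spans$start - 1L, end = spans$end,
                    name = spans$gene)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene spans from BED
#'
#' @param path BED file (chrom, start, end, name).
#' @return Tibble with 1-based inclusive `start`/`end`.
#' @export
read_gene_spans <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    gene = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer converts to 1-based
    end = GenomicRanges::end(gr)
  )
}

spans_granges <- function(spans) {
  GenomicRanges::GRanges(
    seqnames = spans$chrom,
    ranges = IRanges::IRanges(start = spans$start, end = spans$end),
    gene = spans$gene
  )
}
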