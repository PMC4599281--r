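## Shared fixtures, all built in code at test time.

## The seven-patient discovery cohort's clinical baseline characteristics.
clinical_sheet <- function() {
  data.frame(
    sample = paste0("Pt", 1:7),
    age = c(54, 45, 47, 60, 61, 66, 68),
    tumor_size_mm = c(60, 45, 72, 13, 15, 83, 20),
    ttp_months = c(55.5, 38.1, 9.3, 8.1, 4.7, 3.5, 4.3),
    stringsAsFactors = FALSE
  )
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## Minimal 2-sample VCF exercising genotype mapping and phasing.
mini_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("chr3", "121643804", "rs2257212", "C", "T", ".", "PASS", ".",
          "GT", "0/1", "1|1", sep = "\t"),
    paste("chr3", "121646641", ".", "A", "G", ".", "PASS", ".",
          "GT", "./.", "./1", sep = "\t"),
    paste("chr7", "100", ".", "G", "A", ".", "PASS", ".",
          "GT", "0|0", "1/0", sep = "\t")
  ), ".vcf")
}

## A 2-exon plus-strand gene on chr1 with explicit UTRs:
## exon1 [101,160] (UTR 101-130, CDS 131-160), intron [161,200],
## exon2 [201,260] (CDS 201-233, UTR 234-260). CDS length 63.
toy_gene <- function() {
  cds_seq <- paste0("ATG", paste(rep("GCT", 19), collapse = ""), "TAA")
  seq <- paste(rep("T", 300), collapse = "")
  substr(seq, 131, 160) <- substr(cds_seq, 1, 30)
  substr(seq, 201, 233) <- substr(cds_seq, 31, 63)
  gene_model(
    "TOY1", "chr1", "+", span = c(51, 300),
    cds = data.frame(start = c(131, 201), end = c(160, 233)),
    exons = data.frame(start = c(101, 201), end = c(160, 260)),
    seq = seq, seq_offset = 1L
  )
}

## Exhaustive genotype vectors over n samples (columns of a matrix).
all_genotype_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:2), n)))
}
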