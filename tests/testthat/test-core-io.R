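test_that("VCF genotypes map to non-reference allele counts, phase-blind", {
  gm <- read_vcf(mini_vcf())
  expect_equal(nrow(gm$sites), 3L)
  expect_equal(gm$samples, c("S1", "S2"))
  i <- which(gm$sites$pos == 121643804)
  expect_equal(gm$sites$chrom[i], "chr3")
  expect_equal(gm$sites$ref[i], "C")
  expect_equal(gm$sites$alt[i], "T")
  expect_equal(gm$sites$id[i], "rs2257212")
  expect_equal(unname(gm$g[i, ]), c(1L, 2L))      # 0/1 and 1|1
  j <- which(gm$sites$pos == 121646641)
  expect_true(all(is.na(gm$g[j, ])))              # ./. and ./1 both missing
  k <- which(gm$sites$pos == 100)
  expect_equal(unname(gm$g[k, ]), c(0L, 1L))      # 0|0 and 1/0
})

test_that("multi-allelic records are rejected unless split is requested", {
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "500", ".", "A", "C,G", ".", "PASS", ".",
          "GT", "0/1", "2/2", "1/2", sep = "\t")
  ), ".vcf")
  expect_error(read_vcf(vcf), "multi-allelic")
  gm <- read_vcf(vcf, split_multiallelic = TRUE)
  expect_equal(gm$sites$alt, c("C", "G"))
  ## allele C: het, other-alt genotype -> missing, mixed -> missing
  expect_equal(unname(gm$g[1, ]), c(1L, NA, NA))
  expect_equal(unname(gm$g[2, ]), c(NA, 2L, NA))
})

test_that("malformed VCF records are reported by line number", {
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT", "0/1", sep = "\t"),
    "chr1\t200\tbroken"
  ), ".vcf")
  expect_error(read_vcf(vcf), "line 4")
  expect_error(read_vcf(write_lines_tmp("just text", ".vcf")), "fileformat")
})

test_that("VCF round trip preserves sites, IDs and genotype classes", {
  d <- make_discovery_cohort(discovery_design(seed = 11, n_decoys = 20))
  path <- tempfile(fileext = ".vcf")
  write_vcf(d$genotypes, path)
  back <- read_vcf(path)
  expect_equal(back$sites, d$genotypes$sites)
  expect_equal(back$samples, d$genotypes$samples)
  expect_equal(back$g, d$genotypes$g)
})

test_that("sample sheets parse, validate and preserve file order", {
  path <- tempfile(fileext = ".tsv")
  write.table(clinical_sheet(), path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- read_sample_sheet(path)
  expect_equal(nrow(sheet), 7L)
  expect_equal(sheet$ttp_months, c(55.5, 38.1, 9.3, 8.1, 4.7, 3.5, 4.3))

  empty <- write_lines_tmp("sample\tttp_months", ".tsv")
  expect_equal(nrow(read_sample_sheet(empty)), 0L)

  dup <- write_lines_tmp(c("sample\tttp_months", "A\t3", "A\t4"), ".tsv")
  expect_error(read_sample_sheet(dup), "duplicate")

  orphan <- write_lines_tmp(c("sample\tttp_months\tlabel", "A\t3\t", "B\t\t"), ".tsv")
  expect_error(read_sample_sheet(orphan), "neither")

  labels_only <- write_lines_tmp(c("sample\tlabel", "A\tGood", "B\tpoor"), ".tsv")
  expect_equal(read_sample_sheet(labels_only)$label, c("good", "poor"))
})

test_that("cohort summaries recover clinical medians and IQRs", {
  sheet <- clinical_sheet()
  expect_equal(summarize_cohort(sheet, "age")$median, 60)
  expect_equal(summarize_cohort(sheet, "tumor_size_mm")$median, 45)
  one <- summarize_cohort(data.frame(x = 7), "x")
  expect_equal(one$median, 7)
  expect_equal(one$iqr, c(7, 7))
  expect_error(summarize_cohort(data.frame(x = c("a", "b")), "x"), "numeric")

  ## median equals sort-and-pick for odd n
  set.seed(404)
  for (rep in 1:20) {
    x <- runif(2 * sample(1:10, 1) + 1, 0, 100)
    expect_equal(summarize_cohort(data.frame(x = x), "x")$median,
                 sort(x)[(length(x) + 1) / 2])
  }
})

test_that("BED12 coordinates convert to 1-based inclusive gene models", {
  ## one gene, 2 blocks; thick [130,341) -> CDS [131,200] u [301,341]
  ## (111 bases, 37 codons); chromStart 100 -> first base at 101 internally
  fa <- tempfile(fileext = ".fa")
  seq <- paste(rep("A", 500), collapse = "")
  bed <- write_lines_tmp(paste(
    "chr5", "100", "400", "GENE1", "0", "+", "130", "341", "0",
    "2", "100,100,", "0,200,", sep = "\t"
  ), ".bed")
  cds_seq <- paste0("ATG", paste(rep("GGT", 35), collapse = ""), "TAA")
  substr(seq, 131, 200) <- substr(cds_seq, 1, 70)
  substr(seq, 301, 341) <- substr(cds_seq, 71, 111)
  writeLines(c(">chr5", seq), fa)
  models <- read_gene_models(bed, fa)
  gm <- models$GENE1
  expect_equal(gm$span, c(101L, 400L))
  expect_equal(gm$exons, data.frame(start = c(101L, 301L), end = c(200L, 400L)))
  expect_equal(gm$cds, data.frame(start = c(131L, 301L), end = c(200L, 341L)))
  expect_equal(substr(cds_sequence(gm), 1, 3), "ATG")
})

test_that("GFF3 gene models parse with ordered CDS and fail without sequence", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    paste("chr2", "x", "gene", "1000", "1500", ".", "+", ".",
          "ID=gene:G2;Name=G2", sep = "\t"),
    paste("chr2", "x", "CDS", "1301", "1336", ".", "+", "0",
          "Parent=gene:G2", sep = "\t"),
    paste("chr2", "x", "CDS", "1101", "1130", ".", "+", "0",
          "Parent=gene:G2", sep = "\t")
  ), ".gff3")
  seq <- paste(rep("C", 1600), collapse = "")
  cds_seq <- paste0("ATG", paste(rep("CAC", 20), collapse = ""), "TGA")
  substr(seq, 1101, 1130) <- substr(cds_seq, 1, 30)
  substr(seq, 1301, 1336) <- substr(cds_seq, 31, 66)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr2", seq), fa)
  gm <- read_gene_models(gff, fa)$G2
  expect_equal(nrow(gm$cds), 2L)
  expect_equal(gm$cds$start, c(1101L, 1301L))  # re-ordered

  fa_wrong <- tempfile(fileext = ".fa")
  writeLines(c(">chr9", "ACGT"), fa_wrong)
  expect_error(read_gene_models(gff, fa_wrong), "FASTA lacks")
})

test_that("CDS length not divisible by three is rejected by gene name", {
  expect_error(
    gene_model("BADGENE", "chr1", "+", c(1, 100),
               cds = data.frame(start = 10, end = 20)),
    "BADGENE.*not divisible by 3"
  )
})
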