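test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("CTC"), "L")
  expect_equal(translate_codon("TTC"), "F")
  expect_equal(translate_codon("ctc"), "L")
  expect_error(translate_codon("CTN"), "3-mer")
  expect_error(translate_codon("CT"), "3-mer")
})

test_that("candidate-region filter uses gene bodies with flank semantics", {
  gm <- toy_gene()  # span chr1:51-300
  genes <- list(TOY1 = gm)
  cand <- list(targets = "TOY1", adme = character(0))
  sites <- variant_sites("chr1", c(150, 301, 40), rep("T", 3), rep("A", 3))
  kept0 <- filter_candidate_regions(sites, genes, cand, flank = 0)
  expect_equal(kept0$pos, 150L)
  expect_equal(kept0$genes, "TOY1")
  kept1 <- filter_candidate_regions(sites, genes, cand, flank = 1)
  expect_setequal(kept1$pos, c(150L, 301L))
  expect_warning(
    filter_candidate_regions(sites, genes,
                             list(targets = c("TOY1", "GHOST"), adme = NULL)),
    "GHOST"
  )
})

test_that("genomic features classify as coding, UTR or intronic", {
  gm <- toy_gene()
  feat <- function(pos) classify_feature(list(chrom = "chr1", pos = pos), gm)
  expect_equal(feat(140), "coding")    # inside CDS exon 1
  expect_equal(feat(180), "intronic")  # gap between the CDS exons
  expect_equal(feat(110), "utr")       # exon 1, upstream of the CDS
  expect_equal(feat(250), "utr")       # exon 2, downstream of the stop
  expect_equal(feat(60), "intronic")   # span, outside exons
  expect_error(feat(500), "outside span")
})

test_that("effect calls reproduce the published amino-acid pairs", {
  models <- make_table3_gene_models(seed = 2)
  tab <- table3_variants()
  calls <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    annotate_effect(tab[i, ], models[[tab$gene[i]]])
  }))
  expect_equal(calls$ref_aa, tab$ref_aa)
  expect_equal(calls$var_aa, tab$var_aa)
  same <- tab$ref_aa == tab$var_aa
  expect_equal(sum(same), 9L)
  expect_true(all(calls$category[same] == "coding_synonymous"))
  expect_true(all(calls$category[!same] == "coding_missense"))
})

test_that("nonsense, frameshift and in-frame indels classify correctly", {
  gm <- toy_gene()
  ## codon 2 of TOY1 is GCT (positions 134-136); T->A at its 3rd base
  ## keeps alanine; the stop test needs a codon where one change stops:
  ## replace via a custom gene with a TAC codon
  cds_seq <- paste0("ATGTAC", paste(rep("GCT", 18), collapse = ""), "TAA")
  seq <- paste(rep("G", 200), collapse = "")
  substr(seq, 101, 163) <- cds_seq
  g2 <- gene_model("TOY2", "chr2", "+", c(51, 200),
                   cds = data.frame(start = 101, end = 163),
                   seq = seq, seq_offset = 1L)
  nonsense <- annotate_effect(
    variant_sites("chr2", 106, "C", "A"), g2
  )
  expect_equal(nonsense$category, "coding_nonsense")
  expect_equal(nonsense$ref_aa, "Y")
  expect_equal(nonsense$var_aa, "*")
  expect_equal(nonsense$aa_pos, 2L)

  mis <- annotate_effect(variant_sites("chr2", 107, "G", "C"), g2)
  expect_equal(mis$category, "coding_missense")  # GCT -> CCT, A -> P

  del2 <- annotate_effect(variant_sites("chr2", 110, "GCT", "G"), g2)
  expect_equal(del2$category, "coding_frameshift")
  del3 <- annotate_effect(variant_sites("chr2", 110, "GCTG", "G"), g2)
  expect_equal(del3$category, "coding_inframe_indel")

  expect_error(annotate_effect(variant_sites("chr2", 106, "G", "A"), g2),
               "reference mismatch")
})

test_that("minus-strand effect calls equal the mirrored plus-strand calls", {
  ## same codon content built on both strands must give identical calls
  tab <- table3_variants()
  set.seed(9)
  for (g in c("ABCB1", "SLC7A7")) {  # the minus-strand models
    rows <- tab[tab$gene == g, ]
    models <- make_table3_gene_models(seed = 4)
    expect_equal(models[[g]]$strand, "-")
    for (i in seq_len(nrow(rows))) {
      eff <- annotate_effect(rows[i, ], models[[g]])
      expect_equal(c(eff$ref_aa, eff$var_aa), c(rows$ref_aa[i], rows$var_aa[i]))
    }
  }
})

test_that("cascade counts decrease monotonically and handle empty input", {
  models <- make_table3_gene_models(seed = 6)
  cand <- table3_candidates()
  d <- make_discovery_cohort(discovery_design(seed = 19, embed_table3 = TRUE))
  hits <- scan_segregation(d$genotypes, classify_responders(d$sheet))
  casc <- run_cascade(hits, d$models, d$candidates)
  expect_true(casc$n_associated >= casc$n_in_candidate_genes)
  expect_true(casc$n_in_candidate_genes >= casc$n_coding)
  expect_true(casc$n_coding >= casc$n_nonsynonymous)

  empty <- run_cascade(hits[0, ], models, cand)
  expect_equal(empty$n_associated, 0L)
  expect_equal(empty$n_in_candidate_genes, 0L)
  expect_equal(empty$n_coding, 0L)
  expect_equal(empty$n_nonsynonymous, 0L)

  ## decoy-only cohort: nothing lands in candidate genes
  d2 <- make_discovery_cohort(discovery_design(seed = 23, n_decoys = 40,
                                               n_planted = c(0L, 0L, 0L, 0L)))
  hits2 <- scan_segregation(d2$genotypes, classify_responders(d2$sheet))
  rep2 <- run_cascade(hits2, d2$models, d2$candidates)
  expect_equal(rep2$n_in_candidate_genes, 0L)
})

test_that("every coding SNV call is synonymous, missense or nonsense", {
  models <- make_table3_gene_models(seed = 12)
  gm <- models$SLC15A2
  set.seed(21)
  cds_pos <- unlist(lapply(seq_len(nrow(gm$cds)), function(i) {
    seq(gm$cds$start[i], gm$cds$end[i])
  }))
  for (pos in sample(cds_pos, 40)) {
    ref <- substr(gm$seq, pos - gm$seq_offset + 1L, pos - gm$seq_offset + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- annotate_effect(variant_sites(gm$chrom, pos, ref, alt), gm)
    expect_true(eff$category %in%
                  c("coding_synonymous", "coding_missense", "coding_nonsense"))
    expect_equal(eff$category == "coding_synonymous", eff$ref_aa == eff$var_aa)
    expect_equal(eff$category == "coding_nonsense", eff$var_aa == "*")
  }
})
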