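test_that("TTP threshold splits the clinical cohort into responder classes", {
  labels <- classify_responders(within(clinical_sheet(), label <- NA), 5)
  expect_equal(sum(labels == "good"), 4L)
  expect_equal(sum(labels == "poor"), 3L)
  expect_equal(unname(labels), rep(c("good", "poor"), c(4, 3)))

  all_good <- data.frame(sample = c("A", "B"), ttp_months = c(10, 20),
                         label = NA_character_)
  expect_error(classify_responders(all_good), "non-empty")

  explicit <- data.frame(sample = c("A", "B"), ttp_months = NA_real_,
                         label = c("poor", "good"))
  expect_equal(unname(classify_responders(explicit)), c("poor", "good"))

  ## explicit label wins over TTP
  mixed <- data.frame(sample = c("A", "B"), ttp_months = c(50, 2),
                      label = c("poor", "good"))
  expect_equal(unname(classify_responders(mixed)), c("poor", "good"))
})

test_that("subclass rules match their dominant/recessive definitions", {
  labels <- setNames(rep(c("good", "poor"), c(4, 3)), paste0("S", 1:7))
  ms <- function(g) match_subclasses(as.integer(g), labels)$subclasses
  expect_equal(ms(c(1, 2, 1, 1, 0, 0, 0)), 1L)
  expect_equal(ms(c(2, 2, 2, 2, 0, 0, 0)), c(1L, 2L))
  expect_equal(ms(c(0, 0, 0, 0, 2, 2, 2)), c(3L, 4L))
  expect_equal(ms(c(1, 1, 1, 1, 1, 1, 1)), integer(0))
})

test_that("missing genotypes disqualify a site unless tolerated", {
  labels <- setNames(rep(c("good", "poor"), c(2, 2)), paste0("S", 1:4))
  g <- c(1L, NA, 0L, 0L)
  strict <- match_subclasses(g, labels)
  expect_equal(strict$subclasses, integer(0))
  expect_false(strict$complete)
  tol <- match_subclasses(g, labels, missing_policy = "tolerate")
  expect_equal(tol$subclasses, 1L)  # rule holds on observed samples
  ## a fully missing class can never certify a match
  expect_equal(
    match_subclasses(c(NA, NA, 0L, 0L), labels, "tolerate")$subclasses,
    integer(0)
  )
})

test_that("allele flip g -> 2 - g swaps subclasses 1<->4 and 2<->3", {
  labels <- setNames(rep(c("good", "poor"), c(3, 2)), paste0("S", 1:5))
  swap <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)
  set.seed(77)
  for (rep in 1:200) {
    g <- sample(0:2, 5, replace = TRUE)
    a <- match_subclasses(as.integer(g), labels)$subclasses
    b <- match_subclasses(as.integer(2 - g), labels)$subclasses
    expect_setequal(unname(swap[as.character(a)]), b)
  }
})

test_that("closed-form null match counts equal exhaustive enumeration", {
  for (ng in 1:4) {
    for (np in 1:4) {
      labels <- setNames(rep(c("good", "poor"), c(ng, np)),
                         paste0("S", seq_len(ng + np)))
      vecs <- all_genotype_vectors(ng + np)
      per <- c(0L, 0L, 0L, 0L)
      union <- 0L
      for (i in seq_len(nrow(vecs))) {
        sub <- match_subclasses(as.integer(vecs[i, ]), labels)$subclasses
        per[sub] <- per[sub] + 1L
        if (length(sub)) union <- union + 1L
      }
      nm <- null_match_count(ng, np)
      expect_equal(nm$per_subclass, per)
      expect_equal(nm$union, union)
      expect_equal(nm$total, 3^(ng + np))
    }
  }
  expect_equal(null_match_count(1, 1)$union, 6)
  expect_error(null_match_count(0, 3), ">= 1")
})

test_that("scan recovers planted sites, ignores decoys, orders by genome", {
  d <- make_discovery_cohort(discovery_design(seed = 7, n_decoys = 97,
                                              n_planted = c(3L, 0L, 0L, 0L)))
  labels <- classify_responders(d$sheet)
  hits <- scan_segregation(d$genotypes, labels)
  planted <- d$truth[d$truth$class == "planted", ]
  expect_equal(nrow(hits), 3L)
  expect_setequal(paste(hits$chrom, hits$pos), paste(planted$chrom, planted$pos))
  expect_true(all(grepl("1", hits$subclasses)))
  ## genome order
  expect_equal(order(hits$pos[hits$chrom == hits$chrom[1]]),
               seq_len(sum(hits$chrom == hits$chrom[1])))
})

test_that("an all-reference matrix yields no associated variants", {
  sites <- variant_sites("chr1", c(100, 200), c("A", "C"), c("G", "T"))
  gm <- genotype_matrix(sites, paste0("S", 1:4), matrix(0L, 2, 4))
  labels <- setNames(rep(c("good", "poor"), each = 2), paste0("S", 1:4))
  expect_equal(nrow(scan_segregation(gm, labels)), 0L)
})

test_that("scan output is invariant to sample and variant order", {
  d <- make_discovery_cohort(discovery_design(seed = 13, n_decoys = 30))
  labels <- classify_responders(d$sheet)
  ref_hits <- scan_segregation(d$genotypes, labels)
  set.seed(5)
  rp <- sample(nrow(d$genotypes$sites))
  cp <- sample(length(d$genotypes$samples))
  shuffled <- genotype_matrix(d$genotypes$sites[rp, , drop = FALSE],
                              d$genotypes$samples[cp],
                              d$genotypes$g[rp, cp, drop = FALSE])
  expect_equal(scan_segregation(shuffled, labels), ref_hits)
})

test_that("violating a planted vector in one sample destroys the match", {
  labels <- setNames(rep(c("good", "poor"), c(4, 3)), paste0("S", 1:7))
  set.seed(31)
  for (s in 1:4) {
    for (rep in 1:10) {
      g <- switch(s,
        c(sample(1:2, 4, TRUE), rep(0L, 3)),
        c(rep(2L, 4), sample(0:1, 3, TRUE)),
        c(rep(0L, 4), sample(1:2, 3, TRUE)),
        c(sample(0:1, 4, TRUE), rep(2L, 3))
      )
      expect_true(s %in% match_subclasses(as.integer(g), labels)$subclasses)
      ## break the defining constraint in one sample
      i <- sample(7, 1)
      bad <- g
      bad[i] <- switch(s,
        if (i <= 4) 0L else 1L,   # good loses A / poor gains A
        if (i <= 4) sample(0:1, 1) else 2L,
        if (i <= 4) sample(1:2, 1) else 0L,
        if (i <= 4) 2L else sample(0:1, 1)
      )
      expect_false(s %in% match_subclasses(as.integer(bad), labels)$subclasses)
    }
  }
})
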