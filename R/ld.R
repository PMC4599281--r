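#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci from
#' unphased diploid genotypes via the classic EM algorithm: every genotype
#' combination except the double heterozygote has unambiguous haplotype
#' phase; the double heterozygotes are fractionally assigned to the two
#' possible phase resolutions according to the current frequency estimates.
#' Initialization is at linkage equilibrium (product of allele
#' frequencies), which makes the estimate deterministic.
#'
#' From the fitted haplotype frequencies: `D = pAB - pA * pB`,
#' `Dprime = |D| / Dmax`, and `r2 = D^2 / (pA (1-pA) pB (1-pB))`.
#'
#' @param g1,g2 integer vectors of alternate-allele counts (0/1/2, `NA`
#'   allowed) over the same samples.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return `list(D, Dprime, r2, haplotypes = named frequencies (AB, Ab,
#'   aB, ab with "A"/"B" the alternate alleles), n, converged, n_iter)`.
#' @export
ld_pairwise <- function(g1, g2, tol = 1e-8, max_iter = 100L) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[keep]); g2 <- as.integer(g2[keep])
  n <- length(g1)
  if (n < 2L) stop("need >= 2 samples with calls at both loci")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) stop("genotypes must be 0/1/2")
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic locus: LD is undefined")
  }

  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  ## Unambiguous haplotype counts (AB, Ab, aB, ab); A/B = alternate alleles.
  base <- c(
    AB = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"],
    Ab = 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"],
    aB = 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"],
    ab = 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"]
  )
  ndh <- cnt["1", "1"]  # double heterozygotes: AB/ab or Ab/aB

  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt_new <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- cnt_new / (2 * n)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
    if (iter >= max_iter) break
  }

  D <- unname(p["AB"] - pA * pB)
  Dmax <- if (D >= 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  list(
    D = D,
    Dprime = if (Dmax > 0) abs(D) / Dmax else NA_real_,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    haplotypes = p, n = n, converged = converged, n_iter = iter
  )
}

#' Pairwise LD matrix over several SNPs
#'
#' @param g matrix or data.frame of alternate-allele counts, samples in
#'   rows, SNPs in columns.
#' @param stat `"r2"` or `"Dprime"`.
#' @param ... passed to [ld_pairwise()].
#' @return symmetric matrix of the chosen statistic (diagonal 1).
#' @export
ld_matrix <- function(g, stat = c("r2", "Dprime"), ...) {
  stat <- match.arg(stat)
  g <- as.matrix(g)
  k <- ncol(g)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(g), colnames(g))
  if (k < 2L) return(out)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      out[i, j] <- out[j, i] <- ld_pairwise(g[, i], g[, j], ...)[[stat]]
    }
  }
  out
}
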