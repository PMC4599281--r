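#' Normalize chromosome names
#'
#' Collapses the two common chromosome-name dialects ("1" vs "chr1") onto a
#' single style. All internal coordinates in pharmseg are 1-based inclusive
#' and chromosome names are "chr"-prefixed by default.
#'
#' @param x character vector of chromosome names.
#' @param style `"chr"` (default) to add the prefix, `"plain"` to strip it.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("3", "chr3", "X"))
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(x))
  if (style == "chr") paste0("chr", bare) else bare
}

## Natural chromosome rank: chr1..chr22, chrX, chrY, chrM, then others.
chrom_rank <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(bare))
  ifelse(!is.na(num), num,
    ifelse(bare == "X", 23L,
      ifelse(bare == "Y", 24L, ifelse(bare %in% c("M", "MT"), 25L, 26L))
    )
  )
}

## Permutation putting a site table in (chrom, pos) genome order.
order_sites <- function(sites) {
  order(chrom_rank(sites$chrom), sites$chrom, sites$pos, sites$ref, sites$alt)
}

valid_allele <- function(a) {
  nchar(a) >= 1L & grepl("^[ACGT]+$", a)
}

#' Construct a variant site table
#'
#' @param chrom,pos,ref,alt,id parallel vectors describing biallelic variant
#'   sites; `pos` is the 1-based position of the first reference base, and
#'   `ref`/`alt` are plus-strand allele strings over A/C/G/T.
#' @return a `data.frame` with columns chrom, pos, ref, alt, id.
#' @export
variant_sites <- function(chrom, pos, ref, alt, id = NA_character_) {
  sites <- data.frame(
    chrom = normalize_chrom(chrom), pos = as.integer(pos),
    ref = toupper(ref), alt = toupper(alt),
    id = as.character(id), stringsAsFactors = FALSE
  )
  if (any(sites$pos < 1L)) stop("variant positions must be >= 1")
  if (!all(valid_allele(sites$ref)) || !all(valid_allele(sites$alt))) {
    stop("ref and alt alleles must be non-empty strings over {A,C,G,T}")
  }
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  key <- site_key(sites)
  if (anyDuplicated(key)) {
    stop("duplicate variant sites: ", paste(key[duplicated(key)], collapse = ", "))
  }
  sites
}

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Construct a genotype matrix
#'
#' The central discovery-stage container: biallelic variant sites by samples,
#' each genotype stored as the count of non-reference alleles (0, 1, 2) with
#' `NA` for missing calls. Indefinite calls (a missing allele in a diploid
#' genotype) are treated as missing, since perfect-segregation logic needs
#' definite calls.
#'
#' @param sites variant site table from [variant_sites()].
#' @param samples character vector of unique sample identifiers.
#' @param g integer matrix, `nrow(sites)` x `length(samples)`, entries in
#'   \{0, 1, 2, NA\}.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, g) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  sites <- as.data.frame(sites)
  row.names(sites) <- NULL
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (nrow(g) != nrow(sites) || ncol(g) != length(samples)) {
    stop("genotype matrix must be |sites| x |samples|")
  }
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g))) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  dimnames(g) <- list(site_key(sites), samples)
  structure(list(sites = sites, samples = samples, g = g),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d samples (%.1f%% missing)\n",
    nrow(x$sites), length(x$samples), 100 * mean(is.na(x$g))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$g)
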