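#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file into a [genotype_matrix()]. Genotypes are mapped to
#' non-reference allele counts: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2,
#' and any genotype containing a missing allele (`./.`, `./1`, ...) -> `NA`.
#' Phasing separators (`|` vs `/`) are ignored.
#'
#' Multi-allelic records are rejected by default because the segregation
#' analysis is defined over biallelic sites; with
#' `split_multiallelic = TRUE` each alternate allele becomes its own
#' biallelic site and genotypes carrying a *different* alternate allele are
#' set to missing (conservative: they are neither reference nor the allele
#' under test).
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param split_multiallelic split multi-allelic records instead of erroring.
#' @param chrom_style chromosome-name style passed to [normalize_chrom()].
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, split_multiallelic = FALSE, chrom_style = "chr") {
  check_vcf_lines(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ", conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  fmt <- fix$FORMAT
  if (is.null(fmt)) fmt <- v@gt[, "FORMAT"]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw) || all(is.na(gt_raw))) {
    stop("VCF has no GT genotype field: ", path)
  }
  gt_raw <- as.matrix(gt_raw)

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && !split_multiallelic) {
    stop(
      "multi-allelic record(s) at ",
      paste(fix$CHROM[multi], fix$POS[multi], sep = ":", collapse = ", "),
      "; set split_multiallelic = TRUE to split them"
    )
  }

  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); id <- character(0)
  g <- NULL
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      chrom <- c(chrom, fix$CHROM[i])
      pos <- c(pos, as.integer(fix$POS[i]))
      ref <- c(ref, fix$REF[i])
      alt <- c(alt, alts[k])
      id <- c(id, ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", NA_character_, fix$ID[i]))
      g <- rbind(g, gt_to_count(gt_raw[i, ], allele = k))
    }
  }
  sites <- variant_sites(chrom, pos, ref, alt, id)
  sites$chrom <- normalize_chrom(sites$chrom, chrom_style)
  genotype_matrix(sites, colnames(gt_raw), g)
}

## Light structural validation so malformed lines are reported by number.
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header): ", path)
  }
  header_at <- which(startsWith(lines, "#CHROM"))
  if (length(header_at) != 1L) stop("VCF must have exactly one #CHROM header line: ", path)
  n_fields <- length(strsplit(lines[header_at], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10L) stop("VCF has no sample/genotype columns: ", path)
  body <- seq(header_at + 1L, length.out = length(lines) - header_at)
  for (i in body) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop("malformed VCF record at line ", i, ": expected ", n_fields,
           " tab-separated fields, found ", nf)
    }
  }
  invisible(TRUE)
}

## "0/1", "1|0", "./1" ... -> count of `allele`, NA if any allele missing
## or (for split multi-allelics) a different alternate allele is present.
gt_to_count <- function(gt, allele = 1L) {
  vapply(gt, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(sub(":.*$", "", s), "[/|]")[[1]]
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai))) return(NA_integer_)
    if (any(!ai %in% c(0L, allele))) return(NA_integer_)
    sum(ai == allele)
  }, integer(1))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Minimal writer round-tripping everything [read_vcf()] keeps: site
#' coordinates, alleles, IDs and genotype classes (`0/0`, `0/1`, `1/1`,
#' `./.`).
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ord <- order_sites(gm$sites)
  sites <- gm$sites[ord, , drop = FALSE]
  g <- gm$g[ord, , drop = FALSE]
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt_str[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i],
            ifelse(is.na(sites$id[i]), ".", sites$id[i]),
            sites$ref[i], sites$alt[i], ".", "PASS", ".", "GT",
            gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
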