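#' Translate a single codon
#'
#' Standard genetic code; stop codons return `"*"`.
#'
#' @param codon 3-letter string over A/C/G/T.
#' @return one amino-acid letter (or `"*"`).
#' @export
#' @examples
#' translate_codon("CTC")  # L
#' translate_codon("TTC")  # F
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be a 3-mer over {A,C,G,T}: got '", codon, "'")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Restrict variants to candidate gene regions
#'
#' A site is kept iff it lies within `flank` bp of the gene body (span) of
#' at least one candidate gene (drug-target or ADME). Because most
#' associated variants in such scans are intronic, the filter deliberately
#' uses the whole gene body, not just exons. Candidate symbols without a
#' gene model are ignored with a warning.
#'
#' @param sites variant site table (columns chrom, pos, ref, alt, ...).
#' @param genes named list of [gene_model()] objects.
#' @param candidates `list(targets =, adme =)` from [read_candidate_genes()].
#' @param flank bp added on both sides of each gene span (default 0).
#' @return the kept rows of `sites` with an added `genes` column
#'   (comma-joined symbols of every overlapping candidate gene).
#' @export
filter_candidate_regions <- function(sites, genes, candidates, flank = 0L) {
  stopifnot(flank >= 0L)
  symbols <- unique(c(candidates$targets, candidates$adme))
  missing <- setdiff(symbols, names(genes))
  if (length(missing)) {
    warning("candidate gene(s) without a gene model, ignored: ",
            paste(missing, collapse = ", "))
  }
  models <- genes[intersect(symbols, names(genes))]
  assigned <- vapply(seq_len(nrow(sites)), function(i) {
    hit <- vapply(models, function(gm) {
      gm$chrom == sites$chrom[i] &&
        sites$pos[i] >= gm$span[1] - flank &&
        sites$pos[i] <= gm$span[2] + flank
    }, logical(1))
    paste(names(models)[hit], collapse = ",")
  }, character(1))
  out <- sites[nzchar(assigned), , drop = FALSE]
  out$genes <- assigned[nzchar(assigned)]
  row.names(out) <- NULL
  out
}

#' Classify a variant's genomic feature within a gene
#'
#' `coding` if the position falls in a CDS interval; otherwise `utr` if it
#' falls inside an exon (exonic but non-coding); otherwise `intronic`.
#' When the model carries no exon structure, non-CDS positions are labelled
#' `intronic` (UTRs are then indistinguishable from introns).
#'
#' @param site one-row variant site (or list with `chrom`, `pos`).
#' @param gene a [gene_model()].
#' @return `"coding"`, `"utr"` or `"intronic"`.
#' @export
classify_feature <- function(site, gene) {
  pos <- site$pos
  if (normalize_chrom(site$chrom) != gene$chrom ||
      pos < gene$span[1] || pos > gene$span[2]) {
    stop("site ", site$chrom, ":", pos, " outside span of ", gene$gene)
  }
  in_iv <- function(iv) any(iv$start <= pos & iv$end >= pos)
  if (in_iv(gene$cds)) return("coding")
  if (!is.null(gene$exons) && in_iv(gene$exons)) return("utr")
  "intronic"
}

#' Codon-level effect of a variant within a gene
#'
#' For coding SNVs the affected codon is located by the variant's offset in
#' the concatenated CDS (minus-strand genes: reverse-complemented, codon
#' index counted from the strand-correct 5' end), and the reference and
#' variant codons are translated: synonymous if the amino acid is
#' unchanged, nonsense if the variant codon is a stop, otherwise missense.
#' Coding indels are `coding_frameshift` when the length difference is not
#' a multiple of 3, else `coding_inframe_indel`. Non-coding positions get
#' the [classify_feature()] category.
#'
#' @param site one-row variant site.
#' @param gene a [gene_model()] with sequence.
#' @return one-row data.frame: gene, category, ref_aa, var_aa, aa_pos.
#' @export
annotate_effect <- function(site, gene) {
  feature <- classify_feature(site, gene)
  blank <- data.frame(
    gene = gene$gene, category = feature, ref_aa = NA_character_,
    var_aa = NA_character_, aa_pos = NA_integer_, stringsAsFactors = FALSE
  )
  if (feature != "coding") return(blank)

  is_snv <- nchar(site$ref) == 1L && nchar(site$alt) == 1L
  if (!is_snv) {
    shift <- abs(nchar(site$ref) - nchar(site$alt)) %% 3L
    blank$category <- if (shift != 0L) "coding_frameshift" else "coding_inframe_indel"
    return(blank)
  }

  ref_at <- gene_seq_at(gene, site$pos, site$pos)
  if (ref_at != site$ref) {
    stop("reference mismatch at ", site$chrom, ":", site$pos, " in ",
         gene$gene, ": sequence has ", ref_at, ", site.ref is ", site$ref)
  }

  ## 1-based offset of pos in the plus-orientation CDS concatenation
  prior <- 0L
  i0 <- NA_integer_
  for (i in seq_len(nrow(gene$cds))) {
    s <- gene$cds$start[i]; e <- gene$cds$end[i]
    if (site$pos >= s && site$pos <= e) {
      i0 <- prior + (site$pos - s + 1L)
      break
    }
    prior <- prior + (e - s + 1L)
  }
  cds <- cds_sequence(gene)
  L <- nchar(cds)
  j <- if (gene$strand == "+") i0 else L - i0 + 1L
  codon_idx <- (j - 1L) %/% 3L + 1L
  within <- j - 3L * (codon_idx - 1L)
  ref_codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  var_base <- if (gene$strand == "+") site$alt else revcomp(site$alt)
  var_codon <- ref_codon
  substr(var_codon, within, within) <- var_base

  ref_aa <- translate_codon(ref_codon)
  var_aa <- translate_codon(var_codon)
  category <- if (var_aa == "*") {
    "coding_nonsense"
  } else if (ref_aa == var_aa) "coding_synonymous" else "coding_missense"
  data.frame(
    gene = gene$gene, category = category, ref_aa = ref_aa, var_aa = var_aa,
    aa_pos = codon_idx, stringsAsFactors = FALSE
  )
}

#' Run the annotation cascade on scan hits
#'
#' Stages, in order: associated variants -> within candidate gene regions
#' -> coding -> non-synonymous (missense + nonsense). Counts are per site;
#' a site overlapping two candidate genes is counted once but annotated
#' against each overlapping gene (the first containing gene is used for the
#' codon call of record).
#'
#' @param matches scan output from [scan_segregation()] (or any site table).
#' @param genes named list of [gene_model()] objects.
#' @param candidates `list(targets =, adme =)`.
#' @param flank passed to [filter_candidate_regions()].
#' @return an object of class `cascade_report`: stage counts, per-stage
#'   site tables, and an `annotation` table mirroring a coding-variant
#'   results table (gene, chrom, pos, ref, alt, ref_aa, var_aa, category).
#' @export
run_cascade <- function(matches, genes, candidates, flank = 0L) {
  site_cols <- intersect(c("chrom", "pos", "ref", "alt", "id", "subclasses"),
                         names(matches))
  sites <- matches[, site_cols, drop = FALSE]
  in_cand <- filter_candidate_regions(sites, genes, candidates, flank)

  ann <- NULL
  for (i in seq_len(nrow(in_cand))) {
    site <- in_cand[i, , drop = FALSE]
    for (sym in strsplit(site$genes, ",", fixed = TRUE)[[1]]) {
      gm <- genes[[sym]]
      if (site$pos < gm$span[1] || site$pos > gm$span[2]) next  # flank-only hit
      eff <- annotate_effect(site, gm)
      ann <- rbind(ann, cbind(site[, setdiff(names(site), "genes"), drop = FALSE],
                              eff, row.names = NULL))
    }
  }
  if (is.null(ann)) {
    ann <- data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), gene = character(0), category = character(0),
      ref_aa = character(0), var_aa = character(0), aa_pos = integer(0)
    )
  }

  keyify <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  coding_categories <- c("coding_synonymous", "coding_missense",
                         "coding_nonsense", "coding_frameshift",
                         "coding_inframe_indel")
  coding_ann <- ann[ann$category %in% coding_categories, , drop = FALSE]
  nonsyn_ann <- ann[ann$category %in% c("coding_missense", "coding_nonsense"),
                    , drop = FALSE]
  structure(list(
    n_associated = nrow(sites),
    n_in_candidate_genes = nrow(in_cand),
    n_coding = length(unique(keyify(coding_ann))),
    n_nonsynonymous = length(unique(keyify(nonsyn_ann))),
    associated = sites,
    in_candidate_genes = in_cand,
    coding = coding_ann,
    nonsynonymous = nonsyn_ann,
    annotation = ann
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("annotation cascade:\n")
  cat(sprintf("  associated variants      %6d\n", x$n_associated))
  cat(sprintf("  in candidate gene bodies %6d\n", x$n_in_candidate_genes))
  cat(sprintf("  coding                   %6d (%d gene(s))\n",
              x$n_coding, length(unique(x$coding$gene))))
  cat(sprintf("  non-synonymous           %6d (%d gene(s))\n",
              x$n_nonsynonymous, length(unique(x$nonsynonymous$gene))))
  invisible(x)
}
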