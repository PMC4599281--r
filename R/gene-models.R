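#' Construct a gene model
#'
#' A gene model is the minimal structure needed for feature classification
#' and codon-level effect calls: gene body span, strand, ordered CDS
#' intervals, optional exon intervals (for UTR calls), and the plus-strand
#' reference sequence covering the span. All coordinates are 1-based
#' inclusive; minus-strand genes keep their sequence in plus orientation and
#' the strand is applied only at translation time.
#'
#' @param gene gene symbol.
#' @param chrom chromosome name (normalized with [normalize_chrom()]).
#' @param strand `"+"` or `"-"`.
#' @param span length-2 integer vector, gene body `c(start, end)`.
#' @param cds data.frame with columns `start`, `end`: ordered, disjoint CDS
#'   intervals whose total length is divisible by 3.
#' @param exons optional data.frame with columns `start`, `end`; must cover
#'   every CDS interval. When absent, UTRs cannot be distinguished from
#'   introns.
#' @param seq plus-strand reference sequence (character) covering at least
#'   `[seq_offset, seq_offset + nchar(seq) - 1] >= span`.
#' @param seq_offset genomic position of the first base of `seq`.
#' @param check validate the translated CDS (starts with ATG, no internal
#'   stop codon). Synthetic fixtures satisfy this by construction.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, span, cds, exons = NULL,
                       seq = NULL, seq_offset = span[1], check = TRUE) {
  stopifnot(strand %in% c("+", "-"), length(span) == 2L, span[1] <= span[2])
  cds <- as.data.frame(cds)[, c("start", "end")]
  cds <- cds[order(cds$start), , drop = FALSE]
  row.names(cds) <- NULL
  if (any(cds$start > cds$end)) stop(gene, ": CDS interval with start > end")
  if (any(cds$start < span[1] | cds$end > span[2])) {
    stop(gene, ": CDS interval outside gene span")
  }
  if (nrow(cds) > 1L && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stop(gene, ": overlapping CDS intervals")
  }
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    stop(gene, ": CDS length ", cds_len, " not divisible by 3")
  }
  if (!is.null(exons)) {
    exons <- as.data.frame(exons)[, c("start", "end")]
    exons <- exons[order(exons$start), , drop = FALSE]
    row.names(exons) <- NULL
    covered <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
    }, logical(1))
    if (!all(covered)) stop(gene, ": CDS interval not covered by any exon")
  }
  if (!is.null(seq)) {
    seq <- toupper(as.character(seq))
    if (seq_offset > span[1] || seq_offset + nchar(seq) - 1L < span[2]) {
      stop(gene, ": sequence does not cover the gene span")
    }
  }
  gm <- structure(
    list(gene = gene, chrom = normalize_chrom(chrom), strand = strand,
         span = as.integer(span), cds = cds, exons = exons,
         seq = seq, seq_offset = as.integer(seq_offset)),
    class = "gene_model"
  )
  if (check && !is.null(seq)) {
    aa <- translate_cds(gm)
    if (substr(aa, 1, 1) != "M") stop(gene, ": CDS does not start with ATG")
    internal <- substr(aa, 1, nchar(aa) - 1L)
    if (grepl("*", internal, fixed = TRUE)) {
      stop(gene, ": CDS contains an internal stop codon")
    }
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "gene_model %s %s:%d-%d (%s), %d CDS interval(s), %d coding bp\n",
    x$gene, x$chrom, x$span[1], x$span[2], x$strand, nrow(x$cds),
    sum(x$cds$end - x$cds$start + 1L)
  ))
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Plus-strand genomic subsequence [start, end] of a gene model's sequence.
gene_seq_at <- function(gm, start, end) {
  if (is.null(gm$seq)) stop(gm$gene, ": gene model has no sequence")
  substr(gm$seq, start - gm$seq_offset + 1L, end - gm$seq_offset + 1L)
}

#' Coding sequence of a gene model
#'
#' Concatenates the CDS intervals in genomic order and, for minus-strand
#' genes, reverse-complements the result so the returned string always reads
#' 5' to 3' in the coding direction.
#'
#' @param gm a `gene_model` with sequence.
#' @return character string of coding nucleotides.
#' @export
cds_sequence <- function(gm) {
  parts <- vapply(seq_len(nrow(gm$cds)), function(i) {
    gene_seq_at(gm, gm$cds$start[i], gm$cds$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gm$strand == "-") revcomp(s) else s
}

#' Translate the coding sequence of a gene model
#'
#' @param gm a `gene_model` with sequence.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(gm) {
  s <- cds_sequence(gm)
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  paste(vapply(codons, translate_codon, character(1)), collapse = "")
}

#' Read gene models from BED12 or GFF3 plus a reference FASTA
#'
#' BED12 files (0-based half-open; converted to internal 1-based inclusive
#' coordinates) define exons through the block fields and the CDS through
#' `thickStart`/`thickEnd`. GFF3 files (already 1-based inclusive) must
#' contain `gene` features with an `ID` or `Name` attribute carrying the
#' symbol, and `CDS` (and optionally `exon`) features whose `Parent` points
#' at the gene (directly or through one intermediate transcript feature).
#'
#' The FASTA may contain whole chromosomes (`>chr3`) or region records in
#' `samtools faidx` style (`>chr3:121641493-121648368`); each gene span must
#' be fully covered by one record.
#'
#' @param path gene model file (`.bed` or `.gff`/`.gff3`).
#' @param fasta reference FASTA path.
#' @param check passed to [gene_model()].
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, fasta, check = TRUE) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "bed") {
    parse_bed12(path)
  } else if (ext %in% c("gff", "gff3")) {
    parse_gff3(path)
  } else {
    stop("unsupported gene model format: .", ext, " (need BED12 or GFF3)")
  }
  fa <- Biostrings::readDNAStringSet(fasta)
  names(fa) <- sub("\\s.*$", "", names(fa))
  out <- lapply(raw, function(r) {
    hit <- fasta_region(names(fa), r$chrom, r$span[1], r$span[2])
    if (is.na(hit$idx)) {
      stop("FASTA lacks sequence covering ", r$gene, " at ",
           r$chrom, ":", r$span[1], "-", r$span[2])
    }
    seq <- as.character(fa[[hit$idx]])
    gene_model(r$gene, r$chrom, r$strand, r$span, r$cds, exons = r$exons,
               seq = seq, seq_offset = hit$offset, check = check)
  })
  names(out) <- vapply(out, `[[`, character(1), "gene")
  out
}

## Match "chr3" or "chr3:start-end" FASTA records against a needed interval.
fasta_region <- function(rec_names, chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  m <- regmatches(rec_names, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", rec_names))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 0L) next
    rchrom <- normalize_chrom(m[[i]][2])
    if (rchrom != chrom) next
    if (m[[i]][3] == "") return(list(idx = i, offset = 1L))
    rs <- as.integer(m[[i]][3]); re <- as.integer(m[[i]][4])
    if (rs <= start && re >= end) return(list(idx = i, offset = rs))
  }
  list(idx = NA_integer_, offset = NA_integer_)
}

parse_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks)) stop("BED file is not BED12 (no block fields): ", path)
  lapply(seq_along(gr), function(i) {
    x <- gr[i]
    exon_rel <- gr$blocks[[i]]
    exons <- data.frame(
      start = GenomicRanges::start(x) + IRanges::start(exon_rel) - 1L,
      end = GenomicRanges::start(x) + IRanges::end(exon_rel) - 1L
    )
    thick <- gr$thick[i]
    cds <- data.frame(
      start = pmax(exons$start, IRanges::start(thick)),
      end = pmin(exons$end, IRanges::end(thick))
    )
    cds <- cds[cds$start <= cds$end, , drop = FALSE]
    if (nrow(cds) == 0L) stop(gr$name[i], ": BED12 record has no CDS bases")
    list(
      gene = gr$name[i],
      chrom = as.character(GenomicRanges::seqnames(x)),
      strand = as.character(GenomicRanges::strand(x)),
      span = c(GenomicRanges::start(x), GenomicRanges::end(x)),
      cds = cds, exons = exons
    )
  })
}

parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("GFF3 contains no gene features: ", path)
  ids <- as.character(genes$ID)
  symbols <- if (!is.null(genes$Name)) {
    ifelse(is.na(genes$Name), ids, as.character(genes$Name))
  } else ids

  ## Parent of a feature, following at most one transcript-level hop.
  parent_gene <- function(p) {
    if (p %in% ids) return(p)
    hit <- which(as.character(gr$ID) == p)
    if (length(hit) == 1L) {
      pp <- unlist(gr$Parent[hit])
      if (length(pp) == 1L && pp %in% ids) return(pp)
    }
    NA_character_
  }

  feature_table <- function(which_type) {
    f <- gr[type == which_type]
    if (length(f) == 0L) return(NULL)
    parents <- vapply(seq_along(f), function(i) {
      p <- unlist(f$Parent[i])
      if (length(p) == 0L) return(NA_character_)
      parent_gene(p[1])
    }, character(1))
    data.frame(
      gene = parents,
      start = GenomicRanges::start(f),
      end = GenomicRanges::end(f),
      stringsAsFactors = FALSE
    )
  }
  cds_tab <- feature_table("CDS")
  exon_tab <- feature_table("exon")
  if (is.null(cds_tab)) stop("GFF3 contains no CDS features: ", path)

  lapply(seq_along(genes), function(i) {
    gid <- ids[i]
    cds <- cds_tab[!is.na(cds_tab$gene) & cds_tab$gene == gid, c("start", "end")]
    if (nrow(cds) == 0L) stop(symbols[i], ": no CDS features in GFF3")
    exons <- if (!is.null(exon_tab)) {
      ex <- exon_tab[!is.na(exon_tab$gene) & exon_tab$gene == gid, c("start", "end")]
      if (nrow(ex)) ex else NULL
    } else NULL
    list(
      gene = symbols[i],
      chrom = as.character(GenomicRanges::seqnames(genes[i])),
      strand = as.character(GenomicRanges::strand(genes[i])),
      span = c(GenomicRanges::start(genes[i]), GenomicRanges::end(genes[i])),
      cds = cds, exons = exons
    )
  })
}

#' Write gene models as GFF3
#'
#' Inverse of the GFF3 path of [read_gene_models()]: one `gene` feature per
#' model with `exon` and `CDS` children.
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    gid <- paste0("gene:", gm$gene)
    lines <- c(lines, paste(
      gm$chrom, "pharmseg", "gene", gm$span[1], gm$span[2], ".",
      gm$strand, ".", paste0("ID=", gid, ";Name=", gm$gene), sep = "\t"
    ))
    exons <- if (is.null(gm$exons)) gm$cds else gm$exons
    for (i in seq_len(nrow(exons))) {
      lines <- c(lines, paste(
        gm$chrom, "pharmseg", "exon", exons$start[i], exons$end[i], ".",
        gm$strand, ".", paste0("Parent=", gid), sep = "\t"
      ))
    }
    for (i in seq_len(nrow(gm$cds))) {
      lines <- c(lines, paste(
        gm$chrom, "pharmseg", "CDS", gm$cds$start[i], gm$cds$end[i], ".",
        gm$strand, "0", paste0("Parent=", gid), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write gene-model sequences as a region FASTA
#'
#' One record per gene model, named `chrom:start-end` over the stored
#' sequence window (`samtools faidx` region style).
#'
#' @param models list of `gene_model` objects with sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(models, path) {
  seqs <- vapply(models, function(gm) {
    if (is.null(gm$seq)) stop(gm$gene, ": no sequence to write")
    gm$seq
  }, character(1))
  names(seqs) <- vapply(models, function(gm) {
    sprintf("%s:%d-%d", gm$chrom, gm$seq_offset,
            gm$seq_offset + nchar(gm$seq) - 1L)
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
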