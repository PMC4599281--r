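#' Classify samples into good and poor responders
#'
#' An explicit `label` column wins; otherwise a sample is a good responder
#' iff its time-to-progression exceeds `ttp_threshold` months. The default
#' threshold of 5 months separates durable responders from patients
#' progressing within a few months of treatment start.
#'
#' @param sheet sample sheet from [read_sample_sheet()] (columns `sample`,
#'   `ttp_months`, `label`).
#' @param ttp_threshold months; must be > 0.
#' @return named character vector, sample ID -> `"good"`/`"poor"`.
#' @export
classify_responders <- function(sheet, ttp_threshold = 5) {
  stopifnot(ttp_threshold > 0)
  n <- nrow(sheet)
  lab <- if ("label" %in% names(sheet)) sheet$label else rep(NA_character_, n)
  ttp <- if ("ttp_months" %in% names(sheet)) sheet$ttp_months else rep(NA_real_, n)
  from_ttp <- ifelse(ttp > ttp_threshold, "good", "poor")
  lab <- ifelse(is.na(lab), from_ttp, lab)
  if (anyNA(lab)) {
    stop("sample(s) with neither label nor ttp_months: ",
         paste(sheet$sample[is.na(lab)], collapse = ", "))
  }
  labels <- setNames(lab, sheet$sample)
  if (!all(c("good", "poor") %in% labels)) {
    stop("both responder classes must be non-empty (got ",
         sum(labels == "good"), " good, ", sum(labels == "poor"), " poor)")
  }
  labels
}

#' Segregation subclasses of one genotype vector
#'
#' Genotypes are counts of the non-reference ("A") allele. A variant
#' perfectly segregates under:
#'
#' * subclass 1 (A-dominant): every good responder carries A (`g >= 1`),
#'   every poor responder carries none (`g = 0`);
#' * subclass 2 (A-recessive): every good responder is A-homozygous
#'   (`g = 2`), no poor responder is (`g <= 1`);
#' * subclass 3 (B-recessive): every good responder is reference-homozygous
#'   (`g = 0`), every poor responder carries A (`g >= 1`);
#' * subclass 4 (B-dominant): no good responder is A-homozygous (`g <= 1`),
#'   every poor responder is (`g = 2`).
#'
#' Flipping every genotype `g -> 2 - g` (swapping the roles of the A and B
#' alleles) maps subclass 1 to 4 and 2 to 3.
#'
#' All satisfied subclasses are reported. Under the default missing policy a
#' vector with any missing genotype matches nothing; under
#' `"tolerate"`, missing samples are dropped and the rules are applied to
#' the remainder, provided both classes retain at least one observed sample.
#'
#' @param g integer vector of genotypes in \{0,1,2,NA\}, named by sample or
#'   aligned with `labels`.
#' @param labels named vector from [classify_responders()].
#' @param missing_policy `"exclude"` (default) or `"tolerate"`.
#' @return `list(subclasses = integer vector, complete = logical)`.
#' @export
match_subclasses <- function(g, labels, missing_policy = c("exclude", "tolerate")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.null(names(g))) {
    if (!setequal(names(g), names(labels))) {
      stop("genotype vector and labels cover different samples")
    }
    g <- g[names(labels)]
  } else if (length(g) != length(labels)) {
    stop("genotype vector and labels have different lengths")
  }
  complete <- !anyNA(g)
  if (!complete && missing_policy == "exclude") {
    return(list(subclasses = integer(0), complete = FALSE))
  }
  keep <- !is.na(g)
  good <- g[keep & labels == "good"]
  poor <- g[keep & labels == "poor"]
  if (length(good) == 0L || length(poor) == 0L) {
    return(list(subclasses = integer(0), complete = complete))
  }
  sub <- c(
    if (all(good >= 1L) && all(poor == 0L)) 1L,
    if (all(good == 2L) && all(poor <= 1L)) 2L,
    if (all(good == 0L) && all(poor >= 1L)) 3L,
    if (all(good <= 1L) && all(poor == 2L)) 4L
  )
  list(subclasses = as.integer(sub), complete = complete)
}

#' Scan a genotype matrix for perfectly segregating variants
#'
#' Applies [match_subclasses()] to every site and keeps those matching at
#' least one subclass, in genome (chrom, pos) order. The result is
#' invariant to the row and column order of the input matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param labels named vector from [classify_responders()]; must cover
#'   exactly the matrix samples.
#' @param missing_policy passed to [match_subclasses()].
#' @return data.frame with columns chrom, pos, ref, alt, id, subclasses
#'   (comma-joined), complete.
#' @export
scan_segregation <- function(gm, labels, missing_policy = c("exclude", "tolerate")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!setequal(gm$samples, names(labels))) {
    stop("genotype matrix samples and responder labels differ")
  }
  labels <- labels[gm$samples]
  hits <- lapply(seq_len(nrow(gm$g)), function(i) {
    m <- match_subclasses(gm$g[i, ], labels, missing_policy)
    if (length(m$subclasses) == 0L) return(NULL)
    cbind(
      gm$sites[i, , drop = FALSE],
      data.frame(subclasses = paste(m$subclasses, collapse = ","),
                 complete = m$complete, stringsAsFactors = FALSE)
    )
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- cbind(gm$sites[0, , drop = FALSE],
                  data.frame(subclasses = character(0), complete = logical(0)))
  }
  hits <- hits[order_sites(hits), , drop = FALSE]
  row.names(hits) <- NULL
  hits
}

#' Expected number of genotype vectors matching each subclass by chance
#'
#' Closed-form count, over all `3^(n_good + n_poor)` complete genotype
#' vectors, of how many satisfy each segregation subclass and their union
#' (by inclusion-exclusion; only the subclass pairs \{1,2\} and \{3,4\}
#' intersect, in one vector each). This quantifies the false-positive
#' burden of the perfect-match filter: under a uniform null, a fraction
#' union/3^n of variants matches some subclass by chance.
#'
#' @param n_good,n_poor class sizes (both >= 1).
#' @return `list(per_subclass = c(s1, s2, s3, s4), union =, total =)`.
#' @export
#' @examples
#' null_match_count(4, 3)  # 16, 8, 8, 16; union 46 of 2187
null_match_count <- function(n_good, n_poor) {
  if (n_good < 1L || n_poor < 1L) stop("n_good and n_poor must be >= 1")
  per <- c(2^n_good, 2^n_poor, 2^n_poor, 2^n_good)
  union <- sum(per) - 2  # minus |S1 n S2| = |S3 n S4| = 1
  list(per_subclass = per, union = union, total = 3^(n_good + n_poor))
}
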