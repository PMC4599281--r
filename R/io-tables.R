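#' Read a responder sample sheet
#'
#' Tab-separated file with a header; required column `sample`, plus
#' `ttp_months` (time to progression, months) and/or `label`
#' (`good`/`poor`, case-insensitive). Every sample must carry at least one
#' of the two. Additional clinical columns (age, tumour size, stage, ...)
#' are kept as-is so they can feed [summarize_cohort()].
#'
#' @param path path to a TSV file.
#' @return a `data.frame`, one row per sample, in file order.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(df)) stop("sample sheet needs a 'sample' column")
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ID(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  has_ttp <- "ttp_months" %in% names(df)
  has_label <- "label" %in% names(df)
  if (!has_ttp && !has_label) {
    stop("sample sheet needs a 'ttp_months' and/or 'label' column")
  }
  if (has_ttp) {
    df$ttp_months <- as.numeric(df$ttp_months)
    if (any(!is.na(df$ttp_months) & df$ttp_months <= 0)) {
      stop("ttp_months must be > 0")
    }
  } else df$ttp_months <- rep(NA_real_, nrow(df))
  if (has_label) {
    df$label <- tolower(as.character(df$label))
    df$label[df$label %in% c("", "na")] <- NA_character_
    bad <- !is.na(df$label) & !df$label %in% c("good", "poor")
    if (any(bad)) stop("labels must be 'good' or 'poor': ", df$label[bad][1])
  } else df$label <- rep(NA_character_, nrow(df))
  orphan <- is.na(df$ttp_months) & is.na(df$label)
  if (any(orphan)) {
    stop("sample(s) with neither ttp_months nor label: ",
         paste(df$sample[orphan], collapse = ", "))
  }
  df
}

#' Read candidate gene lists
#'
#' Plain-text lists, one gene symbol per line (blank lines and `#` comments
#' ignored): drug-target candidates and ADME (absorption, distribution,
#' metabolism, excretion) candidates. The two sets may overlap.
#'
#' @param targets_path,adme_path paths to the two symbol lists.
#' @return `list(targets =, adme =)` of character vectors.
#' @export
read_candidate_genes <- function(targets_path, adme_path) {
  read_one <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    unique(x[nzchar(x) & !startsWith(x, "#")])
  }
  out <- list(targets = read_one(targets_path), adme = read_one(adme_path))
  if (length(out$targets) == 0L && length(out$adme) == 0L) {
    stop("both candidate gene lists are empty")
  }
  out
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time_months`, `event` (1 = progression/death
#' observed, 0 = censored), `genotype` (e.g. `"C/T"`), and optionally
#' `stage` (ordinal covariate) plus further genotype columns.
#'
#' @param path path to a TSV file.
#' @return a validated `data.frame`.
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  df$time_months <- as.numeric(df$time_months)
  df$event <- as.integer(df$event)
  if (any(is.na(df$time_months) | df$time_months <= 0)) stop("time_months must be > 0")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  df
}

#' Summarize a numeric cohort characteristic
#'
#' Median and interquartile range of one numeric column of a sample sheet
#' (or any data frame), as reported in clinical baseline tables. Quartiles
#' use linear interpolation; the median is the standard mean-of-central-pair
#' definition for even n.
#'
#' @param rows a `data.frame`.
#' @param field name of the numeric column.
#' @return `list(n, median, iqr)` where `iqr` is `c(q25, q75)`.
#' @export
#' @examples
#' summarize_cohort(data.frame(age = c(54, 45, 47, 60, 61, 66, 68)), "age")
summarize_cohort <- function(rows, field) {
  if (!field %in% names(rows)) stop("no column '", field, "'")
  x <- suppressWarnings(as.numeric(rows[[field]]))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("column '", field, "' has no numeric values")
  list(
    n = length(x),
    median = median(x),
    iqr = unname(quantile(x, c(0.25, 0.75)))
  )
}

## Shared plain-TSV writer for all result tables.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
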