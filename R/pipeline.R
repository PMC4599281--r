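#' Build or validate a pipeline run configuration
#'
#' A run configuration is a plain named list (readable from a YAML file)
#' with input paths and analysis settings. Recognised keys:
#' `vcf`, `samples`, `gene_models`, `fasta`, `targets`, `adme` (input
#' paths), `survival`, `genotypes` (optional validation-stage inputs),
#' `out_dir`, `ttp_threshold` (default 5), `flank` (default 0),
#' `missing_policy` (`exclude`/`tolerate`), `ties` (`efron`/`breslow`),
#' `strata_mode` (`dominant`/`recessive`/`additive`), `seed`.
#'
#' @param config named list or path to a YAML file.
#' @param overrides named list taking precedence over the file values.
#' @return validated config list.
#' @export
run_config <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides
  defaults <- list(ttp_threshold = 5, flank = 0L, missing_policy = "exclude",
                   ties = "efron", strata_mode = "dominant", seed = 1L,
                   out_dir = "pharmseg-results")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  required <- c("vcf", "samples", "gene_models", "fasta", "targets", "adme")
  miss <- required[!vapply(required, function(k) !is.null(config[[k]]), logical(1))]
  if (length(miss)) {
    stop("config error: missing required key(s): ", paste(miss, collapse = ", "))
  }
  for (k in c(required, intersect(c("survival", "genotypes"), names(config)))) {
    p <- config[[k]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config error: input file for '", k, "' does not exist: ", p)
    }
  }
  if (!is.numeric(config$seed) || config$seed != as.integer(config$seed)) {
    stop("config error: seed must be an integer")
  }
  config
}

#' Run the discovery-to-validation pipeline
#'
#' Chains the full analysis: read inputs, classify responders, scan for
#' perfectly segregating variants, run the annotation cascade, and (when a
#' survival table is supplied) genotype-stratified Kaplan-Meier curves,
#' log-rank test, stage-adjusted Cox fit and pairwise LD among candidate
#' SNPs. All result tables are written as TSV into `out_dir` together with
#' a machine-readable JSON manifest (inputs, settings, seed, stage counts).
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly, with `$paths` pointing at outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- run_config(config)
  say <- function(...) if (!quiet) message("[pharmseg] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  say("reading genotypes from ", config$vcf)
  gm <- read_vcf(config$vcf)
  sheet <- read_sample_sheet(config$samples)
  models <- read_gene_models(config$gene_models, config$fasta)
  candidates <- read_candidate_genes(config$targets, config$adme)

  labels <- classify_responders(sheet, config$ttp_threshold)
  say(sum(labels == "good"), " good / ", sum(labels == "poor"),
      " poor responders")
  hits <- scan_segregation(gm, labels, config$missing_policy)
  say(nrow(hits), " perfectly segregating variant(s)")
  cascade <- run_cascade(hits, models, candidates, config$flank)

  paths <- list(
    scan = file.path(config$out_dir, "scan.tsv"),
    cascade = file.path(config$out_dir, "cascade.tsv"),
    annotation = file.path(config$out_dir, "annotation.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_tsv(hits, paths$scan)
  write_tsv(data.frame(
    stage = c("associated", "in_candidate_genes", "coding", "nonsynonymous"),
    n = c(cascade$n_associated, cascade$n_in_candidate_genes,
          cascade$n_coding, cascade$n_nonsynonymous)
  ), paths$cascade)
  ann <- cascade$annotation
  write_tsv(ann[order_sites(ann), , drop = FALSE], paths$annotation)

  validation <- NULL
  if (!is.null(config$survival)) {
    say("survival validation from ", config$survival)
    surv <- read_survival_table(config$survival)
    strata <- genotype_strata(surv$genotype, config$strata_mode)
    dat <- data.frame(time = surv$time_months, event = surv$event,
                      refhom = as.integer(strata == levels(strata)[1]))
    covars <- "refhom"
    if ("stage" %in% names(surv)) {
      dat$stage <- as.numeric(surv$stage)
      covars <- c(covars, "stage")
    }
    cox <- cox_fit(dat, covars, ties = config$ties)
    lr <- logrank_test(surv$time_months, surv$event, strata)
    km <- lapply(split(seq_len(nrow(surv)), strata), function(ix) {
      km_estimate(surv$time_months[ix], surv$event[ix])
    })
    km_tab <- do.call(rbind, lapply(names(km), function(gname) {
      k <- km[[gname]]
      data.frame(group = gname, time = k$time, n_risk = k$n_risk,
                 surv = k$surv, var = k$var)
    }))
    paths$cox <- file.path(config$out_dir, "cox.tsv")
    paths$km <- file.path(config$out_dir, "km.tsv")
    write_tsv(cox$table, paths$cox)
    write_tsv(km_tab, paths$km)
    validation <- list(
      cox = cox$table, cox_converged = cox$converged,
      logrank = lr,
      km_medians = lapply(km, `[[`, "median")
    )
    if (!is.null(config$genotypes)) {
      gtab <- read.delim(config$genotypes, stringsAsFactors = FALSE)
      snp_cols <- setdiff(names(gtab), "sample")
      ## allele-count coding; r2/D' are invariant to which allele is "A"
      counts <- vapply(snp_cols, function(cn) {
        parts <- strsplit(gtab[[cn]], "[/|]")
        a0 <- sort(unique(unlist(parts)))[1]
        vapply(parts, function(a) sum(a != a0), integer(1))
      }, integer(nrow(gtab)))
      if (length(snp_cols) >= 2L) {
        ldm <- ld_matrix(counts)
        paths$ld <- file.path(config$out_dir, "ld.tsv")
        write_tsv(cbind(snp = rownames(ldm), as.data.frame(ldm)), paths$ld)
        validation$ld_r2 <- ldm
      }
    }
  }

  manifest <- list(
    package = "pharmseg",
    version = as.character(packageVersion("pharmseg")),
    seed = config$seed,
    inputs = config[c("vcf", "samples", "gene_models", "fasta", "targets",
                      "adme", "survival", "genotypes")],
    settings = config[c("ttp_threshold", "flank", "missing_policy", "ties",
                        "strata_mode")],
    n_samples = length(gm$samples),
    n_sites = nrow(gm$sites),
    n_good = sum(labels == "good"),
    n_poor = sum(labels == "poor"),
    stage_counts = list(
      associated = cascade$n_associated,
      in_candidate_genes = cascade$n_in_candidate_genes,
      coding = cascade$n_coding,
      nonsynonymous = cascade$n_nonsynonymous
    ),
    validation = if (!is.null(validation)) list(
      cox_converged = validation$cox_converged,
      logrank_p = validation$logrank$p,
      hr = validation$cox$hr[validation$cox$term == "refhom"]
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest$paths <- paths
  manifest$cascade <- cascade
  manifest$validation <- validation
  say("results in ", config$out_dir)
  invisible(manifest)
}
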