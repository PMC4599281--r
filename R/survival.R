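#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the curve at event
#' times with Greenwood variances and the median survival time (smallest
#' time with S(t) <= 0.5, `NA` when the curve never reaches 0.5).
#'
#' @param time positive follow-up times (months).
#' @param event 1 = event observed, 0 = censored.
#' @return `list(time, n_risk, n_event, surv, var, median)` of class
#'   `km_curve`; only event times are tabulated.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain")
  sm <- summary(fit, censored = FALSE)
  keep <- sm$n.event > 0
  surv <- sm$surv[keep]
  tt <- sm$time[keep]
  med <- if (any(surv <= 0.5)) min(tt[surv <= 0.5]) else NA_real_
  structure(list(
    time = tt, n_risk = sm$n.risk[keep], n_event = sm$n.event[keep],
    surv = surv, var = (sm$std.err[keep])^2, median = med
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event time(s), median %s\n",
              length(x$time),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected over pooled risk sets with hypergeometric
#' variance ([survival::survdiff()] with `rho = 0`), chi-square reference
#' with k - 1 degrees of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 non-empty groups).
#' @return `list(chisq, df, p)`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("log-rank test needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with the Efron tie
#' correction by default (Breslow available for cross-checks). Hazard
#' ratios are exponentiated coefficients with Wald 95% confidence
#' intervals on the log-hazard scale. Constant covariates are dropped with
#' a warning (coefficient reported as 0); monotone-likelihood/perfect
#' separation is flagged through `converged = FALSE` with CIs suppressed.
#'
#' @param data data.frame with columns `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `list(table = data.frame(term, beta, se, hr, lower95, upper95,
#'   p), converged, n_iterations, n, n_events)` of class `cox_result`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) < 1) stop("Cox fit needs at least one event")

  constant <- vapply(covariates, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) < 2L
  }, logical(1))
  dropped <- covariates[constant]
  kept <- covariates[!constant]
  if (length(dropped)) {
    warning("constant covariate(s) dropped from Cox fit: ",
            paste(dropped, collapse = ", "))
  }
  if (length(kept) == 0L) {
    tab <- data.frame(term = covariates, beta = 0, se = NA_real_, hr = 1,
                      lower95 = NA_real_, upper95 = NA_real_, p = NA_real_)
    return(structure(list(table = tab, converged = FALSE, n_iterations = 0L,
                          n = nrow(data), n_events = sum(data$event)),
                     class = "cox_result"))
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(kept, collapse = " + ")
  ))
  separated <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- !separated && all(is.finite(beta)) && all(abs(beta) < 15)
  z <- qnorm(0.975)
  tab <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lower95 = if (converged) exp(unname(beta) - z * se) else NA_real_,
    upper95 = if (converged) exp(unname(beta) + z * se) else NA_real_,
    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  if (length(dropped)) {
    tab <- rbind(tab, data.frame(
      term = dropped, beta = 0, se = NA_real_, hr = 1,
      lower95 = NA_real_, upper95 = NA_real_, p = NA_real_
    ))
  }
  row.names(tab) <- NULL
  structure(list(
    table = tab, converged = converged, n_iterations = fit$iter,
    n = fit$n, n_events = fit$nevent
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (%d subjects, %d events, %s)\n", x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged"))
  print(x$table, digits = 4)
  invisible(x)
}

#' Collapse diploid genotype calls into analysis strata
#'
#' Default `dominant` mode reproduces the usual carrier split: reference
#' homozygotes (e.g. `C/C`) vs carriers of the alternate allele (`C/T` or
#' `T/T`). `recessive` contrasts alternate homozygotes against everyone
#' else; `additive` keeps the three genotype classes.
#'
#' @param genotype either allele-count integers (0/1/2 copies of the
#'   alternate allele) or strings like `"C/T"` (any allele order, `/` or
#'   `|` separator).
#' @param mode `"dominant"`, `"recessive"` or `"additive"`.
#' @param ref,alt allele letters; required to parse string genotypes and
#'   used to build readable stratum labels.
#' @return factor of stratum labels aligned with `genotype`.
#' @export
#' @examples
#' genotype_strata(c("C/C", "C/T", "T/T"), ref = "C", alt = "T")
genotype_strata <- function(genotype, mode = c("dominant", "recessive", "additive"),
                            ref = "C", alt = "T") {
  mode <- match.arg(mode)
  if (is.character(genotype) || is.factor(genotype)) {
    counts <- vapply(as.character(genotype), function(s) {
      if (is.na(s)) return(NA_integer_)
      a <- strsplit(s, "[/|]")[[1]]
      if (length(a) != 2L || !all(a %in% c(ref, alt))) {
        stop("cannot parse genotype '", s, "' with alleles ", ref, "/", alt)
      }
      sum(a == alt)
    }, integer(1))
  } else {
    counts <- as.integer(genotype)
    if (!all(counts %in% c(0L, 1L, 2L) | is.na(counts))) {
      stop("allele counts must be 0, 1 or 2")
    }
  }
  hom_ref <- paste0(ref, "/", ref)
  het <- paste0(ref, "/", alt)
  hom_alt <- paste0(alt, "/", alt)
  lab <- switch(mode,
    dominant = ifelse(counts == 0L, hom_ref, paste(het, "or", hom_alt)),
    recessive = ifelse(counts == 2L, hom_alt, paste(hom_ref, "or", het)),
    additive = c(hom_ref, het, hom_alt)[counts + 1L]
  )
  levels <- switch(mode,
    dominant = c(hom_ref, paste(het, "or", hom_alt)),
    recessive = c(paste(hom_ref, "or", het), hom_alt),
    additive = c(hom_ref, het, hom_alt)
  )
  observed <- levels[levels %in% lab]
  if (length(observed) < 2L) {
    warning("SNP is monomorphic under mode '", mode,
            "': a single stratum (downstream group tests will fail)")
  }
  factor(lab, levels = levels)
}

#' Genotype concordance between two call sets
#'
#' Per-sample fraction of shared sites where the two matrices report the
#' same genotype class, the standard QC comparing sequencing-derived calls
#' against an orthogonal platform (genotyping array). Pairs with a missing
#' call on either side are excluded from the denominator.
#'
#' @param gm1,gm2 two [genotype_matrix()] objects; compared over the
#'   intersection of their sites and samples.
#' @return `list(per_sample = named rates (percent), overall = percent,
#'   n_sites = number of shared sites)`.
#' @export
concordance <- function(gm1, gm2) {
  samples <- intersect(gm1$samples, gm2$samples)
  sites <- intersect(rownames(gm1$g), rownames(gm2$g))
  if (length(samples) == 0L || length(sites) == 0L) {
    stop("no shared (site, sample) pairs to compare")
  }
  a <- gm1$g[sites, samples, drop = FALSE]
  b <- gm2$g[sites, samples, drop = FALSE]
  comparable <- !is.na(a) & !is.na(b)
  if (!any(comparable)) stop("all shared pairs have a missing call")
  agree <- comparable & (a == b)
  per_sample <- 100 * colSums(agree) / colSums(comparable)
  per_sample[colSums(comparable) == 0] <- NA_real_
  list(
    per_sample = per_sample,
    overall = 100 * sum(agree) / sum(comparable),
    n_sites = length(sites)
  )
}
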