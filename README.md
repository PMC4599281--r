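# pharmseg

Extreme-responder segregation scanning and pharmacogenomic survival
validation for small germline cohorts.

## What problem this solves

Some patients respond extraordinarily well to a drug; others fail within
months. When the contrast is that stark, even a seven-patient cohort can
expose germline variants associated with response — not by association
testing, but by demanding a *perfect* genotype–phenotype match. pharmseg
implements that workflow end to end for people analysing
extreme-phenotype sequencing studies (the motivating setting is sorafenib
response in hepatocellular carcinoma):

1. **Segregation scan.** Each diploid genotype is coded as the count
   *g* ∈ {0,1,2} of non-reference ("A") alleles. A variant is reported when
   its genotype vector satisfies one of four dominant/recessive
   subclasses: A-dominant (all good responders *g* ≥ 1, all poor *g* = 0),
   A-recessive (good *g* = 2, poor *g* ≤ 1), B-recessive (good *g* = 0, poor
   *g* ≥ 1), B-dominant (good *g* ≤ 1, poor *g* = 2). `null_match_count()`
   gives the closed-form chance-match burden of the filter:
   2^(n_g+1) + 2^(n_p+1) − 2 of the 3^(n_g+n_p) complete vectors — 46 of
   2187 for a 4-good/3-poor design.
2. **Annotation cascade.** Associated variants are restricted to
   candidate (drug-target / ADME) gene bodies, classified as
   intronic/UTR/coding, and coding SNVs get codon-level calls
   (synonymous, missense, nonsense; strand-aware codon lookup in the CDS
   frame).
3. **Survival validation.** In an independent cohort: pairwise linkage
   disequilibrium among candidate SNPs (EM haplotype frequencies → D, D′,
   r²), genotype-stratified Kaplan–Meier curves, log-rank test, and a
   stage-adjusted Cox proportional-hazards model with Wald CIs — the
   hazard ratio of reference homozygotes vs carriers is the headline
   number.
4. **Synthetic cohorts.** Deterministic generators emit every input
   format the pipeline reads (VCF, sample-sheet TSV, GFF3 + region FASTA,
   candidate lists, survival TSV) with planted ground truth, including
   gene models whose codon context reproduces the published coding-variant
   table exactly.

## Worked example

```r
library(pharmseg)

## discovery: simulate the 4+3 cohort with the published coding variants embedded
d      <- make_discovery_cohort(discovery_design(seed = 7, embed_table3 = TRUE))
labels <- classify_responders(d$sheet)          # 4 good / 3 poor by the 5-month TTP rule
hits   <- scan_segregation(d$genotypes, labels) # 19 perfectly segregating variants
run_cascade(hits, d$models, d$candidates)
#> annotation cascade:
#>   associated variants          19
#>   in candidate gene bodies     19
#>   coding                       15 (9 gene(s))
#>   non-synonymous                6 (4 gene(s))
```

The 19 associated variants are the 4 planted intronic variants plus the 15
embedded coding variants; the cascade narrows them to 15 coding calls in 9
genes and 6 non-synonymous calls in 4 genes (ABCB1 S→A, FMO3 E→K, MUSK
M→I, and SLC15A2 L→F, P→S, R→K) — five of the coding variants sit in
SLC15A2.

```r
## validation: 174-patient cohort, true hazard ratio 2.18 for C/C vs carriers
v      <- make_validation_cohort(validation_design(seed = 42))
s      <- v$survival
strata <- genotype_strata(s$genotype, "dominant")  # C/C vs C/T-or-T/T
cox_fit(data.frame(time = s$time_months, event = s$event,
                   refhom = as.integer(strata == "C/C"), stage = s$stage),
        c("refhom", "stage"))
#> Cox PH fit (174 subjects, 126 events, converged)
#>     term   beta     se    hr lower95 upper95        p
#> 1 refhom 1.0857 0.3581 2.962  1.4679   5.975 0.002431
#> 2  stage 0.1346 0.2132 1.144  0.7533   1.738 0.527799
```

At n = 174 a single cohort estimates the hazard ratio noisily (here 2.96
against a generating value of 2.18, with a wide CI — exactly the
uncertainty a 174-patient validation carries); averaged over replicate
cohorts the fitter is unbiased, which is what the acceptance script
measures. The three candidate SNPs are generated as a fully linked block,
and `ld_matrix(v$allele_counts)` returns pairwise r² = 1.

A YAML-driven `run_pipeline()` chains all stages and writes TSV results
plus a JSON manifest; `inst/cli/pharmseg.R` wraps it for shell use
(`simulate`, `scan`, `annotate`, `validate`, `run-all`).

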