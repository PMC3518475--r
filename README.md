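# oligomiR

MicroRNA qPCR profiling of oligo- and polymetastatic progression after lung
metastasectomy.

## The problem

A subset of patients who present with a limited number of metastases
("oligometastases", ≤5 lesions) can be cured by surgical resection or
radiotherapy, while others progress rapidly and widely ("polymetastases").
`oligomiR` implements an analysis pipeline that links microRNA expression in
resected lung metastases to the **rate of metastatic progression** after
surgery, for researchers profiling archival (FFPE) tumor tissue on
TaqMan-array-style qPCR cards.

The pipeline:

1. **Clinical stratification.** Each patient's rate of progression is
   `r = (# recurrent metastases) / (years from surgery to last follow-up or
   death)`. Patients are classed LRP (`r < 0.6`/yr, including no recurrence),
   HRP (`r > 3.6`/yr) or IRP (the closed band between). Independently,
   progression is polymetastatic (PM) when, within 18 months of first
   recurrence, more than 5 new metastases appear inside any 4-month window or
   disease spreads within a body cavity; otherwise oligometastatic (OM).
2. **Ct preprocessing.** Wells are flagged (`Unreliable` below Ct 10,
   `Undetermined` above Ct 37 or missing), samples with too few detectable
   microRNAs (Ct < 38) are excluded, and the matrix is normalized by
   delta-Ct against the pooled mean of the endogenous controls RNU-44 and
   RNU-48 (discovery dialect) or by quantile normalization (validation
   dialect). Control coefficient of variation must stay ≤ 5%.
3. **Differential prioritization.** For each microRNA, the delta-delta-Ct
   between groups, `ddCt = mean dCt(HRP) − mean dCt(LRP)`, gives a signed
   fold change `±2^|ddCt|` (negative = down-regulated in HRP), with an
   unadjusted two-tailed Student t-test p-value; microRNAs with `p ≤ 0.05`
   are prioritized.
4. **Family / strand-pair enrichment** (the package's core statistic). It
   counts microRNA families (≥3 assayed members, miRBase `miFam.dat`
   annotation) with at least 3 members significantly co-deregulated in the
   same direction at ≥2-fold and odds ratio > 3, plus -3p/-5p strand pairs
   with both mature strands congruently deregulated. Significance of the
   total count comes from label-shuffling permutations (draw 48 of all 63
   samples, relabel 16/32, recompute the whole differential table; empirical
   `p = (1 + #{null ≥ observed}) / (1 + N)`).
5. **Cluster enrichment.** Unsupervised average-linkage clustering of
   samples on the 1 − Pearson correlation distance; the two main dendrogram
   branches are tested for phenotype enrichment by a two-sided Fisher exact
   test with the uncorrected cross-product odds ratio, and branch recall is
   given an F-distribution (Clopper–Pearson) 5–95% proportion interval.
6. **Survival.** Kaplan–Meier curves and medians per phenotype and the
   log-rank (Mantel–Cox) test, plus Mann–Whitney and Spearman statistics for
   the clinical comparisons.

A seeded **synthetic cohort generator** reproduces the structure this
analysis assumes (63 patients split 32 LRP / 16 HRP / 15 IRP, a 376-microRNA
card with two low-variance controls, planted differential microRNAs,
families and strand pairs, a strong negative rate-vs-time-to-recurrence
coupling, and per-group survival medians of 63.5 / 18 months), with a
ground-truth record so every stage can be validated end to end.

## Worked example

```r
library(oligomiR)

co <- generateCohort(cohortSpec(seed = 1))
ph <- stratifyCohort(cohortClinical(co))
attr(ph, "summary")
#> LRP HRP IRP
#>  32  16  15

x   <- deltaCtNormalize(flagEntries(cohortCt(co)))
tab <- differentialTable(x, ph$rate_class)      # HRP vs LRP delta-delta-Ct
head(prioritize(tab, 0.05)[, c("mirna_id", "signed_fold", "p_value")], 3)
#>         mirna_id signed_fold      p_value
#> 164 hsa-miR-7004  -13.579036 1.722929e-11
#> 167 hsa-miR-7007  -10.241947 3.424749e-10
#> 165 hsa-miR-7005   -9.264558 8.596952e-09

mifam <- system.file("extdata", "synthetic_mifam.dat", package = "oligomiR")
catal <- familyCatalog(parseMiFam(mifam), setdiff(rownames(x), controlIds(x)))
familyPermutationTest(x, ph$rate_class, catal, nPerm = 10000, seed = 2)
#> Family / -3p/-5p co-expression enrichment
#>   prioritized families: mir-501
#>   prioritized pairs: hsa-mir-601, hsa-mir-602
#>   observed count: 3
#>   empirical p = 9.999e-05 (10000 permutations, seed 2)
```

The prioritized table reads like a fold-change ranking: the planted
microRNAs (2-to-8-fold down-shifts in HRP samples, here estimated with
sampling noise on 16 + 32 patients) head the list. The enrichment test
finds the planted 4-member family and the two planted -3p/-5p pairs
(observed count 3) far out in the permutation null. Branch statistics for a
labelled dendrogram partition come from `clusterSamples()` +
`branchEnrichment()`, e.g.

```r
contingencyStats(matrix(c(13, 12, 3, 20), 2, byrow = TRUE))
#>      [,1] [,2]
#> [1,]   13   12
#> [2,]    3   20
#> odds ratio = 7.22, two-tailed Fisher exact p = 0.0059
```

The whole chain — stratify, QC, normalize, differential, enrichment,
clustering, survival — runs as one call with `runPipeline(pipelineConfig(...))`,
or from a shell via `inst/scripts/oligomir.R` (`simulate` and `run`
subcommands).

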