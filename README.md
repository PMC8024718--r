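# metCNA

Downstream analysis of DNA copy-number profiles from **multiple
metastatic lesions per patient**, built for cohorts of resected
colorectal liver metastases but applicable to any multi-lesion total
copy-number data.

Patients with several liver metastases pose a question that single-biopsy
genomics cannot answer: how much do the lesions of one patient diverge,
and does that divergence — or the overall aberration load — carry
prognostic information beyond driver-gene mutations? `metCNA` implements
the full downstream pipeline for this question on segmented total
copy-number input:

* **Harmonization** — sample-wise segments are split at every breakpoint
  occurring in any lesion, yielding the *smallest regions of overlap*, a
  region × lesion copy-number matrix (`harmonizeLesions()`, a
  `RangedSummarizedExperiment` subclass).
* **Gain/loss calling** — a region is gained/lost in a lesion when its
  copy number is ≥ 1 copy above / ≤ 1 copy below the lesion's
  length-weighted **median genome-wide copy number**
  (`callAberrations()`).
* **CNA burden** — percent of covered base pairs with a non-neutral
  call, averaged per patient (`cnaBurden()`); the "fraction genome
  altered" statistic.
* **Intermetastatic heterogeneity** — four per-patient estimators
  (`patientHeterogeneity()`): mean pairwise Euclidean distance, mean
  pairwise (1 − Pearson r), the discordant-gene fraction (aberrant genes
  not shared by all lesions), and a variance-filtered Euclidean variant;
  each dichotomized at the cohort median.
* **High-level amplifications** — regions with ≥ 15 *additional copies*
  over ploidy in any lesion, merged into events and classified as
  `homogeneous` (every lesion ≥ 15), `intermediate_concordant` (every
  lesion ≥ 5) or `heterogeneous` (`detectAmplifications()`,
  `classifyConcordance()`), with cancer-gene annotation.
* **Mutation grouping** — per-lesion KRAS/NRAS/BRAF-V600E/TP53 calls
  aggregate to patient level ("any lesion mutated ⇒ mutated") and map to
  the strata double-wild-type / TP53-only / RAS-BRAF-only /
  **co-mutation** (`classifyMutationGroup()`).
* **Survival** — five-year cancer-specific survival with other-cause
  deaths censored, MSS + R0/R1 eligibility filtering, Kaplan–Meier,
  two-group log-rank, a 1-df log-rank **trend** test for ordered strata,
  and Cox regression with Efron ties (`stratifiedSurvival()`,
  `coxFit()`), including the combined mutation × CNA strata.
* **Synthetic cohorts** — `generateCohort()` draws multi-lesion cohorts
  with truncal/private events on a CRC-typical arm prior, injected
  amplifications, mutually exclusive driver mutations at realistic
  prevalences, and group-specific exponential survival, together with a
  truth record for recovery tests.

## Worked example

```r
library(metCNA)

co <- generateCohort(cohortConfig(nPatients = 6,
                                  genome = syntheticGenome("mini", 5e4),
                                  nGenes = 120), seed = 42)
rm <- harmonizeLesions(co$lesions)
rm
#> RegionMatrix: 229 regions x 23 lesions (6 patients)
#>   assays: copyNumber

cm <- callAberrations(rm)          # gains/losses vs per-lesion median
head(cnaBurden(cm)$perPatient)
#>   patient_id n_lesions   burden
#> 1       P001         2 5.284909
#> 2       P002         4 2.830227
#> 3       P003         2 9.113091
#> 4       P004         2 4.190636
#> 5       P005         6 3.795985
#> 6       P006         7 4.622961

het <- patientHeterogeneity(cm, genes = co$genes)
het[, c("patient_id", "n_lesions", "euclidean", "discordant", "euclidean_label")]
#>   patient_id n_lesions euclidean discordant euclidean_label
#> 1       P001         2 44.940615  0.3000000            high
#> 2       P002         4  4.772365  0.4000000             low
#> 3       P003         2 12.005065  0.1666667            high
#> 4       P004         2  3.464102  0.2000000             low
#> 5       P005         6 15.062311  0.8000000            high
#> 6       P006         7  5.510495  0.7727273             low
```

The burden column is the percent of the genome with aberrant copy
number, averaged over each patient's lesions. `euclidean` is the mean
pairwise distance between that patient's lesion profiles (its absolute
scale depends on the region count; only the high/low split at the
cohort median is used downstream), and `discordant` is the fraction of
aberrant genes not shared identically by all lesions — patient P005
carries mostly private events, P004 mostly truncal ones.

`runPipeline(pipelineConfig(...))` chains every step (load → harmonize
→ call → burden/heterogeneity/amplification → groups → survival) and
writes deterministic TSV tables plus a run manifest; a thin
command-line wrapper lives at `inst/scripts/run-pipeline.R`.

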