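---
title: "Quantifying intermetastatic copy-number heterogeneity with metCNA"
author: "metCNA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intermetastatic copy-number heterogeneity with metCNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metCNA)
```

## The analysis problem

Colorectal cancer patients who undergo liver resection often present with
several distinct metastatic lesions. When each lesion has been profiled
for total DNA copy number (segmented output of an allele-specific array
or sequencing pipeline such as ASCAT), three questions arise that this
package answers in a reusable, tested form:

1. **How aberrant is each tumor genome?** — the copy-number aberration
   (CNA) burden, i.e. the percent of base pairs called gained or lost.
2. **How different are a patient's metastases from one another?** —
   intrapatient intermetastatic heterogeneity, summarized per patient.
3. **Do these genomic measures, combined with driver-gene mutations
   (KRAS/NRAS/BRAF-V600E and TP53), stratify cancer-specific
   survival?**

The package deliberately starts *after* segmentation: its inputs are
per-lesion segment tables, a gene interval file, and a clinical table.
Array preprocessing, segmentation itself and its quality control are out
of scope.

## Data model and harmonization

Lesion profiles are held in a `LesionSet` (a `GRangesList` of
non-overlapping segments with a `copyNumber` column plus per-lesion
metadata). Analyses across lesions require a common coordinate system:
`harmonizeLesions()` introduces a breakpoint at every breakpoint present
in any lesion, producing the *smallest regions of overlap* — the
coarsest partition of the covered genome on which every lesion is
piecewise constant. The result is a `RegionMatrix`, a
`RangedSummarizedExperiment` with one `copyNumber` entry per (region,
lesion), `NA` where a lesion has no segment. The operation is idempotent
and preserves each lesion's genomic footprint; both properties are
enforced by tests against a brute-force per-base-pair oracle.

Only autosomes are analyzed; X/Y rows are dropped at load time so that
no downstream step has to reason about sex chromosomes.

On file boundaries the package follows each format's native convention
(SEG-style tables are 1-based inclusive, BED is 0-based half-open);
internally segments live in the native 1-based closed `IRanges`
representation.

## Calling gains and losses

A region is called gained in a lesion when its copy number exceeds the
lesion's *median genome-wide copy number* by at least 1 copy, and lost
when it falls at least 1 copy below it (closed comparisons, thresholds
configurable via `gainThreshold`/`lossThreshold`). The median is
computed as the **length-weighted** median of segment values —
equivalent to the median over per-base-pair copy numbers — because an
unweighted median over segments would be biased by segmentation density.
This baseline choice makes calls invariant to subdividing any segment,
a property the suite checks explicitly.

The CNA burden of a lesion is the percent of its covered base pairs
with a non-neutral call; the patient-level burden is the mean across
the patient's lesions. Regions missing in a lesion are excluded from
that lesion's denominator (the upstream pipeline is assumed to leave
gaps only where it had no information).

## Heterogeneity estimators

`patientHeterogeneity()` computes four per-patient summaries on the
harmonized matrix, each requiring at least two lesions:

* **Euclidean** (`hetEuclidean`): mean Euclidean distance over all
  lesion pairs, one coordinate per region. This is the primary measure;
  its absolute scale depends on the cohort's region count, and only the
  ranking feeds the median split, so the unweighted form is the
  default.
* **Correlation** (`hetCorrelation`): mean (1 − Pearson r) over pairs,
  in [0, 2]; undefined for constant profiles.
* **Discordant-gene fraction** (`hetDiscordantFraction`): of the genes
  aberrant in at least one lesion, the fraction whose ternary call is
  not identical across all lesions. Genes gained (or lost) in every
  lesion with different amplitudes count as concordant — this measure is
  deliberately more conservative than the distances.
* **Variance-filtered** (`hetVarianceFiltered`): mean pairwise Euclidean
  distance restricted to regions whose across-lesion variance exceeds a
  threshold, a legacy variant retained for comparability. The default
  threshold is 0.03; because both 0.03 and 0.3 are in circulation for
  this legacy statistic, the threshold is exposed as an option rather
  than hard-coded.

Missing regions are handled pairwise-complete; a lesion pair sharing
fewer than `minSharedRegions` (default 10) regions is refused with an
explicit status instead of being silently computed.

An optional `lengthWeighted` mode weights squared differences by region
length as a fraction of the pair's shared length (weights summing to 1,
a length-weighted RMS difference). This formulation was chosen over
weighting by length/mean-length because it is *exactly* invariant under
segment subdivision — mean region length changes when a segment splits,
which would rescale the score by the square root of the region-count
ratio without changing any ranking. The default remains unweighted, the
literal reading of a distance on a value matrix.

Scores are dichotomized at the cohort median (`dichotomizeByMedian`),
with ties assigned to "low" so that "high" always means strictly above
the median — a deterministic, conservative rule.

## Amplifications and concordance

`detectAmplifications()` searches the harmonized matrix for regions
where any lesion carries at least 15 *additional copies* relative to
its ploidy (supplied externally or estimated as the length-weighted
median copy number; comparisons use the unrounded difference).
Qualifying abutting regions merge into one event; an event's per-lesion
additional copies are the maximum over member regions. Intrapatient
concordance depends only on the minimum across lesions:

| minimum across lesions | class |
|---|---|
| ≥ 15 | homogeneous |
| ≥ 5 and < 15 | intermediate_concordant |
| < 5 | heterogeneous |

Events are reported per merged genomic region (genes are attached by
overlap annotation), which avoids double-counting an amplicon that
covers several genes. Patients with a single analyzed lesion are
flagged and excluded from concordance summaries.

## Mutation groups and survival conventions

Per-lesion mutation calls aggregate to patient level with an "any
lesion mutated ⇒ patient mutated" rule; patients with both mutated and
wild-type lesions keep a heterogeneity flag but count as mutated.
Patients partition into four strata — double wild-type, TP53-only,
RAS/BRAF-only, and co-mutation (a RAS-pathway mutation together with
TP53) — with unknown defining genes excluding a patient from grouped
analyses rather than defaulting to wild-type. KRAS/NRAS/BRAF-V600E are
expected mutually exclusive; violations are listed, not repaired.

Survival analyses use five-year cancer-specific survival: time runs
from treatment start, cancer deaths are events, other-cause deaths are
censored at their time, and the 60-month survival is read from the
Kaplan-Meier curve with last-value-carried-forward. Only
microsatellite-stable patients with R0/R1 liver resections are
eligible; removals are counted in the run manifest. Two groups are
compared by the log-rank test; three or more ordered groups by a
one-degree-of-freedom log-rank trend test (score contrast of
observed-minus-expected events with equally spaced scores, implemented
on top of `survival::survdiff()`'s output because no suitable trend
implementation is available in the package's dependency set). Cox
models use the Efron tie approximation — follow-up is recorded in
months, ties are common, and Efron is the less biased standard choice.
No p-value is adjusted for multiple testing anywhere, matching the
exploratory design of the analyses the package supports. The combined
mutation-by-CNA analysis orders strata as no-co-mutation <
co-mutation/low < co-mutation/high, with no-co-mutation the Cox
reference group.

## What the synthetic cohorts emulate

Because real multi-lesion copy-number cohorts of this kind are rarely
publicly deposited, the package validates itself on synthetic cohorts
(`generateCohort()`), which emulate:

* 2–8 lesions per patient; truncal events shared by all of a patient's
  lesions and private events drawn independently per lesion, with a
  per-patient lognormal rate multiplier creating genuine between-patient
  heterogeneity variation;
* a colorectal-cancer-typical arm-level placement prior (recurrent
  gains on 7p/7q/8q/13q/20q, losses on 1p/4p/4q/8p/17p/18p/18q),
  switchable to uniform for unbiased property tests;
* occasional high-level amplifications (≥ 15 additional copies) with a
  concordance-class mix of 31% homogeneous / 38% intermediate / 31%
  heterogeneous; when the private-event rate is zero, amplification
  amplitudes are forced identical across lesions so that "no private
  events" really means identical lesions;
* patient-level mutation prevalences of 42.7% (KRAS), 4.7% (NRAS),
  1.8% (BRAF-V600E) and 72.5% (TP53), with RAS/BRAF mutual exclusivity
  enforced by construction;
* exponential cancer-specific survival with stratum-specific hazards
  (baseline median survival 48 months; hazard ratios 2.3 / 2.6 / 4.1
  for TP53-only / RAS-BRAF-only / co-mutation, and a further 1.6 for a
  latent high-CNA-divergence propensity), plus independent other-cause
  and uniform administrative censoring. The exponential form was chosen
  because nothing in the analysis design constrains the hazard shape and it makes analytic expectations available for recovery
  tests.

The generator writes a truth record (event lists, true discordant-gene
fraction, group label, generative hazard, per-lesion ploidy) that is
reproducible from `(config, seed)`.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: probe-level noise, segmentation
error and quality-control artefacts; whole-genome doubling dynamics and
subclonal mixtures; realistic lesion phylogenies (private events are
exchangeable rather than tree-structured); and correlations between
clinical covariates and genomics beyond the survival hazards. Tests on
synthetic cohorts establish *software correctness and statistical
calibration*, not clinical conclusions.

## Problem sizes and numerical choices

The test-suite and the acceptance script run on miniature genomes (22
chromosomes scaled down to between 10^3 and 10^5 bp each, or a handful
of a few-hundred-bp chromosomes for the per-base oracles) so that brute-force per-base
oracles can be enumerated exactly; the end-to-end determinism check
uses a 64-patient, ~220-lesion cohort at human genome scale. These
sizes were chosen as the smallest at which every property under test is
non-trivially exercised.

Further numerical conventions:

* the weighted median interpolates the two straddling values when the
  half-weight point falls exactly on a segment boundary (matching the
  ordinary median of the base-pair expansion);
* gene-to-region assignment takes the region with the largest overlap,
  ties broken by the earlier region — deterministic and order-free;
* `NaN`-producing degenerate cases (constant profiles in the
  correlation measure, zero aberrant genes in the discordant fraction,
  no surviving regions in the variance filter) carry explicit status
  attributes instead of silent `NA`s;
* all output tables embed the package version and a configuration hash
  but no timestamp, so identical runs are byte-identical.

## Known limitations

* Total copy number only: no allele-specific states, no purity
  correction (an aberrant-cell-fraction column is carried through for
  external estimates but not used in calling).
* The discordant-gene fraction needs a gene list; with none supplied it
  falls back to harmonized regions, which changes its granularity.
* The log-rank trend test relies on the asymptotic chi-square null; on
  very small strata its p-values inherit the usual small-sample
  caveats (the suite quantifies this against a permutation null).
* Single-lesion patients contribute to burden and amplification
  detection but never to heterogeneity or concordance summaries.
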