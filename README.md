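# hrdact

Combined homologous-recombination-deficiency (HRD) and immune-activation
analysis for predicting response to anthracycline/cyclophosphamide/taxane
(ACT) chemotherapy in triple-negative breast cancer (TNBC).

TNBC patients respond very unevenly to ACT. Tumours that have lost
homologous recombination repair carry characteristic genomic scars and
respond well to DNA-damaging chemotherapy; among HR-proficient tumours, a
subgroup with an interferon-primed, checkpoint-expressing immune
microenvironment also does well. `hrdact` implements the full analysis
chain that identifies both phenotypes and combines them into a single
responder classifier, for biostatisticians and computational biologists
working with multi-omic breast-cancer cohorts.

## What it computes

* **Genomic scars** from allele-specific copy-number segments: counts of
  large LOH regions (> 15 Mb, not whole-chromosome), telomeric allelic
  imbalances (ntAI) and large-scale transitions (LST), summed into the
  HRD score. HR status: deficient iff a deleterious tumour *BRCA1/2*
  mutation or HRD score ≥ 42. Also *BRCA1* promoter-methylation calls
  (cg13782816 β > 0.9) and tumour mutation burden.
* **Mutational signatures**: 96-channel trinucleotide spectra
  (pyrimidine-strand convention), per-sample exposure refitting by
  forward selection with non-negative least squares and a 6% drop floor,
  SBS3-dominance calls (≥ 0.3), the insertion/deletion ratio, and an
  HRDetect-style lasso-logistic deficiency probability.
* **Immune scores**: ssGSEA-style single-sample pathway activities
  (rank-based, exponent 0.25), summed over immune response pathways or
  averaged over marker genes; positivity = top quartile.
* **The HRD expression signature**: differential expression between HR
  status groups (negative-binomial Wald test; DESeq2 backend optional) →
  univariate Cox on the failure-free interval (FFI) → lasso reduction,
  then per-sample prognostic scores

  PS_i = Σ_j Exp_ij / HR_j,  HRDPS_i = PS_i,up − PS_i,down

  where HR_j is factor j's univariate Cox hazard ratio and Exp_ij its
  log expression.
* **Cohort statistics**: Kaplan-Meier/log-rank, adjusted Cox models
  (Efron ties), likelihood-ratio comparison of nested models, time-fixed
  ROC at 60 months, Fisher's exact test (both sidedness variants), and
  Wilcoxon/Kruskal-Wallis with BH correction and a 10,000-iteration
  permutation variant.
* **Pipelines**: `run_discovery()` (scars → HR status → signatures →
  immune score → ACT labels → survival statistics) and
  `run_validation()` (HRDPS + IS → combined status → four-group survival
  and pCR tables).
* **A synthetic multi-omic cohort generator** with planted ground truth
  (`generate_cohort()`): 57.8% HRD prevalence, BRCA1/2 carriers at
  7.2%/6%, a planted FFI hazard ratio of 0.16 for HRD, immune activation
  concentrated among HR-proficient patients, an HRD-correlated
  expression signature and bimodal methylation — so every stage above is
  testable without patient data.

## Worked example

```r
library(hrdact)

bundle <- generate_cohort(cohort_config(n_samples = 600, seed = 1))
report <- run_discovery(bundle)
report
```

```
Discovery run: 600 samples

 HR-deficient HR-proficient 
          354           246 
FFI Cox HR(HRD) = 0.218 [0.162, 0.293], p = 5.95e-24
Log-rank p (FFI by HR status) = 2.61e-28
5-y ROC AUC: combined 0.713 vs HRD alone 0.712
```

The cohort plants an FFI hazard ratio of 0.16 for HR deficiency plus a
protective immune-activation effect concentrated in HR-proficient
patients. The age/stage-adjusted Cox fit on the *classified* (not
ground-truth) HR status estimates 0.218 with a confidence interval well
clear of 1 — attenuated above 0.16 exactly because the co-planted immune
effect confounds the marginal contrast (conditioning on both planted
flags recovers 0.16; that recovery is an acceptance test). The log-rank
test on the same grouping is strongly significant, and the combined
HRD-or-immune classifier edges out HRD alone for predicting 5-year
failure-free status — a small ordering effect here, demonstrated
systematically across replicates in the acceptance suite.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic discovery cohort from the given seed,
runs the complete discovery analysis end-to-end (scar scoring, HR-status
classification, signature exposures, immune scoring, response labelling,
Cox/log-rank/ROC statistics), prints the report summary, and writes the
results JSON to `--out`.

## Layout

```
R/                     implementation
tests/testthat/        unit, property and acceptance tests
scripts/acceptance.R   end-to-end acceptance driver
vignettes/             methods vignette (model, assumptions, calibration)
inst/extdata/          synthetic placeholder immune gene sets (GMT)
```

The packaged immune gene sets and the 5-column signature matrix are
deterministic synthetic stand-ins; supply curated GMT files and real
signature matrices for analyses of real cohorts. See the methods
vignette for the model, parameter defaults and their provenance, and
known limitations.
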