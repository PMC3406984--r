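---
title: "Validating cancer surgery records in administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cancer surgery records in administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcvalidate)
```

## The problem

Cancer registries are the reference source for whether and when a patient
had the operation that removed their primary tumor, but registry coding is
slow (18 months to 2 years) and many registries do not collect treatment
at all. Administrative data — physician billing claims and hospital
discharge abstracts — are available within months, so the practical
question is how completely and accurately they identify cancer surgery
when the registry is taken as the gold standard.

`crcvalidate` implements that validation pipeline for colorectal cancer:

1. **Cohort construction.** Registry records with colorectal ICD-O
   topography (`c18.0`, `c18.2`–`c18.9` colon; `c19.9`, `c20.9` rectum)
   are kept; records missing the person-level linkage identifier (ULI),
   with a histology that cannot be staged, or with stage 0 (in-situ)
   disease are excluded, in that fixed priority order. Patients whose
   stage is missing for any other reason are retained and reported as
   their own stratum.
2. **First-surgery linkage.** For each source, the earliest claim whose
   procedure code is on the qualifying list and whose service date lies
   in the closed window from 7 days before to 548 days after diagnosis
   is the patient's surgery event. A combined administrative dataset
   takes the union of the two sources, keeping the earlier date when both
   have one.
3. **Validation measures.** Each source is cross-tabulated against the
   registry indicator, and sensitivity, specificity, PPV, NPV and
   observed agreement are computed with Wilson 95% intervals,
   overall and by year of diagnosis, stage, and tumor site. Observed
   agreement `(TP+TN)/N` is used instead of Cohen's kappa because the
   near-degenerate prevalence in stage I–III strata (over 98% operated)
   makes kappa uninterpretable there.

Two further components make the pipeline testable without any
confidential data: a synthetic linked-cohort generator, and a
reconstruction module that recovers integer 2×2 tables from published
marginal counts and rounded whole-percent measures.

## Measures, intervals, instability

With `tp, fp, fn, tn` counted against registry truth,

$$\mathrm{Se} = \frac{tp}{tp+fn},\quad
\mathrm{Sp} = \frac{tn}{tn+fp},\quad
\mathrm{PPV} = \frac{tp}{tp+fp},\quad
\mathrm{NPV} = \frac{tn}{tn+fn},\quad
\mathrm{OA} = \frac{tp+tn}{n}.$$

A measure with a zero denominator is reported as *undefined*, never as 0
or 100. Two algebraic identities are enforced by tests on every computed
table (to `1e-12`): the Bayes relation
$\mathrm{PPV} = \mathrm{Se}\,\pi / (\mathrm{Se}\,\pi + (1-\mathrm{Sp})(1-\pi))$
with $\pi$ the truth prevalence, and the complement relation
$\mathrm{OA} = \mathrm{Se}\,\pi + \mathrm{Sp}(1-\pi)$.

Confidence intervals use the Wilson score interval by default, because
Wald intervals collapse or escape $[0,1]$ in the near-100% strata this
design produces; a Wald option exists for comparison
(`compute_measures(..., ci_method = "wald")`). An estimate is flagged
**unstable** when its 95% CI is wider than 15 percentage points (strict
inequality, "wider than") or when the width is at least 40% of the
estimate (inclusive, "or more"). Empirical coverage of the Wilson
interval is tested at $p = 0.8$, $n = 100$ over 10,000 replicates and
required to fall in [93%, 97%] (the exact coverage there is 94.1%).

Percentages shown in reports are rounded **half-up** (0.5 away from
zero), the convention of printed clinical tables; base R's IEEE
round-half-even is deliberately not used for display. Internal values
keep full precision.

## The synthetic generator

`generator_config()` describes a linked cohort; `generate_cohort()`
produces the registry extract, the billing claims, the hospital claims,
and a per-patient latent truth log. The observation model:

* stage and site are drawn per patient; the registry records a surgery
  with a per-stage probability, dated diagnosis + delay;
* a registry surgery is administratively invisible with a per-stage
  *registry-only* probability — the polypectomy mechanism, where an
  outpatient polypectomy counts as primary-tumor removal for the registry
  but produces no inpatient or billing surgery code;
* otherwise each source captures the surgery independently with its
  capture probability, and the claim date is jittered off the registry
  date with a small probability (jittered dates are clamped to the
  linkage window; window exclusion itself is tested with explicit
  fixtures);
* patients without a registry surgery undergo an administratively visible
  operation with a per-stage *false-positive* probability — the
  palliative de-bulking/stoma mechanism concentrated in stage IV. By
  default the two sources see the same latent event (correlation 1) and
  capture it independently, since such operations are real
  hospitalisations visible to both systems; `fp_correlation` scales this
  down to independent per-source events.

Defaults are calibrated to the structure of a published provincial
cohort: 8,533 records over diagnosis years 2000–2005, ~85% registry
surgery prevalence overall, near-100% for stages I–III and ~60% for
stage IV, stage distribution and exclusion-seeding rates matching the
printed frequency table, capture probabilities 0.99 (billing) and 0.96
(hospital) with the registry-only probability 0.09 concentrated in
stage I — together these imply marginal sensitivities near 0.97 and
0.94 — per-stage false-positive rates near one minus the published
combined specificities, and a 5% date-jitter probability (so ~95% of
administrative dates match the registry exactly). The diagnosis-to-
surgery delay is a rounded gamma (shape 2, scale 15 days, clamped to
[−7, 548]); no published delay distribution exists, so this is a module
parameter, not a claim about any real jurisdiction.

What the generator does **not** emulate: correlated misses between
sources for true surgeries (the two sources miss independently here,
so synthetic combined sensitivity gains more from pooling than real
data showed), stage-specific capture, realistic procedure vocabularies
(synthetic codes such as `SURG01` suffice; real code lists drop in via
`read_code_list()`), billing fee policy, readmissions, or migration.
Passing tests on synthetic data therefore demonstrate the pipeline's
correctness, not the validity of any particular administrative source.

## Reconstructing published 2×2 tables

Published validation tables report marginals (denominator, registry
positives, source positives) and whole-percent measures, not the
underlying cross-tabulation. Given the marginals, one seed measure
determines the table: `reconstruct_from_seed()` converts the printed
percentage back to a count under the stated rounding convention and
derives the remaining cells. For an agreement seed the diagonal total
`tp + tn` is split using `tp − tn = test_pos − (n − truth_pos)`; when
the rounded total has the opposite parity to the marginals no exact
table exists and the half is floored. An infeasible seed (negative
cell) is reported as infeasible, not an error.

`feasible_tp_set()` goes further: it enumerates every integer `tp`
consistent with the marginals and checks which reproduce *all* stated
rounded measures simultaneously. A non-empty set certifies the
published row as internally consistent; an empty set proves no integer
table can produce those printed values under that rounding convention.
On the overall billing row the set is a contiguous range of ten values
around `tp ≈ 6825`; on the overall hospital row the five printed
measures are jointly infeasible under half-up rounding — dropping the
NPV value restores feasibility, locating the inconsistency — which may
reflect a different rounding convention or a typographical slip in the
source table. The package reports such findings and does not decide
among explanations. `rounding = "half-even"` is available to probe the
sensitivity of feasibility verdicts to the convention.

## Numerical and design choices

* **Window ends closed.** "7 days prior to or up to 548 days" includes
  both offsets −7 and +548; offsets are whole days with no time-of-day.
* **Registry truth is not windowed.** A registry surgery date is truth
  regardless of its offset from diagnosis; only the administrative
  extraction is windowed.
* **Tie-breaks.** Two same-date qualifying claims in one source are
  resolved by lexicographic procedure code, making linkage invariant to
  input row order (a tested property). The choice cannot affect any
  reported measure, which depends only on the date.
* **Exclusion priority.** Missing ULI, then unstageable histology, then
  stage 0, so each record is counted once and tallies are deterministic
  even when rules overlap; records with non-colorectal topography are
  out-of-scope input counted in a separate bucket.
* **Half-up rounding** with a `1e-9` epsilon guard against binary
  representation of exact halves.
* **Determinism.** Generation is bit-for-bit reproducible from
  `rng_seed`; reports rerun byte-identically on identical inputs, with
  fixed stratum order (all, year ascending, stage I–IV then Missing,
  colon then rectum).

## Problem sizes used in tests

Module tests run cohorts of a few hundred to 6,000 patients; the
parameter-recovery check uses 20,000 patients (3 binomial standard
errors around configured capture probabilities), the jitter-recovery
check 12,000, and the composition check of the stratified report 5,000.
The feasibility audit enumerates ~6,800 candidate tables, which is
instantaneous. The whole suite completes in well under a minute.

## Limitations

The pipeline validates *identification of surgery* at the date level; it
does not distinguish primary-tumor resection from reconstruction or
stoma surgery by code semantics (the first qualifying claim is assumed
to be the resection), does not implement Collaborative Staging (a
stageability flag is input), and the synthetic generator's independence
assumptions mean stratum-level synthetic results should not be read as
estimates for any real administrative system.
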