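# crcvalidate

Validation of colorectal-cancer surgery records in administrative health
data against a cancer registry treated as the gold standard.

Cancer registries record the date of the operation that removed a
patient's primary tumor, but registry coding lags treatment by 18 months
or more. Physician billing claims and hospital discharge abstracts are
available within months — if they identify surgery completely and
accurately enough. `crcvalidate` is the pipeline for answering that
question: it builds the analysis cohort from a registry extract (ICD-O
colorectal topography; exclusions for missing linkage identifier,
unstageable histology, and stage 0 disease), links each patient to their
first qualifying surgery claim per source within a closed window of −7 to
+548 days around diagnosis, combines the two administrative sources
(union, earlier date wins), and computes sensitivity, specificity,
positive and negative predictive value, and observed agreement

    Se = TP/(TP+FN)   Sp = TN/(TN+FP)   PPV = TP/(TP+FP)
    NPV = TN/(TN+FN)  OA = (TP+TN)/N

with Wilson 95% confidence intervals and instability flags (CI wider
than 15 percentage points, or width ≥ 40% of the estimate), overall and
stratified by year of diagnosis, stage, and tumor site.

Because real registry and claims databases are confidential, the package
also provides:

* a **synthetic linked-cohort generator** (`generator_config()`,
  `generate_cohort()`) whose observation model reproduces the structure
  such validation studies report — near-100% surgery prevalence in
  stages I–III, registry-only stage-I polypectomies, administrative-only
  stage-IV palliative operations, per-source capture probabilities, and
  small date jitter — with a per-patient latent truth log for testing;
* a **reconstruction module** (`reconstruct_from_seed()`,
  `feasible_tp_set()`) that recovers the integer 2×2 table behind a
  published row of marginal counts and rounded whole-percent measures,
  and exhaustively audits whether a full set of printed measures is even
  jointly consistent with its marginals.

## Worked example

Simulate a linked cohort, run the pipeline, and look at the overall
billing row:

```r
library(crcvalidate)
ds  <- generate_cohort(generator_config(n_patients = 2000, rng_seed = 42))
res <- run_pipeline(ds$registry, ds$billing, ds$hospital)

res$tally
#>   n_input n_nonqualifying_site n_missing_uli n_unstageable n_stage0 n_included
#> 1    2000                    0             0            42       18       1940

subset(res$table2, stratum_factor == "all" & source == "billing")
#>   stratum_factor stratum_level  source     measure estimate_pct ci_low_pct ci_high_pct unstable defined
#> 1            all           all billing sensitivity           97       96.6        98.1    FALSE    TRUE
#> 2            all           all billing specificity           72       67.2        77.2    FALSE    TRUE
#> 3            all           all billing         ppv           95       93.8        95.9    FALSE    TRUE
#> 4            all           all billing         npv           84       79.5        88.3    FALSE    TRUE
#> 5            all           all billing   agreement           94       92.4        94.6    FALSE    TRUE
```

Of 2,000 simulated registry records, 60 are excluded (42 unstageable
histology, 18 stage 0). Billing claims then identify registry-recorded
surgeries with 97% sensitivity and 72% specificity — the false positives
are stage-IV palliative operations the registry does not count as
primary-tumor removal, and about 95% of billing dates match the registry
date exactly (`res$date_report`).

Reconstruct the 2×2 table behind a published overall row (N = 8,308,
7,066 registry positives, 7,173 billing positives, printed specificity
72%):

```r
t <- reconstruct_from_seed(marginal_spec(8308, 7066, 7173), "specificity", 72)
t
#>             registry
#> source       surgery no surgery
#>   surgery       6825        348
#>   no surgery     241        894

feasible_tp_set(marginal_spec(8308, 7066, 7173),
                c(sensitivity = 97, specificity = 72, ppv = 95,
                  npv = 79, agreement = 93))
#>  [1] 6822 6823 6824 6825 6826 6827 6828 6829 6830 6831
```

The reconstructed table yields sensitivity 97%, PPV 95%, and observed
agreement 93% on re-rounding, and the feasibility audit certifies that
exactly ten integer tables (TP between 6,822 and 6,831) reproduce all
five printed measures simultaneously — the published row is internally
consistent.

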