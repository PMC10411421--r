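---
title: "Methods: a tiered EHR phenotype for advanced chronic kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tiered EHR phenotype for advanced chronic kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdtier)
```

## The problem and the model

Chronic kidney disease (CKD) is staged by estimated glomerular filtration
rate (eGFR); stages 4–5 ("advanced" CKD, eGFR < 30 ml·min⁻¹·1.73 m⁻²
before dialysis dependence) carry the highest risk of progression to
kidney failure and are the population that pre-dialysis education and
nephrology referral programs need to find. Neither of the two routinely
available signals identifies this population well on its own:

* **Diagnosis codes** (ICD-10 N18.4, N18.5) are assigned inconsistently;
  a large fraction of laboratory-confirmed advanced CKD carries no code,
  and some coded patients have recovered kidney function.
* **A single recent eGFR** below 30 can reflect an acute kidney injury
  (AKI), volume depletion, or ordinary biological and assay variability
  in serum creatinine rather than sustained disease. CKD is by definition
  a *sustained* reduction — guideline phenotypes for stage ≥ 3 therefore
  require two qualifying values more than 90 days apart.

`ckdtier` implements a tiered rule-based phenotype that grades the
evidence instead of forcing a binary call. From each patient's **index
eGFR** (latest value in a 12-month lookback) and **prior eGFR** (most
recent value at least 90 days before the index), plus diagnosis codes:

* **high**: both values < 30 — sustained advanced CKD;
* **intermediate, subgroup 1**: index < 30, prior in [30, 60) — apparent
  progression into stage 4/5; patients with an AKI code (N17 category) in
  the 90 days before the index value are carved out (`excluded_aki`)
  because the drop may be reversible;
* **intermediate, subgroup 2**: index in [30, 60), prior < 30, with an
  advanced-CKD code — apparent regression out of stage 4/5 where the
  clinical record still asserts advanced disease;
* **low**: both values ≥ 30 with an advanced-CKD code — coded but not
  laboratory-confirmed;
* **unclassified**: everything else, including a missing prior value.

The tiers are mutually exclusive and collectively exhaustive over the
source cohort; an exhaustive truth-table test pins every cell.

eGFR is computed with the 4-variable MDRD study equation
(IDMS-traceable re-expression),

$$\mathrm{eGFR} = 175 \cdot \mathrm{Scr}^{-1.154} \cdot
\mathrm{age}^{-0.203} \cdot 0.742^{[\mathrm{female}]} \cdot
1.212^{[\mathrm{Black}]},$$

with creatinine in mg/dL and age in years at the collection date. The
MDRD equation (rather than CKD-EPI) is the package's reference equation
because it remains the stored convention in several large health-system
data warehouses; the leading coefficient is a parameter (`coefficient`,
default 175; the older non-IDMS form used 186) so a system can match its
local convention. CKD-EPI 2009/2021 and cystatin-C equations are out of
scope, as is albuminuria staging — urine protein measurement is too
sparsely recorded in routine EHR data to support a parsimonious
real-time rule.

## Cohort extraction

The source cohort mirrors a data-warehouse extraction anchored at a
reference ("as-of") date:

1. active enrollees → those with ≥ 1 creatinine result in the lookback
   window (the prevalence denominator);
2. inclusion by *either* arm: index eGFR ≤ 30, or an N18.4/N18.5 code in
   the window;
3. exclusion of dialysis/ESKD patients by ICD-10 and CPT code sets.

Two conventions deserve note. First, the eGFR arm of cohort *inclusion*
uses a non-strict `≤ 30` while the tier classifier and the comparator
phenotypes use strict `< 30` comparisons; both conventions circulate in
the phenotyping literature and the package preserves the distinction
rather than harmonising it (`egfr_inclusive` switches the inclusion arm
to strict). Because eGFR is a continuous quantity this matters only for
values exactly on the boundary. Second, code-arm members with no
creatinine lab in the window are *retained* in the cohort (the inclusion
logic is a genuine OR) but are `unclassified`, since no eGFR-based tier
can be assigned; they remain visible in the assignment table rather than
silently vanishing.

The dialysis/ESKD exclusion list shipped with the package (ICD-10 Z99.2,
N18.6, Z49 prefix; CPT 90935–90999) is a clearly-labelled synthetic
stand-in: production systems maintain local dialysis lists and should
override it via the code-set YAML.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lookback_days` | 365 | days | "last 12 months" window ending at the reference date, both endpoints included |
| `min_gap_days` | 90 | days | minimum index-to-prior separation establishing chronicity |
| `egfr_threshold` | 30 | ml·min⁻¹·1.73 m⁻² | stage 4/5 boundary |
| stage upper bound | 60 | ml·min⁻¹·1.73 m⁻² | stage 3 boundary used by the intermediate/low rows |
| `aki_window_days` | 90 | days | AKI lookback before the index date, closed interval |
| `horizon_days` | 180 | days | 6-month follow-up horizon after the reference date |
| `coefficient` | 175 | — | MDRD leading coefficient |
| `ci_method` | wilson | — | binomial interval for all reported proportions |

All date windows are whole calendar days and closed at both ends;
"12 months" is 365 days including the reference date. Months enter only
through the monthly re-extraction grid (steps of 30 days).

## Numerical and tie-breaking choices

* **Thresholds at full precision.** eGFR values are never rounded before
  comparison; display rounding (half-up, one decimal) is applied only
  when formatting. This keeps classification independent of display
  conventions.
* **Same-day duplicate labs** resolve to the *lowest* eGFR — the
  conservative choice when screening for advanced disease. The selection
  is therefore invariant to the input ordering of the lab table, which a
  property test enforces.
* **The prior eGFR is the most recent qualifying value** (latest value
  dated ≥ 90 days before the index), not the oldest available one,
  matching the "two values 90 days apart" reading of chronicity.
* **Undefined tiers stay undefined.** Combinations the tier table does
  not cover (index < 30 with prior ≥ 60; index ≥ 60 with prior < 30;
  missing prior) are `unclassified` rather than forced into a tier; a
  residual group is expected in practice since not every patient carries
  two usable values.
* **AKI carve-out applies to subgroup 1 only.** The rising pattern
  (subgroup 2) already requires a diagnosis code as corroboration, and
  its index value is ≥ 30, so an AKI exclusion there has no analogous
  rationale; the asymmetry is deliberate.
* **Confidence intervals** use the Wilson score interval
  (`prop.test(..., correct = FALSE)`), with Wald as an option. At the
  boundary (0 or 100%), the degenerate side is pinned to exactly 0
  or 100. Wilson is the default because it behaves correctly at small
  counts and near-boundary proportions, where Wald collapses.
* **Follow-up denominators differ by design**: "any subsequent eGFR
  ≥ 30" is a percentage of the whole group, while "current eGFR ≥ 30"
  (and hence the probability of remaining in advanced CKD) is a
  percentage of patients who *have* a subsequent measurement. "Current"
  means the latest value inside the horizon — this is the only reading
  under which the two statistics are jointly coherent, and the tests
  enforce it by brute-force re-evaluation.
* **Cumulative prevalence** re-runs the full extraction at 30-day
  snapshot offsets (0, 30, …, 180) and accumulates the union of patients
  ever classified high or intermediate, over the *fixed* day-0 tested
  denominator.

## What the synthetic generator emulates — and what it does not

`generate_registry()` exists so that every stage of the pipeline can be
exercised and scored without access to protected clinical data. Per
patient it simulates:

* a group label (high / intermediate / low / non-CKD / dialysis) from
  configurable mixture weights; defaults put ~1.9% of patients in the
  advanced tiers in roughly the 53/27/18 high/intermediate/low split
  characteristic of such cohorts, with 0.3% dialysis;
* true eGFR anchors drawn from per-group truncated normals (defaults
  20.3 ± 6.6, 27.4 ± 5.6 and 42.1 ± 16.6 ml·min⁻¹·1.73 m⁻² for
  high/intermediate/low), an index anchor near the reference date and a
  prior anchor 90–330 days earlier, per-group linear drift afterwards,
  and a transient 30% eGFR dip for 30 days after an AKI event;
* serum creatinine obtained by *inverting* the MDRD equation at the
  patient's demographics (age at the collection date, so the generative
  and analytic models agree exactly) and multiplying by lognormal noise
  with `noise_sd = 0.15` on the log scale — roughly a 15% coefficient of
  variation, a realistic magnitude for combined biologic plus assay
  creatinine variability. Because eGFR scales as Scr^−1.154, this
  reproduces the familiar phenomenon that a meaningful minority of true
  stage-4 patients show a follow-up eGFR ≥ 30 while true stage-5
  patients rarely do;
* a coding model: advanced-CKD codes with probability
  `coding_sensitivity` (default 0.55) for high/subgroup-1 patients —
  subgroup-2 and low-risk patients carry codes by construction, as their
  definitions require them — plus a small false-positive rate for
  non-CKD patients; dialysis codes unless miscoded
  (`dialysis_miscode_rate`, default 0.112, matching the order of
  miscoding that manual chart review uncovers); AKI (N17) codes for the
  carved-out fraction (`aki_rate`, default 0.10) dated 0–60 days before
  the index value so the dip never contaminates the prior anchor;
* follow-up labs from a per-group Poisson process (defaults 1.4–1.8
  labs/year for the advanced tiers, calibrated so that roughly half to
  six-tenths of the cohort has a follow-up measurement within 180 days);
  demographics from truncated-normal age 75.3 ± 11.1 on [20, 105],
  95.8% male, 21.9% Black / 67.8% white marginals.

In the noiseless, zero-drift, perfectly-coded limit the generator and
classifier are exact mirror images: every generated patient's assigned
tier equals their ground-truth tier, and the acceptance suite asserts
100% agreement. With default noise the pipeline reproduces the
qualitative structure that motivates the tiered design — stability at
6 months is graded high > intermediate > low — which the test suite
asserts as an ordering, not as point values.

What the generator does **not** emulate: co-morbidity structure in the
code stream, informative timing of measurements (sicker-gets-measured
enters only through per-group rates, not within-patient state), assay
changeovers, unit errors, transfers of care, or death/censoring. Passing
tests on synthetic data therefore demonstrate the *logic* of the
phenotype and metrics, not its operating characteristics on any real
health system's data.

## Problem sizes and runtime choices

The test suite runs oracle-equivalence checks (brute-force per-patient
enumeration vs the vectorised implementation) on 200 random registries
of 20–150 patients, parameter-recovery checks on cohorts of 1,759
(tier weights) and 5,000 (coding sensitivity at 0.6, judged against
binomial 95% bounds on the eligible pool), the noiseless-limit exactness
check at 2,000 patients, and the stability ordering on a 40,000-patient
registry. These sizes give comfortable statistical resolution for every
assertion while keeping the whole suite under a minute on one CPU.

## Known limitations

* The tier-weight recovery carries small systematic fluxes: the AKI
  carve-out removes ~`aki_rate` of subgroup 1 from the intermediate
  count, and creatinine noise leaks borderline intermediate patients
  into the low tier. Both effects are inherent to the phenotype acting
  on noisy data (they are the very misclassification the tiering is
  designed to expose), so configured weights are recovered to within a
  few percentage points, not exactly.
* Code-based sensitivity estimated *within* the extracted cohort is
  upward-biased, because uncoded patients whose noisy index eGFR rises
  above 30 drop out of the cohort entirely; unbiased recovery of the
  coding model must score codes against ground truth over the full
  tested population, which is what the acceptance suite does.
* ICD-10 matching is prefix-based after dot-normalisation and CPT
  matching is exact; no mapping from ICD-9 or local code systems is
  attempted.
* The package reads flat delimited extracts only — no FHIR, OMOP or
  warehouse connectivity, by design.
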