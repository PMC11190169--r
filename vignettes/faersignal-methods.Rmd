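---
title: "Methods: disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the model

A spontaneous-reporting database such as FAERS accumulates voluntarily
submitted case reports, each listing a patient's drugs (with role codes:
primary suspect PS, secondary suspect SS, concomitant C, interacting I),
the observed adverse events coded as MedDRA preferred terms (PT), serious
outcomes, and sparse demographics. There is no denominator of exposed
patients, so incidence cannot be estimated. Disproportionality analysis asks
a weaker but answerable question: within the database, is the pair
(drug, event) reported more often than expected if drug and event were
reported independently?

For one drug and one event term the reports cross-classify into a 2×2 table:
`a` = reports with drug and event, `b` = drug without event, `c` = event
without drug, `d` = neither, with `N = a+b+c+d` the database size. Four
estimators of the observed-to-expected disproportion are computed, each with
its conventional decision rule:

* **ROR** (reporting odds ratio) `ad/bc`, with the log-normal 95% interval
  `exp(ln ROR ± 1.96·se)`, `se = sqrt(1/a+1/b+1/c+1/d)`. Positive when the
  lower bound exceeds 1 and `a ≥ 3`.
* **PRR** (proportional reporting ratio) `[a/(a+b)]/[c/(c+d)]`, used with
  the Pearson chi-square of independence on the table,
  `(ad−bc)²·N / [(a+b)(a+c)(b+d)(c+d)]`, without Yates continuity
  correction, and its upper-tail p-value at one degree of freedom. Positive
  when `PRR ≥ 2`, `χ² ≥ 4`, `a ≥ 3` and `p < 0.05`.
* **BCPNN information component** `IC = log2[aN/((a+b)(a+c))]`, the
  log-scale observed-to-expected ratio. Its lower 95% credibility bound
  IC025 is taken from the closed-form Bayesian approximation of the BCPNN
  (Bate et al. 1998) with the standard priors
  (γ₁₁ = α₁ = β₁ = 1, α = β = 2): `IC025 = E(IC) − 2·sqrt(V(IC))`. Positive
  when `IC025 > 0`.
* **EBGM** here is the closed-form relative reporting ratio
  `aN/((a+b)(a+c))` — identically `2^IC` — with
  `EBGM05 = exp(ln EBGM − 1.96·se)`. Positive when `EBGM05 > 2`. This is
  *not* the full DuMouchel gamma-Poisson shrinkage (MGPS); no shrinkage is
  applied.

The `all_four` rule — the conjunction of the four criteria — is the
stringent screen; detected signals are ranked by EBGM05 descending (ties by
`a` descending, then event name). A signal is a statistical alert about
reporting behaviour, not a causal claim.

All inequalities are applied exactly as stated: `ror_low > 1` and
`ebgm_low > 2` and `ic_low > 0` are strict, `PRR ≥ 2`, `χ² ≥ 4` and `a ≥ 3`
are inclusive, `p < 0.05` is strict. The case-count screen always uses the
raw `a`.

## Parameters that matter

* **Role filter** (`roles`, default `"PS"`): exposure means the report lists
  the drug under one of these role codes. Primary-suspect-only is the usual
  convention for the study drug's own table and matches how the bundled
  reference tables were built (their exposed margin is the PS report count);
  widening to `c("PS","SS","C","I")` never shrinks the exposed margin.
* **Level** (`"pt"` or `"soc"`): at SOC level a report counts once per SOC if
  at least one of its PTs maps there (primary SOC only; secondary links in
  the map are stored but unused). PTs absent from the map go to a designated
  `UNMAPPED` SOC with a warning — mapping is total, so no event is silently
  dropped.
* **Minimum case count** (`min_case_filter()`, conventional `n_min = 3`,
  inclusive): below three co-occurrence reports the estimators are too
  unstable to interpret.
* **Comparator**: the background is always *all other reports in the store*
  (full-database comparator). No active-comparator mode is provided.
* **Event attribution** is report-level presence: if an exposed report lists
  the event, it contributes to `a` even when another drug is co-suspect, and
  only reaction PTs are counted (indication PTs are profiled separately,
  never counted as events).
* **Deduplication** keeps, per case identifier, the report with the greatest
  `(receipt_date, case_version, primaryid)` in lexicographic order — the
  usual "latest version wins" rule, made fully deterministic by the two
  tie-breaks. Both the deduplicated and the raw report counts are exposed
  (`n_reports(store)`, `n_reports(store, raw = TRUE)`) because database
  denominators are quoted under either convention.

## Numerical choices

* All statistics are computed in double precision; FAERS-scale cells
  (`d ≈ 1.9·10⁶`) overflow 32-bit integers in the cross products.
* The multiplier 1.96 is used literally in the CI formulas, matching the
  convention in which the reference tables were computed.
* p-values below 1e-300 are clamped to 0 for display (reference tables print
  `0.00E+00`).
* **Zero cells**: the Haldane–Anscombe correction (+0.5 to *all four* cells)
  is applied only when some cell is zero, and the table is flagged
  `corrected`. Tables with all cells positive are never perturbed. With the
  correction disabled, a zero cell is an explicit error rather than a silent
  `Inf`/`NaN`.
* `IC` and `log2(EBGM)` are one formula on two scales; the test suite asserts
  the identity to 1e-9 on a thousand random tables, and checks χ² against an
  independently coded expected-counts formulation `Σ(O−E)²/E` at 1e-9
  relative error.

## The bundled reference tables and their quirks

The package ships the published tirzepatide signal tables (46 PT rows, 8 SOC
rows; PS exposure, 2022Q2–2023Q3 window, N = 1,904,481) as plain-TSV
fixtures, with the printed statistics kept as strings so the printed
precision is known. Three findings from validating against them, all
reproduced by `test-acceptance.R`:

* ROR with both CI bounds, χ², IC, EBGM and EBGM05 are reproduced at printed
  precision for every row from the row's own `(a,b,c,d)` (the comparison
  allows the rounding direction of the last printed digit, since a handful
  of cells sit exactly on a half-way boundary).
* Many PT rows print a **PRR inconsistent with the PRR formula given their
  own counts** (e.g. the gastrooesophageal reflux row prints 2.97 where the
  formula gives 39.88, which is what the row's own ROR ≈ 40.3 corroborates
  for a rare event). The implementation follows the formula; only the five
  PT rows whose printed PRR is self-consistent, plus all SOC rows, are
  asserted against. One PT row ("Increased appetite") similarly prints a χ²
  about 0.9 away from the value implied by its own cells and is excluded
  from the χ² assertion.
* The printed **IC025 values do not correspond to the standard BCPNN
  closed-form bound** (nor to any simple variant we evaluated); the exact
  variance used by the source analysis is not recoverable from the printed
  values. IC025 therefore drives the decision rule but is validated against
  an independent evaluation of the closed form, not against the printed
  column. The IC *point* estimates do reproduce.

Because of the synthetic PT codes in the bundled MedDRA fixture (real codes
are licensed), real-data work should supply a genuine PT→SOC table through
`read_meddra_map()`.

## The synthetic generator

`sim_config()` + `simulate_reports()` emulate the *structure* of a quarterly
extract: Zipf-distributed drug and event vocabularies; a truncated-geometric
drug count per report (minimum 1, mean 2) with one drug flagged PS uniformly
at random; independent per-PT event occurrence (mean two PTs per report); a
rarely reported study drug (default marginal exposure 0.01); duplicate case
versions with probability 0.05; FAERS-like demographic missingness (60% of
ages unknown, 15% of sexes, mirroring the magnitude seen in real profiles);
serious-outcome codes at low rates dominated by hospitalization; and
reporting volume growing linearly across the 2022Q2–2023Q3 quarters.

A planted association multiplies one event's baseline per-report probability
by a rate ratio λ among reports exposed to the planted drug. When the event
and the exposure are rare, the population value of the relative reporting
ratio is essentially λ, so EBGM (and ROR) should recover it. The recovery
condition exercised in the acceptance suite uses n = 200,000 reports,
exposure 0.01 and baseline 0.005 at λ = 10: the expected co-occurrence count
is ≈100, whose binomial sampling error makes a 25% tolerance on EBGM a
comfortable but honest band. The null (no planted signals) false-positive
check runs twenty replicates of 50,000 reports and requires that at most 1%
of drug–event pairs with `a ≥ 3` pass the all-four rule; the observed rate
is far below the band because the four criteria are jointly stringent.
Duplicate versions are emitted with content identical to the original (only
`case_version` and `primaryid` change), which keeps deduplication exactly
commutative with window filtering and makes round-trip comparisons exact.

What the generator deliberately does **not** emulate — and hence what
passing tests do not show about real data: within-report event correlation
(real reactions co-occur in syndromes), drug–demographic confounding,
calibration to real FAERS marginal frequencies, temporal reporting trends
(beyond linear growth), stimulated-reporting artefacts, and duplicates whose
content differs between versions. Estimator behaviour under those features
must be judged on real extracts.

## Problem sizes and determinism

The test suite and the acceptance script use n = 200,000 reports for the
recovery check, 20 × 50,000 for the null screen, and 5,000 for the
serialization round trip — sizes at which the Monte-Carlo bands above are
meaningful while a full run stays in the low minutes on one CPU. Every
stochastic step is driven by a single integer seed (the acceptance script's
`--seed` flag); the simulator is deterministic given its configuration.

## Limitations

* The EBGM column is the closed-form relative reporting ratio, not MGPS
  shrinkage; for very small `a` it is more volatile than a shrunk estimate
  (the `a ≥ 3` screen and EBGM05 bound are the guard rails).
* No multiple-comparison adjustment is applied across event terms, matching
  standard pharmacovigilance screening practice; the output is a ranked
  shortlist for clinical review, not a family of confirmatory tests.
* No stratified (age/sex/quarter) tables; the comparator is the whole
  database window.
* Ingestion covers the `$`-delimited quarterly dialect only (no E2B XML),
  and drug normalization is a plain synonym dictionary, not a full
  vocabulary service.
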