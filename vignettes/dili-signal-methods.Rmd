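---
title: "Methods: disproportionality signal detection and receptor-affinity correlation for drug-induced liver injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and receptor-affinity correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilisignal)
library(dplyr)
```

## The problem

Drug-induced liver injury (DILI) is rare, idiosyncratic, and hard to study
prospectively, which makes large spontaneous-reporting databases (such as
FAERS) the practical substrate for hypothesis generation. `dilisignal`
implements a pharmacoepidemiologic–pharmacodynamic workflow for
antipsychotics and hepatotoxicity: it detects signals of disproportionate
reporting for a liver-injury term set in case/non-case fashion, computes
receptor binding (pKi) and receptor occupancy quantities from *in vitro*
pharmacology, and correlates the drug-level reporting odds ratios with
those pharmacodynamic and physicochemical predictors.

Because real FAERS extracts cannot be bundled (and the MedDRA SMQ term
lists are licensed), the package ships a calibrated synthetic generator of
individual case safety reports with *known* ground-truth reporting odds.
Every stage of the pipeline is therefore testable end to end against a
known truth, which is how the test suite and the acceptance script
validate the statistics.

## Case/non-case disproportionality

A *case* is a report whose reaction set contains at least one term of the
hepatic term set; *non-cases* are all other reports in the database. For a
drug $D$, exposure means a primary- or secondary-suspect role;
concomitant and interacting rows are excluded from exposure (but their
reaction information still counts toward the case definition, since the
case, not the drug row, carries the clinical event). The 2×2 table per
drug and stratum is

|            | event          | no event |
|------------|----------------|----------|
| exposed    | $a$            | $b$      |
| unexposed  | $c$            | $d$      |

with the comparator being *all other drugs* — other antipsychotics
included.

**Reporting odds ratio.** $\mathrm{ROR} = ad/bc$ with the 95% Wald
interval $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$.
Being symmetric on the log scale, the point estimate equals the geometric
mean of its bounds — a structural identity the acceptance checks exploit
to verify published values. With any zero cell the ROR is reported as
undefined; an optional Haldane–Anscombe correction (+0.5 to every cell of
an affected table) exists behind a flag but is off by default, because a
signal decided by a corrected zero-cell table would deserve explicit
scrutiny rather than silent inclusion.

**Information component.** The IC is the shrunken log2 observed-to-
expected ratio with $O = a$, $E = (a+b)(a+c)/N$:

$$\mathrm{IC} = \log_2 \frac{O + 0.5}{E + 0.5},$$

with closed-form 95% credibility bounds
$\mathrm{IC}_{025} = \mathrm{IC} - 3.3(O+0.5)^{-1/2} - 2.41(O+0.5)^{-1}$
and
$\mathrm{IC}_{975} = \mathrm{IC} + 2.4(O+0.5)^{-1/2} - 0.5(O+0.5)^{-1}$.
These are the standard closed-form approximations to the credibility
interval of the shrunken observed-to-expected ratio; they remain defined
at $O = 0$. The +0.5 terms pull small-count estimates toward zero, which
the test suite asserts as $|\mathrm{IC}| \le |\log_2 O/E|$. $E$ is always
computed within the stratum under analysis, so each subgroup is a
self-contained case/non-case design.

**Dual signal criterion.** A drug signals when
$\mathrm{ROR}_{\text{low}} > 1$ *and* $\mathrm{IC}_{025} > 0$ with at
least 3 exposed cases. Rows below the minimum case count are retained but
marked non-reportable (rendered as NA in display tables). The dual
criterion is deliberately conservative; under a null simulation its
drug-level false-positive rate is far below the 5% that either component
alone would nominally allow.

## Preprocessing decisions

* **Deduplication.** Exact duplicate rows (same case id, drug, role,
  reaction, sex, age) collapse to one. A case id whose rows disagree on
  sex or age cannot be uniquely identified and is dropped entirely, with
  the count logged. A missing age on one row versus a recorded age on
  another counts as a disagreement. Near-duplicates under *different*
  case ids are left alone: collapsing them would require a record-linkage
  model that the case/non-case design does not depend on.
* **Strata.** `total`, `female`, `male`, `age_ge_65`. Sex-unknown cases
  stay in `total` but in neither sex stratum; the elderly stratum requires
  a non-missing age with the boundary included (age ≥ 65).
* **Term matching** is case-insensitive after whitespace normalisation.
  No MedDRA hierarchy traversal is attempted: the term set is a flat list,
  and the bundled hepatic list is a synthetic stand-in, not the licensed
  SMQ.

## Receptor pharmacology

Ten receptor classes are modelled: D2, D3, 5-HT1A, 5-HT2A, 5-HT2C,
5-HT7, H1, alpha-1, alpha-2 (subtype-agnostic), and cholinergic
(subtype-agnostic). Where several sources report a Ki for the same
drug–receptor pair the **median** is used (mean of the central pair for
even counts). Binding affinity is expressed as
$\mathrm{pKi} = 9 - \log_{10}(K_i\,[\mathrm{nM}])$, i.e. $-\log_{10}$ of
Ki in molar.

Receptor occupancy follows occupancy theory:

$$\mathrm{CU} = \frac{1000 \cdot \mathrm{FU} \cdot \mathrm{CT}}{\mathrm{MW}},
\qquad
\mathrm{Occ}(\%) = 100\,\frac{\mathrm{CU}}{K_i + \mathrm{CU}},$$

where FU is the unbound fraction, CT the total blood concentration in
ng/mL taken as the *upper limit of the therapeutic reference range*, MW
the molecular weight in g/mol, and CU the unbound concentration in nM.
Occupancy is 50% at CU = Ki, increases in CU, decreases in Ki, and stays
in [0, 100). The occupancy analysis uses the same median Ki as the pKi
analysis, keeping the two predictor families consistent. Partial agonists
are treated identically to antagonists — affinity only, no efficacy
weighting. Missing FU or CT leaves occupancy missing; nothing is imputed.

The pharmacology matrix has one row per drug and 23 predictor columns:
10 pKi, 10 occupancy, molecular weight, LogP, and FDA approval year.

## The correlation battery

For each stratum (`total`, `female`, `male` by default) and each
predictor, the drug-level ROR is correlated with the predictor by Pearson
correlation; significance uses the two-sided t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom at an
uncorrected $p < 0.05$. Design choices worth stating explicitly:

* **The ROR itself, not log ROR, is the correlated outcome.** This
  matches how such drug-level analyses are conventionally reported; an
  optional `outcome = "log_ror"` mode exists but is off by default.
* **Pairwise-complete deletion** per predictor: a drug missing a Ki for
  one receptor still contributes to every other predictor. With all 19
  drugs present the battery reports $r(17)$, i.e. df = 17.
* **No multiplicity correction** is applied, consistent with a
  hypothesis-generating analysis; `significant` is a flag, not a claim.
* The elderly stratum is excluded from the battery by default: with few
  exposed elderly cases, many drugs fall under the 3-case rule and the
  drug-level correlation would not be comparably powered. It can be
  enabled through `strata`.
* Drugs whose ROR is undefined (zero cell) or non-reportable (< 3 cases)
  are dropped from that stratum's battery.

Scatter exports pair each drug's predictor value with its ROR and attach
the least-squares line and a pointwise 95% confidence band;
`autoplot()` renders the conventional figure (red regression line, grey
band).

## The synthetic report generator

`simulate_reports()` emulates a FAERS-like table restricted to an
antipsychotic study set. Its defaults *are* the study conditions the rest
of the package is tested under:

* ~3% of cases carry a hepatic event at baseline, matching the
  event-background share of a large adverse-event database restricted to
  a liver-injury query (about 365k of 12.3M reports).
* 19 study drugs with true reporting odds spanning 0.2–3.5 and one drug
  (risperidone) elevated only in women, so the stratified analysis has a
  sex-specific signal to recover.
* Exposure probabilities between 0.001 and 0.025 reflecting prescribing
  frequency; each case additionally carries one comparator drug from a
  background pool so non-cases are populated.
* Sexes ~47.5/47.5/5 (female/male/unknown); ages from a two-component
  mixture putting ~20% of cases at 65+, with 8% of ages missing.
* 5% of cases are submitted twice verbatim (same case id) — the
  deduplication stage's unambiguous ground truth; 20% of exposed
  study-drug rows carry the concomitant role and never multiply the event
  odds, so the suspect-role filter has a measurable effect.

The generative model is case-level logistic odds: a case's event odds are
the background odds times the theta of every suspect-role exposure in the
case's stratum. This is the simplest model whose true ROR equals the
configured theta under rare exposure, which the tests verify by Monte
Carlo (a theta of 3 is recovered within [2.5, 3.5] in ≥95% of seeds at
200,000 cases). The RNG is R's Mersenne-Twister, recorded in the output's
`rng_kind` attribute; determinism is promised within this implementation,
not across languages.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: reporting dynamics over time,
drug–drug interaction effects on the event odds, near-duplicates with
different case ids, free-text drug-name noise (inputs are assumed
normalised), and age given in units other than years.

## Numerical and engineering choices

* z = 1.96 fixed for the 95% Wald interval; no continuity correction
  except the optional zero-cell rule.
* Exact-fit correlations (|r| = 1) report p = 0 by convention; fewer than
  3 complete pairs or zero variance yield an undefined result with a
  reason, and the battery continues past them.
* Full precision is kept in all stored outputs; display rounding (2
  decimals, as signal tables are conventionally printed) happens only in
  `tidy(x, digits = )` and the rendered report table.
* The pipeline writes a manifest with row counts at every filter step
  (input rows, post-dedup, suspect-role rows, per-stratum N) so the
  denominators behind every table are auditable, and re-running with the
  same inputs is byte-identical.

## Problem sizes used by the tests and the acceptance script

Monte-Carlo checks run at 200,000 cases per seed (100 seeds in the test
suite, 30 in the acceptance script) for parameter recovery; the null
calibration uses 20 seeds × 50,000 cases in the suite and 10 in the
script; Wald coverage uses 600 simulated tables; the end-to-end
affinity-gradient recovery uses 19 drugs × 60,000 cases. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances while
keeping a full run on a single CPU in the minutes range.

## Limitations

Disproportionality is not risk: the ROR orders reporting, not incidence,
and no causal reading is intended. The correlation battery is
hypothesis-generating by design (uncorrected, drug-level, n = 19). The
bundled pharmacology tables are synthetic stand-ins for licensed or
curated sources and are suitable for demonstrating and testing the
machinery, not for substantive inference about the drugs named.
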