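# dilisignal

Pharmacoepidemiologic–pharmacodynamic analysis of drug-induced liver
injury (DILI) in spontaneous adverse-event reporting data, built for the
antipsychotic use case but applicable to any drug set with a reaction
term list and a receptor pharmacology table.

Drug-induced liver injury is rare and idiosyncratic, so large
spontaneous-reporting databases (FAERS-style) are the practical way to
generate hypotheses about which drugs — and which pharmacodynamic
properties — carry hepatotoxic risk. `dilisignal` provides the full
workflow for researchers in pharmacovigilance and clinical pharmacology:

* **Case/non-case disproportionality.** For each drug and stratum
  (total, female, male, age ≥ 65) the 2×2 table of hepatic-event cases
  versus all other reports, with exposure restricted to primary/secondary
  suspect roles; the reporting odds ratio ROR = ad/bc with its 95% Wald
  interval exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); the shrinkage
  information component IC = log2((O+0.5)/(E+0.5)), E = (a+b)(a+c)/N,
  with closed-form 95% credibility bounds; and the dual signal criterion
  (lower ROR bound > 1 **and** IC025 > 0, with ≥ 3 cases).
* **Receptor pharmacology.** pKi = 9 − log10(Ki in nM) with median
  aggregation over sources, and receptor occupancy
  Occ(%) = 100·CU/(Ki + CU) with CU = 1000·FU·CT/MW, over ten receptor
  classes (D2, D3, 5-HT1A, 5-HT2A, 5-HT2C, 5-HT7, H1, alpha-1, alpha-2,
  cholinergic).
* **Correlation battery.** Drug-level Pearson correlation of the ROR
  against each pKi, occupancy, molecular weight, LogP, and approval year,
  with the two-sided t-test t = r·√((n−2)/(1−r²)), uncorrected p < 0.05,
  per stratum — plus scatter exports with OLS line and 95% confidence
  band, and `autoplot()` figures.
* **A calibrated synthetic FAERS generator** with known ground-truth
  reporting odds (duplicate submissions, suspect vs. concomitant roles,
  sex/age strata, a configurable background event rate near 3%), so the
  whole pipeline is testable without access to FAERS or licensed MedDRA
  term lists.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted result objects support broom-style
`tidy()`/`glance()` and ggplot2 `autoplot()`.

## Worked example

Simulate a 50,000-case study under the default conditions (19
antipsychotics, ~3% background hepatic-event rate, true reporting odds
spanning 0.2–3.5), run the disproportionality analysis, and correlate the
resulting RORs with the bundled *synthetic* pharmacology tables:

```r
library(dilisignal)
library(dplyr)

rpt <- simulate_reports(sim_config(n_cases = 50000, seed = 2024))
cv  <- build_case_views(deduplicate(rpt), smq_termset(hepatic_smq_example()))
res <- run_disproportionality(cv, drugs = names(default_drug_exposure()))
glance(res)
#> # A tibble: 1 × 5
#>   n_drugs n_strata n_reported n_signals n_cases_total
#>     <int>    <int>      <int>     <int>         <int>
#> 1      19        4         29         4         50000

tidy(res, digits = 2) |>
  filter(stratum == "total", is_signal) |>
  select(drug, n_cases, ror, ror_low, ror_high, ic, ic025)
#> # A tibble: 2 × 7
#>   drug       n_cases   ror ror_low ror_high    ic ic025
#>   <chr>        <int> <dbl>   <dbl>    <dbl> <dbl> <dbl>
#> 1 loxapine         8  3.55    1.71     7.37  1.53  0.12
#> 2 olanzapine      54  2.34    1.76     3.09  1.12  0.63
```

At this sample size only the strongest generating odds (loxapine 2.74,
olanzapine 1.76 by construction) clear the conservative dual criterion in
the total stratum; the estimates bracket their generating values and the
remaining drugs stay below the signal threshold. The correlation battery
then links the RORs to the pharmacology matrix:

```r
pharm <- build_pharm_matrix(
  read_ki_table(system.file("extdata", "ki_synthetic.tsv",
                            package = "dilisignal")),
  read_drug_properties(system.file("extdata",
                                   "drug_properties_synthetic.tsv",
                                   package = "dilisignal")))
bat <- run_battery(res, pharm)
glance(bat)
#> # A tibble: 1 × 5
#>   n_tests n_computable n_significant alpha outcome
#>     <int>        <int>         <int> <dbl> <chr>  
#> 1      69           69             9  0.05 ror
```

Each battery row reports the predictor, stratum, number of drugs with
both values present, df = n − 2, Pearson r, t, and the uncorrected
two-sided p. (The bundled Ki table is random synthetic data, so its
"significant" rows are the expected multiplicity noise — the vignette
discusses why no correction is applied.) `export_scatter()` +
`autoplot()` draw the conventional affinity-vs-ROR figure with a red
regression line and grey 95% band.

An end-to-end orchestration — read report/term/pharmacology files, run
every stage, write tables, scatters and an auditable run manifest — is
available through `pipeline_config()` + `run_pipeline()`.

## Data notes

Everything under `inst/extdata/` is synthetic: the hepatic term list is a
placeholder for the licensed MedDRA SMQ, and the Ki/property tables are
generated stand-ins with realistic magnitudes. They exist so examples and
tests run self-contained; substantive analyses must supply real inputs
via `read_smq()`, `read_ki_table()`, `read_drug_properties()` and
`read_reports()`.
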