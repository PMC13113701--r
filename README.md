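# stewardpair

Paired antimicrobial-stewardship benchmarking of empiric antibiotic regimens.

## The problem

Antimicrobial stewardship programs target a small set of high-leverage empiric
decisions — starting a carbapenem, an antipseudomonal β-lactam, or an
anti-MRSA agent in the first 24 h of admission — because these choices
disproportionately drive resistance selection pressure. When a counterfactual
recommender (for example an offline, shadow-mode decision-support model)
proposes an empiric regimen for the *same* admission the clinician treated,
the natural evaluation is a paired process benchmark: does each arm's regimen
cross a prespecified escalation guardrail without a structured justification,
and how do the two arms differ within admissions?

`stewardpair` implements that benchmark end to end for analysts working on
stewardship evaluations:

* **Contextual guardrails.** A component violation is class use without a
  justification proxy. Severity proxy `SEVERE` = any of {ICU admission/transfer,
  septic shock, vasopressors, mechanical ventilation, respiratory failure};
  MDR-risk proxy `MDR_RISK` = any of {prior ESBL/CRE/VRE, antibiotics or
  hospitalization in the prior 90 days, long-term-care residence,
  healthcare-associated acquisition}; anti-MRSA use is justified by documented
  prior MRSA colonization. The weighted penalty is

  Penalty = 2·I_carb + 1·I_APS + 1·I_MRSA

  and the paired delta is ΔPenalty = Penalty(recommendation) −
  Penalty(clinician); negative values favour the recommendation arm.

* **Paired statistics.** Exact McNemar test (two-sided, doubled smaller
  binomial tail), matched odds ratio from discordant counts with 0.5
  continuity correction, OR = (n01+0.5)/(n10+0.5), with Wald 95% CI on the
  log scale; paired risk difference; exact sign test on non-tied pairs;
  Wilcoxon signed-rank (zeros dropped, midranks, exact by sign-flip
  enumeration up to n = 25); seeded percentile bootstrap CI for the median
  (n_boot = 5000, seed = 7); Holm step-down adjustment over the prespecified
  six-member paired-delta family.

* **Secondary process endpoints.** Broad-spectrum exposure composite,
  per-component violation endpoints, acquisition-cost deltas at 24 h and in
  the 72 h continued-therapy subset, ΔDDD/24 h (WHO ATC/DDD style), AWaRe
  mean/max score deltas (ACCESS = 1, WATCH = 2, RESERVE = 3),
  microbiology-evaluable coverage, regimen concordance, and a NO_ANTIBIOTIC
  quality-control report.

* **Synthetic data.** A stochastic paired-cohort generator (documented
  baseline prevalences, configurable arm discordance) and a deterministic
  493-admission fixture whose computed endpoints reproduce a complete
  published set of paired 2×2 tables, used as the package's acceptance
  harness.

## Worked example

```r
library(stewardpair)
cohort <- table2_fixture()      # deterministic 493-admission benchmark cohort
bundle <- run_all(cohort)       # full endpoint battery
print(bundle)
```

prints (abridged):

```
stewardpair results bundle (N = 493 admissions)
  primary_any_violation        N=493  OR 0.216 (0.127-0.367) RD -0.122  p=1.6e-10
  delta_penalty                N=493  median 0 (IQR 0-0)  -/0/+: 79/398/16  pW=4.55e-09 pS=3.47e-11
  carbapenem_violation         N=493  OR 0.178 (0.077-0.410) RD -0.061  p=2.83e-06
  antipseudomonal_violation    N=493  OR 0.049 (0.010-0.253) RD -0.059  p=2.98e-08
  anti_mrsa_violation          N=493  OR 0.415 (0.220-0.784) RD -0.039  p=0.00661
  broad_spectrum_any           N=493  OR 0.345 (0.250-0.477) RD -0.191  p=7.26e-12
  coverage_micro_evaluable     N=158  OR 2.238 (1.081-4.633) RD +0.082  p=0.0351
```

Reading the first line: guardrail violations occurred in 17.0% of clinician
regimens versus 4.9% of recommendation regimens; the matched OR of 0.216
(discordant pairs 76 clinician-only vs 16 recommendation-only) with exact
McNemar p = 1.6e-10 says the recommendation arm crossed the guardrails far
less often within the same admissions. ΔPenalty was tied in 398/493
admissions and favoured the recommendation arm in 79 of the 95 non-ties. The
coverage line is the one endpoint pointing the other way-up: among the 158
microbiology-evaluable admissions, the recommendation arm more often provided
in-vitro active coverage (matched OR 2.24).

## Command line

```sh
inst/cli/stewardpair simulate --fixture --out cohort.csv
inst/cli/stewardpair simulate --n 500 --seed 11 --out sim.csv
inst/cli/stewardpair analyze --cohort cohort.csv --out results/
inst/cli/stewardpair report --bundle results/results.json
```

Exit statuses: 0 success, 2 validation error, 3 I/O error, 4 catalog-QC
failure (an unmapped agent aborts the analysis and writes
`qc_unmapped_agents.csv`).

## Data formats

* Agent catalog: CSV/TSV with columns `code, display_name, is_carbapenem,
  is_antipseudomonal, is_anti_mrsa, aware_class, ddd_ref_g, unit_cost_eur`
  (booleans 0/1). The shipped catalog covers ~28 common inpatient agents;
  unit costs are a synthetic price list and every mapping is overridable.
* Cohort: CSV with one row per admission (regimens as semicolon-delimited
  `CODE@dose_g` tokens, booleans 0/1, blanks = absent = FALSE) or nested
  JSON. See `?read_cohort`.

See `vignettes/stewardship-benchmarking.Rmd` for the model, assumptions,
numerical conventions and limitations.
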