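---
title: "Paired stewardship benchmarking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired stewardship benchmarking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stewardpair)
```

## The model

`stewardpair` evaluates paired empiric antibiotic regimens — the clinician's
actual first-24 h order set and a counterfactual recommendation for the same
admission — against a rule-based stewardship construct. The unit of analysis
is the admission; the paired design removes confounding by admission-level
case mix, since each admission is its own control.

Three broad-spectrum escalation decisions are audited as *contextual
guardrail components*: carbapenem use, antipseudomonal β-lactam use, and
anti-MRSA agent use. A component is **violated** when the class appears in
the regimen and its justification rule evaluates false on the structured
admission context:

* carbapenem justified iff `SEVERE | MDR_RISK`
* antipseudomonal justified iff `SEVERE | MDR_RISK`
* anti-MRSA justified iff `PRIOR_MRSA` (documented prior colonization)

`SEVERE` is the disjunction of five early severity/support indicators (ICU
admission/transfer, septic shock, vasopressors, mechanical ventilation,
respiratory failure documented within 24 h); `MDR_RISK` is the disjunction of
five history/setting variables (prior ESBL/CRE/VRE, antibiotics in the prior
90 days, hospitalization in the prior 90 days, long-term-care residence,
healthcare-associated acquisition). The weighted penalty is

$$\mathrm{Penalty} = \sum_k w_k I_k = 2\,I_{\mathrm{carb}} +
1\,I_{\mathrm{APS}} + 1\,I_{\mathrm{MRSA}},$$

an ordinal hierarchy of unjustified spectrum expansion, not a utility scale.
The primary paired endpoint is the any-violation indicator; the key secondary
endpoint is $\Delta$Penalty (recommendation − clinician, negative favouring
the recommendation arm).

Justification rules are configurable Boolean expressions over the fixed proxy
vocabulary `{SEVERE, MDR_RISK, PRIOR_MRSA}` because the exact institutional
rule set of any given deployment (e.g. additional class-specific
microbiological proxies) varies; the defaults above are the package's
prespecified construct. Two related conventions are fixed deliberately:

* **Carbapenems do not co-trigger the antipseudomonal component.** Although
  carbapenems are pharmacologically antipseudomonal, the three components are
  separate indicators with separate discordant counts; double-flagging would
  conflate them. The catalog validator enforces disjoint flags (overridable
  per catalog for sensitivity analyses).
* **`sepsis_documented` is carried as a covariate but is not part of
  `SEVERE`**, which is defined by the five specific indicators listed above.
  A user who wants it in the rule can reference a custom catalog of flags via
  the configurable rules.

**Missing-as-absent.** Absent or blank context fields are read as FALSE —
the absence of documentation is treated as the absence of the condition, the
standard constraint of retrospective prescribing data. Substitutions are
counted per field at ingestion and reported in the analysis log.

## Paired inference

All tests are two-sided.

* **Exact McNemar**: with discordant counts $d = n_{01}+n_{10}$ and
  $k = \min(n_{01}, n_{10})$, $p = \min(1, 2\,P[X \le k])$,
  $X \sim \mathrm{Bin}(d, 1/2)$; $p = 1$ when $d = 0$. The doubled-smaller-
  tail convention is used (rather than mid-p or a chi-square approximation)
  because it is exact, conservative, and reproduces published results from
  printed discordant counts.
* **Matched OR**: $(n_{01}+0.5)/(n_{10}+0.5)$ with Wald 95% CI on the log
  scale, SE $=\sqrt{1/(n_{01}+0.5)+1/(n_{10}+0.5)}$. The continuity
  correction keeps zero-discordant tables finite. The paired risk difference
  is the recommendation-arm event rate minus the clinician rate.
* **Sign test**: exact binomial on non-tied pairs — appropriate when ties
  dominate, as they do for integer penalty deltas.
* **Wilcoxon signed-rank**: zeros dropped (Wilcoxon's original handling,
  chosen over Pratt's as the most common library default), midranks for tied
  magnitudes. For ≤ 25 non-zero deltas the exact two-sided p is computed by
  full sign-flip enumeration via dynamic programming on doubled ranks
  (doubling keeps midranks integral); beyond that, a normal approximation
  with tie-corrected variance and continuity correction. Two-sidedness is
  defined by $|W - \mu| \ge |w_{\mathrm{obs}} - \mu|$, which coincides with
  the doubled-tail definition under the symmetric null.
* **Bootstrap median CI**: percentile method, resampling admissions with
  replacement, defaults n_boot = 5000 and seed = 7. The percentile method is
  the simplest method consistent with degenerate tie-dominated deltas (a
  median CI of exactly 0–0). One seeded generator draws n indices per
  replicate, replicates in order, so the interval is bit-reproducible for a
  given input order; the caller's RNG state is saved and restored.
* **Holm step-down** over the prespecified paired-delta family (m = 6, fixed
  order: penalty, cost 24 h, cost 72 h, AWaRe mean, AWaRe max, DDD/24 h),
  applied to each endpoint's Wilcoxon p — the headline paired-delta test,
  with the sign test reported as sensitivity.

Numbers are stored at full precision; display rounding (OR/RD to 3 decimals,
p to 3 significant figures) happens only in the summary CSV and reports.

## Secondary endpoint conventions

* **Costs** are drug-acquisition only: flat per-day catalog price (EUR per
  day at DDD) × window length — 1 day for the 24 h window, 3 days for the
  72 h window. The 72 h endpoint is computed only within the
  continued-therapy subset (clinician therapy continued ≥ 3 days) and prices
  both arms over 3 flat days; proration of discontinued agents is not
  attempted because discontinuation timing is not part of the data model. The
  shipped unit costs are a **synthetic price list** (real tariffs are
  institution-specific); all cost results flow entirely from the catalog, so
  a richer mapping is a data change, not a code change.
* **DDD/24 h** is $\sum_{\text{agents}} \text{dose}_g / \text{DDD}_g$, WHO
  ATC/DDD style. Shipped DDD references use the parenteral route where that
  is the typical inpatient form.
* **AWaRe scores** map ACCESS/WATCH/RESERVE to 1/2/3 (monotone in
  stewardship priority; the mapping is an argument). A regimen is summarised
  by the mean and max of its agent scores. An empty regimen contributes 0 to
  AWaRe scores, cost and DDD — a logged convention, since "no antibiotic" has
  no natural place on the AWaRe scale.
* **Coverage** flags are inputs, not computed: susceptibility adjudication
  (S/I/R handling, syndrome linkage) cannot be reconstructed from the data
  model, so evaluable admissions carry recorded 0/1 coverage per arm, and the
  endpoint is simply the paired binary on those flags over the evaluable
  subset, with the non-evaluable count reported. Zero evaluable admissions
  mark the endpoint non-computable rather than failing the run.
* **Concordance**: "primary agent" is the first-listed agent of each regimen
  (the natural reading of an ordered order-set; regimen order is preserved in
  the file formats even though violation logic is order-free). Identical
  sets compare unordered unique code sets.

## Synthetic data: what it emulates and what it does not

`generate_cohort()` draws context flags **independently** at documented
baseline prevalences (e.g. respiratory failure 0.759, ICU 0.286,
vasopressors 0.258, LTCF 0.065, prior MRSA colonization 0.012), then draws
each arm's class use conditional on the justification proxies, with the
recommendation arm configured to escalate rarely without a trigger. Because
the documented severity burden makes `SEVERE ∨ MDR_RISK` very common
(≈ 93%), unjustified use — and hence violations — is rare under independence
defaults; the generator is a structural emulator for property tests and power
exploration, not a re-creation of any observed violation rates. Features of
real data it does not model: correlation among severity flags (a shared
latent severity would raise the variance of proxy counts), syndrome-specific
prescribing, dose rounding to vial sizes, and within-year drift.

The deterministic `table2_fixture()` carries the published numbers instead.
It is built by constraint assignment from *minimal witnesses* — e.g. a
violation is encoded as "carbapenem with all proxies false" — so that the
computed endpoints reproduce, exactly, a complete published set of paired
tables: the primary 2×2 (393, 16, 76, 8), component discordants (36, 6),
(30, 1), (32, 13), the broad-spectrum table (discordants 143/49, totals
289/195), the coverage subset (38, 23, 10, 87) over 158 evaluable, the
concordance counts 57/137/148/345, and five empty recommendation regimens
with all proxies false. The penalty-delta magnitudes are under-determined by
the published sign counts (79/16/398) and moments (mean −0.219, SD 0.789);
the fixture pins one consistent multiset — negatives 4×(−4), 5×(−3),
33×(−2), 37×(−1); positives 3×(+3), 4×(+2), 9×(+1), giving
$\sum d = -108$ and $\sum d^2 = 330$ — realised by explicit per-admission
violation profiles that simultaneously satisfy every component table. A
green fixture test therefore establishes that the full pipeline computes the
published statistics from the published structure; it does not establish
anything about unpublished case-level quantities (Wilcoxon p-values for the
penalty delta, cost medians, cohort cost totals), which depend on magnitudes
and prices the fixture cannot know. Those code paths are covered by
independent-oracle and property tests instead.

## Simulation recovery designs

`recovery_experiment()` draws paired violation statuses from explicit cell
probabilities, materialises them as witness cohorts, and runs the real
primary-endpoint pipeline each replicate.

* **Null design** (type-I error): discordance probability 0.10 per direction.
  Chosen a priori from the attained-size analysis of the exact test: the
  doubled-tail binomial is conservative, and at expected discordant counts
  around 99 its attained size is ≈ 4–4.5%, comfortably inside a ±2-point
  band around the nominal 5% without being so small-d conservative that the
  band is missed.
* **Coverage design**: cell probabilities (0.88, 0.02, 0.08, 0.02), i.e.
  generating discordance odds 0.25 — near the observed primary effect — at
  which the log-scale Wald interval's coverage is close to nominal.

## Known limitations

* The guardrail construct is a benchmarking rule set, not a validated
  appropriateness score; results quantify concordance with the rules.
* The exact Boolean logic of any institution's appendix-level rule set may
  extend the three-proxy vocabulary; such rules need code-level extension of
  the vocabulary, though any Boolean combination of the three proxies is a
  configuration change.
* Costs are acquisition-only, flat per-day, synthetic by default.
* The generator's independence assumption understates the clustering of
  severity documentation in real admissions.
* The Wilcoxon zero/tie policy (zeros dropped) and the bootstrap interval
  method (percentile) are pinned conventions; alternatives (Pratt, BCa) are
  deliberately out of scope.
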