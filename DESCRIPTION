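Package: stewardpair
Title: Paired Antimicrobial Stewardship Benchmarking of Empiric Antibiotic Regimens
Version: 0.1.0
Authors@R: person("stewardpair", "maintainers", email = "maintainers@stewardpair.org", role = c("aut", "cre"))
Description: Rule-based contextual guardrail scoring of paired empiric antibiotic
    regimens (clinician versus counterfactual recommendation for the same
    admission) and the complete prespecified paired-endpoint statistics battery:
    exact McNemar test, matched odds ratio with continuity correction, sign test,
    Wilcoxon signed-rank, seeded bootstrap confidence intervals for the median,
    and Holm step-down multiplicity adjustment. Includes an antibiotic agent
    catalog (class flags, WHO AWaRe class, DDD references, unit costs), a
    synthetic paired-cohort generator, a deterministic benchmarking fixture, and
    a command-line pipeline (simulate, analyze, report).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
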