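# Shared vocabulary constants (loaded first; other files reference these at
# top level).

AWARE_LEVELS <- c("ACCESS", "WATCH", "RESERVE")

CATALOG_COLUMNS <- c(
  "code", "display_name", "is_carbapenem", "is_antipseudomonal",
  "is_anti_mrsa", "aware_class", "ddd_ref_g", "unit_cost_eur"
)

SEVERE_FIELDS <- c("icu_24h", "septic_shock", "vasopressors",
                   "mechanical_ventilation", "respiratory_failure")

MDR_FIELDS <- c("prior_esbl_cre_vre", "abx_prior_90d", "hosp_prior_90d",
                "ltcf_resident", "healthcare_associated")

CONTEXT_FLAGS <- c(SEVERE_FIELDS, MDR_FIELDS,
                   "prior_mrsa_colonization", "sepsis_documented")

GUARDRAIL_COMPONENTS <- c("carb", "aps", "mrsa")

# Fixed proxy vocabulary the justification rules may reference.
RULE_VOCAB <- c("SEVERE", "MDR_RISK", "PRIOR_MRSA")
RULE_ALLOWED_NAMES <- c(RULE_VOCAB, "(", "&", "|", "!", "&&", "||", "xor")
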