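# Shared builders: in-code catalogs and minimal cohorts.

catalog_header <- paste("code,display_name,is_carbapenem,is_antipseudomonal",
                        "is_anti_mrsa,aware_class,ddd_ref_g,unit_cost_eur",
                        sep = ",")

write_catalog_file <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(catalog_header, rows), path)
  path
}

# Six-agent catalog covering all three class flags plus narrow agents.
tiny_catalog <- function() {
  load_catalog(write_catalog_file(c(
    "MEROPENEM,Meropenem,1,0,0,WATCH,3,24",
    "PIPTAZ,Piperacillin/tazobactam,0,1,0,WATCH,14,15",
    "VANCO,Vancomycin,0,0,1,WATCH,2,12",
    "CEFTRIAXONE,Ceftriaxone,0,0,0,WATCH,2,2.5",
    "AMOXI,Amoxicillin,0,0,0,ACCESS,1.5,1.5",
    "DOXY,Doxycycline,0,0,0,ACCESS,0.1,0.8"
  )), version_tag = "tiny")
}

# Admission context: all flags FALSE unless overridden.
make_ctx <- function(...) {
  ctx <- as.list(setNames(rep(FALSE, length(stewardpair:::CONTEXT_FLAGS)),
                          stewardpair:::CONTEXT_FLAGS))
  over <- list(...)
  ctx[names(over)] <- over
  ctx
}

# Cohort from parallel lists of regimens (+ optional per-admission context
# overrides as a list of named lists).
make_cohort <- function(clin, llm, ctx_overrides = NULL,
                        continued_72h = TRUE, micro_evaluable = FALSE,
                        clin_covered = NA_integer_,
                        llm_covered = NA_integer_) {
  n <- length(clin)
  df <- data.frame(admission_id = sprintf("T%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (fl in stewardpair:::CONTEXT_FLAGS) df[[fl]] <- FALSE
  if (!is.null(ctx_overrides)) {
    for (i in seq_along(ctx_overrides)) {
      for (nm in names(ctx_overrides[[i]])) {
        df[[nm]][i] <- ctx_overrides[[i]][[nm]]
      }
    }
  }
  df$continued_72h <- rep_len(continued_72h, n)
  df$micro_evaluable <- rep_len(micro_evaluable, n)
  df$clin_covered <- rep_len(clin_covered, n)
  df$llm_covered <- rep_len(llm_covered, n)
  df$clin_regimen <- clin
  df$llm_regimen <- llm
  steward_cohort(df)
}

# Independent two-sided exact binomial oracle: doubled smaller tail from
# binomial coefficients (no pbinom).
binom_two_sided_oracle <- function(k, d) {
  if (d == 0L) return(1)
  tail <- sum(choose(d, 0:k)) / 2^d
  min(1, 2 * tail)
}

# Brute-force Wilcoxon signed-rank oracle: enumerate all 2^n sign
# assignments of the midranks; two-sided p by |W - mu| >= observed.
wilcoxon_oracle <- function(deltas) {
  nz <- deltas[deltas != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}
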