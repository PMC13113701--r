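cat6 <- tiny_catalog()
cfg0 <- guardrail_config()

test_that("regimen_cost is flat per-day pricing", {
  expect_equal(regimen_cost(regimen(), cat6), 0)
  expect_equal(regimen_cost(regimen("CEFTRIAXONE", 2), cat6, days = 1), 2.5)
  two <- regimen(c("MEROPENEM", "VANCO"), c(3, 2))
  expect_equal(regimen_cost(two, cat6, days = 3), 3 * (24 + 12))
  expect_error(regimen_cost(regimen("NOSUCH", 1), cat6),
               class = "stewardpair_unmapped_agent")
})

test_that("regimen_ddd follows dose / DDD reference", {
  expect_equal(regimen_ddd(regimen(), cat6), 0)
  expect_equal(regimen_ddd(regimen("MEROPENEM", 3), cat6), 1)
  halves <- regimen(c("MEROPENEM", "VANCO"), c(1.5, 1))
  expect_equal(regimen_ddd(halves, cat6), 1)
})

test_that("AWaRe regimen scores use the 1/2/3 mapping with empty = 0", {
  sc <- stewardpair:::aware_regimen_scores(regimen("AMOXI", 1.5), cat6)
  expect_equal(unname(sc), c(1, 1))
  mix <- stewardpair:::aware_regimen_scores(
    regimen(c("AMOXI", "MEROPENEM"), c(1.5, 3)), cat6)  # ACCESS + WATCH
  expect_equal(unname(mix), c(1.5, 2))
  expect_equal(unname(stewardpair:::aware_regimen_scores(regimen(), cat6)),
               c(0, 0))
})

test_that("cost delta endpoints: toy arithmetic and the 72 h subset filter", {
  prices <- load_catalog(write_catalog_file(c(
    "A,Agent A,0,0,0,ACCESS,1,10",
    "B,Agent B,0,0,0,ACCESS,1,4")))
  cohort <- make_cohort(list(regimen("A", 1), regimen("A", 1)),
                        list(regimen("B", 1), regimen("B", 1)),
                        continued_72h = FALSE)
  ep <- compute_cost_deltas(cohort, prices, "H24", n_boot = 100)
  expect_equal(ep$delta_summary$median, -6)
  expect_equal(unname(ep$totals), c(20, 8))
  expect_error(compute_cost_deltas(cohort, prices, "H72", n_boot = 100),
               "continued_72h", class = "stewardpair_validation_error")
  cohort2 <- make_cohort(list(regimen("A", 1)), list(regimen("B", 1)),
                         continued_72h = TRUE)
  ep72 <- compute_cost_deltas(cohort2, prices, "H72", n_boot = 100)
  expect_equal(ep72$delta_summary$median, 3 * (4 - 10))
  expect_equal(ep72$n, 1L)
})

test_that("coverage endpoint restricts to the evaluable subset", {
  cohort <- make_cohort(
    rep(list(regimen("AMOXI", 1.5)), 4),
    rep(list(regimen("DOXY", 0.1)), 4),
    micro_evaluable = c(TRUE, TRUE, TRUE, FALSE),
    clin_covered = c(1L, 0L, 1L, NA),
    llm_covered = c(1L, 1L, 0L, NA))
  ep <- compute_coverage_endpoint(cohort)
  expect_true(ep$computable)
  expect_equal(ep$n, 3L)
  expect_equal(ep$n_not_evaluable, 1L)
  expect_equal(unlist(unclass(ep$table)),
               c(n00 = 0L, n01 = 1L, n10 = 1L, n11 = 1L))
  # zero evaluable admissions: non-computable, not an error
  none <- make_cohort(list(regimen("AMOXI", 1.5)), list(regimen()))
  ep0 <- compute_coverage_endpoint(none)
  expect_false(ep0$computable)
  expect_equal(ep0$n, 0L)
})

test_that("evaluable admissions must carry both coverage fields", {
  expect_error(make_cohort(list(regimen("AMOXI", 1.5)),
                           list(regimen("DOXY", 0.1)),
                           micro_evaluable = TRUE,
                           clin_covered = 1L, llm_covered = NA_integer_),
               "coverage", class = "stewardpair_validation_error")
})

test_that("concordance counts identical sets, primary agent and overlap", {
  cohort <- make_cohort(
    list(regimen(c("AMOXI", "DOXY"), c(1.5, 0.1)),   # identical set
         regimen(c("AMOXI", "DOXY"), c(1.5, 0.1)),   # same primary only
         regimen(c("PIPTAZ", "VANCO"), c(14, 2)),    # overlap, diff primary
         regimen("CEFTRIAXONE", 2),                  # disjoint
         regimen("AMOXI", 1.5)),                     # vs empty
    list(regimen(c("AMOXI", "DOXY"), c(1.5, 0.1)),
         regimen("AMOXI", 1.5),
         regimen(c("VANCO", "CEFTRIAXONE"), c(2, 2)),
         regimen("DOXY", 0.1),
         regimen()))
  cc <- compute_concordance(cohort)
  expect_equal(cc$n_identical_set, 1L)
  expect_equal(cc$n_same_primary_agent, 2L)
  expect_equal(cc$n_any_overlap, 3L)
  expect_equal(cc$n_no_overlap, 2L)
  expect_equal(cc$n_any_overlap + cc$n_no_overlap, cc$n)
})

test_that("NO_ANTIBIOTIC QC flags empty regimens with active triggers", {
  cohort <- make_cohort(
    rep(list(regimen("AMOXI", 1.5)), 3),
    list(regimen(), regimen(), regimen("DOXY", 0.1)),
    ctx_overrides = list(make_ctx(icu_24h = TRUE), make_ctx(), make_ctx()))
  qc <- no_antibiotic_qc(cohort)
  expect_equal(nrow(qc), 2L)
  expect_equal(qc$flagged, c(TRUE, FALSE))
  full <- make_cohort(list(regimen("AMOXI", 1.5)), list(regimen("DOXY", 0.1)))
  expect_equal(nrow(no_antibiotic_qc(full)), 0L)
})

test_that("run_all aborts on unmapped agents with a QC pointer", {
  bad <- make_cohort(list(regimen("NOSUCH", 1)), list(regimen("DOXY", 0.1)))
  err <- tryCatch(run_all(bad, cfg0, cat6), condition = function(c) c)
  expect_s3_class(err, "stewardpair_qc_error")
  expect_equal(err$qc_report$code, "NOSUCH")
})

test_that("fully concordant cohorts give OR 1, p 1 and zero deltas", {
  reg <- regimen("MEROPENEM", 3)
  cohort <- make_cohort(rep(list(reg), 6), rep(list(reg), 6))
  b <- suppressWarnings(run_all(cohort, cfg0, cat6, n_boot = 100))
  expect_equal(b$endpoints$primary$or_result$or_hat, 1)
  expect_equal(b$endpoints$primary$or_result$p_exact, 1)
  expect_equal(unlist(unclass(b$endpoints$primary$table))[["n11"]], 6L)
  expect_true(all(b$endpoints$penalty$deltas == 0))
  expect_equal(b$endpoints$penalty$delta_summary$p_sign, 1)
  expect_equal(nrow(b$holm_family), 6L)
})

test_that("single-admission discordant cohort yields table (0,0,1,0)", {
  cohort <- make_cohort(list(regimen("MEROPENEM", 3)),
                        list(regimen("DOXY", 0.1)))
  ep <- compute_primary(cohort, cfg0, cat6)
  expect_equal(unlist(unclass(ep$table)),
               c(n00 = 0L, n01 = 0L, n10 = 1L, n11 = 0L))
})

test_that("arm rates reconstructed from tables match direct tallies", {
  set.seed(21)
  pool <- list(regimen(), regimen("AMOXI", 1.5), regimen("MEROPENEM", 3),
               regimen(c("PIPTAZ", "VANCO"), c(14, 2)))
  cohort <- make_cohort(sample(pool, 30, replace = TRUE),
                        sample(pool, 30, replace = TRUE))
  b <- suppressWarnings(run_all(cohort, cfg0, cat6, n_boot = 100))
  for (k in c("primary", "carb", "aps", "mrsa", "broad")) {
    e <- b$endpoints[[k]]
    t <- e$table
    expect_equal(unname(e$arm_rates["clin"]), (t$n10 + t$n11) / e$n)
    expect_equal(unname(e$arm_rates["llm"]), (t$n01 + t$n11) / e$n)
  }
  # penalty-delta sign consistency with per-arm assessments
  a_clin <- stewardpair:::assess_cohort_arm(cohort, "clin", cfg0, cat6)
  a_llm <- stewardpair:::assess_cohort_arm(cohort, "llm", cfg0, cat6)
  d <- b$endpoints$penalty$deltas
  expect_true(all((d < 0) == (a_clin$penalty > a_llm$penalty)))
  # Holm family is monotone in raw-p order
  hf <- b$holm_family[!is.na(b$holm_family$raw_p), ]
  o <- order(hf$raw_p)
  expect_true(all(diff(hf$adjusted_p[o]) >= -1e-12))
})
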