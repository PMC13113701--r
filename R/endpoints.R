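# Endpoint pipeline: assembles the full prespecified endpoint battery over a
# paired cohort.

new_endpoint <- function(endpoint_id, n, table = NULL, or_result = NULL,
                         delta_summary = NULL, arm_rates = NULL, ...) {
  structure(list(endpoint_id = endpoint_id, n = n, table = table,
                 or_result = or_result, delta_summary = delta_summary,
                 arm_rates = arm_rates, ...),
            class = "endpoint_result")
}

endpoint_binary <- function(endpoint_id, clin, llm) {
  t <- build_paired_table(clin, llm)
  new_endpoint(endpoint_id, n = length(clin), table = t,
               or_result = matched_odds_ratio(t),
               arm_rates = c(clin = mean(clin), llm = mean(llm)))
}

endpoint_delta <- function(endpoint_id, deltas, n_boot, seed) {
  new_endpoint(endpoint_id, n = length(deltas),
               delta_summary = delta_summary(deltas, with_bootstrap = TRUE,
                                             n_boot = n_boot, seed = seed),
               deltas = deltas)
}

require_qc_pass <- function(cohort, catalog) {
  qc <- catalog_qc(cohort, catalog)
  if (nrow(qc) > 0L) {
    sp_stop(sprintf(
      "catalog QC failed: %d unmapped agent reference(s), first: %s/%s '%s'",
      nrow(qc), qc$admission_id[1L], qc$arm[1L], qc$code[1L]),
      "stewardpair_qc_error", qc_report = qc)
  }
  invisible(qc)
}

#' Primary endpoint: any contextual guardrail violation (paired binary)
#'
#' Scores both arms with the guardrail engine, tallies the paired 2x2 table of
#' any-violation indicators, and computes the matched OR, 95\% CI, risk
#' difference and exact McNemar p-value.
#'
#' @param cohort a \code{steward_cohort}.
#' @param cfg a [guardrail_config()].
#' @param catalog an \code{agent_catalog}.
#' @return an \code{endpoint_result}.
#' @export
compute_primary <- function(cohort, cfg = guardrail_config(),
                            catalog = default_catalog()) {
  require_qc_pass(cohort, catalog)
  a_clin <- assess_cohort_arm(cohort, "clin", cfg, catalog)
  a_llm <- assess_cohort_arm(cohort, "llm", cfg, catalog)
  endpoint_binary("primary_any_violation",
                  as.integer(a_clin$any_violation),
                  as.integer(a_llm$any_violation))
}

#' Key secondary endpoint: paired penalty delta
#'
#' Per-admission \eqn{\Delta} penalty (recommendation minus clinician), with
#' median/IQR, sign counts, Wilcoxon and sign tests, and the seeded bootstrap
#' CI for the median.
#'
#' @inheritParams compute_primary
#' @param n_boot,boot_seed bootstrap settings (defaults 5000 / 7).
#' @return an \code{endpoint_result}.
#' @export
compute_penalty_endpoint <- function(cohort, cfg = guardrail_config(),
                                     catalog = default_catalog(),
                                     n_boot = 5000L, boot_seed = 7L) {
  require_qc_pass(cohort, catalog)
  a_clin <- assess_cohort_arm(cohort, "clin", cfg, catalog)
  a_llm <- assess_cohort_arm(cohort, "llm", cfg, catalog)
  endpoint_delta("delta_penalty", a_llm$penalty - a_clin$penalty,
                 n_boot, boot_seed)
}

#' Component violation endpoints (carbapenem, antipseudomonal, anti-MRSA)
#'
#' One paired-binary endpoint per guardrail component, using the same matched
#' OR / exact McNemar machinery as the primary endpoint.
#'
#' @inheritParams compute_primary
#' @return named list of three \code{endpoint_result}s
#'   (\code{carb}, \code{aps}, \code{mrsa}).
#' @export
compute_component_endpoints <- function(cohort, cfg = guardrail_config(),
                                        catalog = default_catalog()) {
  require_qc_pass(cohort, catalog)
  a_clin <- assess_cohort_arm(cohort, "clin", cfg, catalog)
  a_llm <- assess_cohort_arm(cohort, "llm", cfg, catalog)
  cols <- c(carb = "I_carb", aps = "I_aps", mrsa = "I_mrsa")
  ids <- c(carb = "carbapenem_violation", aps = "antipseudomonal_violation",
           mrsa = "anti_mrsa_violation")
  out <- lapply(names(cols), function(k) {
    endpoint_binary(ids[[k]], a_clin[[cols[[k]]]], a_llm[[cols[[k]]]])
  })
  names(out) <- names(cols)
  out
}

#' Broad-spectrum exposure composite (paired binary)
#'
#' Any carbapenem, antipseudomonal beta-lactam or anti-MRSA agent in the
#' regimen, regardless of context (exposure, not violation).
#'
#' @inheritParams compute_primary
#' @return an \code{endpoint_result}.
#' @export
compute_broad_spectrum_endpoint <- function(cohort,
                                            catalog = default_catalog()) {
  require_qc_pass(cohort, catalog)
  pres_clin <- colSums(class_presence(cohort$clin_regimen, catalog)) > 0L
  pres_llm <- colSums(class_presence(cohort$llm_regimen, catalog)) > 0L
  endpoint_binary("broad_spectrum_any", as.integer(pres_clin),
                  as.integer(pres_llm))
}

#' Acquisition cost of a regimen over a window
#'
#' Flat per-day pricing: the sum over agents of the catalog unit cost (EUR per
#' day at DDD) times the window length in days (1 for the 24 h window, 3 for
#' the 72 h window). Empty regimen costs 0.
#'
#' @param reg a [regimen()].
#' @param catalog an \code{agent_catalog}.
#' @param days window length in days.
#' @return cost in EUR.
#' @export
regimen_cost <- function(reg, catalog = default_catalog(), days = 1) {
  if (nrow(reg) == 0L) return(0)
  idx <- match(toupper(trimws(reg$code)), rownames(catalog))
  if (anyNA(idx)) {
    sp_stop(sprintf("unmapped antibiotic agent code: '%s'",
                    reg$code[which(is.na(idx))[1L]]),
            "stewardpair_unmapped_agent")
  }
  sum(catalog$unit_cost_eur[idx]) * days
}

#' Paired cost-delta endpoint (24 h or 72 h window)
#'
#' Per-admission acquisition-cost difference (recommendation minus clinician).
#' The 24 h window uses all admissions at 1 day of therapy; the 72 h window is
#' restricted to the continued-therapy subset (clinician empiric therapy
#' continued at least 3 days) and prices 3 flat days for both arms.
#'
#' @inheritParams compute_penalty_endpoint
#' @param window \code{"H24"} or \code{"H72"}.
#' @return an \code{endpoint_result} (also carries the per-arm cohort totals).
#' @export
compute_cost_deltas <- function(cohort, catalog = default_catalog(),
                                window = c("H24", "H72"), n_boot = 5000L,
                                boot_seed = 7L) {
  window <- match.arg(window)
  require_qc_pass(cohort, catalog)
  if (window == "H72") {
    cohort <- cohort[cohort$continued_72h, , drop = FALSE]
    if (nrow(cohort) == 0L) {
      sp_stop("72 h cost endpoint: no admissions satisfy continued_72h",
              "stewardpair_validation_error")
    }
    days <- 3
  } else {
    days <- 1
  }
  cost_clin <- vapply(cohort$clin_regimen, regimen_cost, numeric(1L),
                      catalog = catalog, days = days)
  cost_llm <- vapply(cohort$llm_regimen, regimen_cost, numeric(1L),
                     catalog = catalog, days = days)
  ep <- endpoint_delta(paste0("delta_cost_", tolower(window)),
                       cost_llm - cost_clin, n_boot, boot_seed)
  ep$totals <- c(clin = sum(cost_clin), llm = sum(cost_llm))
  ep
}

#' Defined daily doses delivered by a regimen per 24 h
#'
#' WHO ATC/DDD-style consumption: the sum over agents of daily dose divided by
#' the agent's DDD reference. Empty regimen gives 0.
#'
#' @inheritParams regimen_cost
#' @return DDD count (non-negative real).
#' @export
regimen_ddd <- function(reg, catalog = default_catalog()) {
  if (nrow(reg) == 0L) return(0)
  idx <- match(toupper(trimws(reg$code)), rownames(catalog))
  if (anyNA(idx)) {
    sp_stop(sprintf("unmapped antibiotic agent code: '%s'",
                    reg$code[which(is.na(idx))[1L]]),
            "stewardpair_unmapped_agent")
  }
  sum(reg$dose_g / catalog$ddd_ref_g[idx])
}

compute_ddd_endpoint <- function(cohort, catalog = default_catalog(),
                                 n_boot = 5000L, boot_seed = 7L) {
  require_qc_pass(cohort, catalog)
  d_clin <- vapply(cohort$clin_regimen, regimen_ddd, numeric(1L),
                   catalog = catalog)
  d_llm <- vapply(cohort$llm_regimen, regimen_ddd, numeric(1L),
                  catalog = catalog)
  endpoint_delta("delta_ddd_24h", d_llm - d_clin, n_boot, boot_seed)
}

# Numeric AWaRe mapping: monotone in stewardship priority; configurable.
AWARE_SCORES <- c(ACCESS = 1, WATCH = 2, RESERVE = 3)

aware_regimen_scores <- function(reg, catalog, mapping = AWARE_SCORES) {
  if (nrow(reg) == 0L) return(c(mean = 0, max = 0))  # empty-regimen convention
  idx <- match(toupper(trimws(reg$code)), rownames(catalog))
  if (anyNA(idx)) {
    sp_stop(sprintf("unmapped antibiotic agent code: '%s'",
                    reg$code[which(is.na(idx))[1L]]),
            "stewardpair_unmapped_agent")
  }
  s <- mapping[catalog$aware_class[idx]]
  c(mean = mean(s), max = max(s))
}

#' Paired AWaRe delta endpoints (mean and max scores)
#'
#' Agent-level AWaRe classes are mapped to numeric scores (ACCESS = 1,
#' WATCH = 2, RESERVE = 3); each regimen is summarised by the mean and the max
#' of its agent scores (empty regimen scores 0 by convention), and paired
#' deltas (recommendation minus clinician) are summarised.
#'
#' @inheritParams compute_penalty_endpoint
#' @param mapping named numeric AWaRe score mapping.
#' @return named list of two \code{endpoint_result}s
#'   (\code{aware_mean}, \code{aware_max}).
#' @export
compute_aware_deltas <- function(cohort, catalog = default_catalog(),
                                 mapping = AWARE_SCORES, n_boot = 5000L,
                                 boot_seed = 7L) {
  require_qc_pass(cohort, catalog)
  s_clin <- vapply(cohort$clin_regimen, aware_regimen_scores, numeric(2L),
                   catalog = catalog, mapping = mapping)
  s_llm <- vapply(cohort$llm_regimen, aware_regimen_scores, numeric(2L),
                  catalog = catalog, mapping = mapping)
  list(aware_mean = endpoint_delta("delta_aware_mean",
                                   s_llm["mean", ] - s_clin["mean", ],
                                   n_boot, boot_seed),
       aware_max = endpoint_delta("delta_aware_max",
                                  s_llm["max", ] - s_clin["max", ],
                                  n_boot, boot_seed))
}

#' Microbiology-evaluable coverage endpoint
#'
#' Paired binary on the recorded active-coverage flags, restricted to
#' microbiology-evaluable admissions. Coverage adjudication is an input
#' (\code{clin_covered}/\code{llm_covered}), not computed here. With zero
#' evaluable admissions the endpoint is marked non-computable rather than
#' raising an error.
#'
#' @param cohort a \code{steward_cohort}.
#' @return an \code{endpoint_result}; carries \code{n_not_evaluable} and a
#'   \code{computable} flag.
#' @export
compute_coverage_endpoint <- function(cohort) {
  ev <- cohort$micro_evaluable
  sub <- cohort[ev, , drop = FALSE]
  if (nrow(sub) == 0L) {
    ep <- new_endpoint("coverage_micro_evaluable", n = 0L,
                       computable = FALSE, n_not_evaluable = nrow(cohort))
    return(ep)
  }
  ep <- endpoint_binary("coverage_micro_evaluable", sub$clin_covered,
                        sub$llm_covered)
  ep$computable <- TRUE
  ep$n_not_evaluable <- sum(!ev)
  ep
}

#' Regimen concordance between arms
#'
#' Four counts over the cohort: identical agent sets, same primary agent (the
#' first-listed agent of each regimen; both non-empty), any set overlap, and
#' no overlap.
#'
#' @param cohort a \code{steward_cohort}.
#' @return a \code{concordance_summary} list of counts plus the denominator.
#' @export
compute_concordance <- function(cohort) {
  sets_clin <- lapply(cohort$clin_regimen, function(r) sort(unique(r$code)))
  sets_llm <- lapply(cohort$llm_regimen, function(r) sort(unique(r$code)))
  identical_set <- mapply(identical, sets_clin, sets_llm)
  prim <- function(r) if (nrow(r) > 0L) r$code[1L] else NA_character_
  p_clin <- vapply(cohort$clin_regimen, prim, "")
  p_llm <- vapply(cohort$llm_regimen, prim, "")
  same_primary <- !is.na(p_clin) & !is.na(p_llm) & p_clin == p_llm
  overlap <- mapply(function(a, b) length(intersect(a, b)) > 0L,
                    sets_clin, sets_llm)
  structure(list(n = nrow(cohort),
                 n_identical_set = sum(identical_set),
                 n_same_primary_agent = sum(same_primary),
                 n_any_overlap = sum(overlap),
                 n_no_overlap = sum(!overlap)),
            class = "concordance_summary")
}

#' QC report for empty recommendation regimens (NO_ANTIBIOTIC)
#'
#' Lists every admission whose recommendation-arm regimen is empty, with its
#' SEVERE and MDR_RISK proxy values; such an admission is flagged when either
#' proxy is TRUE (withholding therapy despite a structured trigger).
#'
#' @param cohort a \code{steward_cohort}.
#' @param cfg a [guardrail_config()] (proxies only; rules unused).
#' @return data.frame with columns \code{admission_id}, \code{severe},
#'   \code{mdr_risk}, \code{flagged}.
#' @export
no_antibiotic_qc <- function(cohort, cfg = guardrail_config()) {
  empty <- vapply(cohort$llm_regimen, nrow, integer(1L)) == 0L
  sub <- cohort[empty, , drop = FALSE]
  severe <- if (nrow(sub)) severe_proxy(sub) else logical(0)
  mdr <- if (nrow(sub)) mdr_risk_proxy(sub) else logical(0)
  data.frame(admission_id = sub$admission_id, severe = severe,
             mdr_risk = mdr, flagged = severe | mdr,
             stringsAsFactors = FALSE)
}

# Fixed order of the prespecified paired-delta multiplicity family (m = 6).
HOLM_FAMILY <- c("delta_penalty", "delta_cost_h24", "delta_cost_h72",
                 "delta_aware_mean", "delta_aware_max", "delta_ddd_24h")

#' Run the full endpoint battery
#'
#' Executes, in order: catalog QC (aborting on failure), the primary
#' any-violation endpoint, the penalty delta, the three component endpoints,
#' the broad-spectrum composite, cost deltas at 24 h and 72 h, the DDD delta,
#' the two AWaRe deltas, the microbiology-evaluable coverage endpoint,
#' concordance, the NO_ANTIBIOTIC QC, and the Holm-adjusted paired-delta
#' family (m = 6, fixed order: penalty, cost 24 h, cost 72 h, AWaRe mean,
#' AWaRe max, DDD) using each delta endpoint's Wilcoxon p-value. Denominators
#' are complete-case per endpoint.
#'
#' @inheritParams compute_penalty_endpoint
#' @return a \code{results_bundle}: list with \code{endpoints} (named list of
#'   \code{endpoint_result}s), \code{holm_family} (data.frame),
#'   \code{concordance}, and \code{qc}.
#' @export
run_all <- function(cohort, cfg = guardrail_config(),
                    catalog = default_catalog(), n_boot = 5000L,
                    boot_seed = 7L) {
  require_qc_pass(cohort, catalog)
  a_clin <- assess_cohort_arm(cohort, "clin", cfg, catalog)
  a_llm <- assess_cohort_arm(cohort, "llm", cfg, catalog)

  eps <- list()
  eps$primary <- endpoint_binary("primary_any_violation",
                                 as.integer(a_clin$any_violation),
                                 as.integer(a_llm$any_violation))
  eps$penalty <- endpoint_delta("delta_penalty",
                                a_llm$penalty - a_clin$penalty,
                                n_boot, boot_seed)
  eps$carb <- endpoint_binary("carbapenem_violation", a_clin$I_carb,
                              a_llm$I_carb)
  eps$aps <- endpoint_binary("antipseudomonal_violation", a_clin$I_aps,
                             a_llm$I_aps)
  eps$mrsa <- endpoint_binary("anti_mrsa_violation", a_clin$I_mrsa,
                              a_llm$I_mrsa)
  eps$broad <- endpoint_binary("broad_spectrum_any",
                               as.integer(a_clin$broad_spectrum),
                               as.integer(a_llm$broad_spectrum))
  eps$cost_24h <- compute_cost_deltas(cohort, catalog, "H24", n_boot,
                                      boot_seed)
  eps$cost_72h <- compute_cost_deltas(cohort, catalog, "H72", n_boot,
                                      boot_seed)
  eps$ddd <- compute_ddd_endpoint(cohort, catalog, n_boot, boot_seed)
  aware <- compute_aware_deltas(cohort, catalog, n_boot = n_boot,
                                boot_seed = boot_seed)
  eps$aware_mean <- aware$aware_mean
  eps$aware_max <- aware$aware_max
  eps$coverage <- compute_coverage_endpoint(cohort)

  raw_p <- vapply(eps, function(e) {
    if (is.null(e$delta_summary)) NA_real_ else e$delta_summary$p_wilcoxon
  }, numeric(1L))
  ids <- vapply(eps, `[[`, "", "endpoint_id")
  fam_idx <- match(HOLM_FAMILY, ids)
  fam_raw <- unname(raw_p[fam_idx])
  holm <- data.frame(endpoint_id = HOLM_FAMILY, raw_p = fam_raw,
                     adjusted_p = holm_adjust(fam_raw),
                     stringsAsFactors = FALSE)

  structure(list(endpoints = eps,
                 holm_family = holm,
                 concordance = compute_concordance(cohort),
                 qc = list(catalog = catalog_qc(cohort, catalog),
                           no_antibiotic = no_antibiotic_qc(cohort, cfg),
                           missing_as_absent =
                             attr(cohort, "missing_as_absent") %||% integer(0)),
                 n = nrow(cohort),
                 catalog_version = attr(catalog, "version_tag")),
            class = "results_bundle")
}

# Display rounding conventions: OR/RD to 3 decimals, p to 3 significant
# figures. Applied only at rendering; stored values are full precision.
fmt_or <- function(x) formatC(round(x, 3), format = "fg", digits = 8)
fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  format(signif(p, 3), scientific = p < 1e-3)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("stewardpair results bundle (N = %d admissions)\n", x$n))
  for (e in x$endpoints) {
    if (!is.null(e$or_result)) {
      cat(sprintf(
        "  %-28s N=%-4d OR %.3f (%.3f-%.3f) RD %+.3f  p=%s\n",
        e$endpoint_id, e$n, e$or_result$or_hat, e$or_result$ci_low,
        e$or_result$ci_high, e$or_result$rd, fmt_p(e$or_result$p_exact)))
    } else if (!is.null(e$delta_summary)) {
      s <- e$delta_summary
      cat(sprintf(
        "  %-28s N=%-4d median %g (IQR %g-%g)  -/0/+: %d/%d/%d  pW=%s pS=%s\n",
        e$endpoint_id, e$n, s$median, s$q1, s$q3, s$n_neg, s$n_zero, s$n_pos,
        fmt_p(s$p_wilcoxon), fmt_p(s$p_sign)))
    } else {
      cat(sprintf("  %-28s not computable (n = %d evaluable)\n",
                  e$endpoint_id, e$n))
    }
  }
  cat("  Holm family (m = 6):\n")
  for (i in seq_len(nrow(x$holm_family))) {
    cat(sprintf("    %-18s raw=%s adj=%s\n", x$holm_family$endpoint_id[i],
                fmt_p(x$holm_family$raw_p[i]),
                fmt_p(x$holm_family$adjusted_p[i])))
  }
  invisible(x)
}
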