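# Contextual guardrail engine: justification proxies, per-component violation
# indicators, and the weighted penalty.

#' Construct a regimen
#'
#' A regimen is the set of systemic antibacterial agents initiated concurrently
#' in the first 24 h (one arm of an admission). An empty regimen encodes
#' NO_ANTIBIOTIC. Agent order is preserved: the first-listed agent is the
#' regimen's "primary agent" for concordance purposes.
#'
#' @param codes character vector of agent codes (unique within the regimen).
#' @param doses_g daily doses in grams, one per code, all positive.
#' @return a \code{regimen} data.frame with columns \code{code}, \code{dose_g}.
#' @export
regimen <- function(codes = character(), doses_g = numeric()) {
  codes <- toupper(trimws(as.character(codes)))
  doses_g <- as.numeric(doses_g)
  if (length(codes) != length(doses_g)) {
    sp_stop("codes and doses_g must have equal length",
            "stewardpair_validation_error")
  }
  if (anyDuplicated(codes)) {
    sp_stop(sprintf("duplicate agent code within regimen: %s",
                    codes[duplicated(codes)][1L]),
            "stewardpair_validation_error")
  }
  if (length(doses_g) && any(!is.finite(doses_g) | doses_g <= 0)) {
    sp_stop("all daily doses must be positive and finite",
            "stewardpair_validation_error")
  }
  structure(data.frame(code = codes, dose_g = doses_g,
                       stringsAsFactors = FALSE),
            class = c("regimen", "data.frame"))
}

#' Guardrail configuration: weights and justification rules
#'
#' The penalty is the weighted sum of component violation indicators,
#' \eqn{\mathrm{Penalty} = \sum_k w_k I_k}, over the components carbapenem
#' (\code{carb}), antipseudomonal beta-lactam (\code{aps}) and anti-MRSA
#' (\code{mrsa}). Prespecified weights are 2/1/1. A component is violated when
#' the class is used and its justification rule evaluates to \code{FALSE} on
#' the admission context. Rules are Boolean expressions over the fixed proxy
#' vocabulary \code{SEVERE}, \code{MDR_RISK}, \code{PRIOR_MRSA}; the defaults
#' justify carbapenem and antipseudomonal use by \code{SEVERE | MDR_RISK} and
#' anti-MRSA use by documented prior MRSA colonization.
#'
#' @param weights named positive numeric vector over
#'   \code{c("carb","aps","mrsa")}.
#' @param rules named list of rule strings, one per component.
#' @return a \code{guardrail_config}.
#' @export
guardrail_config <- function(weights = c(carb = 2, aps = 1, mrsa = 1),
                             rules = list(carb = "SEVERE | MDR_RISK",
                                          aps  = "SEVERE | MDR_RISK",
                                          mrsa = "PRIOR_MRSA")) {
  if (!setequal(names(weights), GUARDRAIL_COMPONENTS) ||
      !setequal(names(rules), GUARDRAIL_COMPONENTS)) {
    sp_stop("weights and rules must be named over components carb, aps, mrsa",
            "stewardpair_validation_error")
  }
  weights <- weights[GUARDRAIL_COMPONENTS]
  rules <- rules[GUARDRAIL_COMPONENTS]
  if (any(!is.finite(weights) | weights <= 0)) {
    sp_stop("guardrail weights must be strictly positive",
            "stewardpair_validation_error")
  }
  exprs <- lapply(names(rules), function(k) {
    rule <- rules[[k]]
    e <- tryCatch(parse(text = rule)[[1L]], error = function(err) {
      sp_stop(sprintf("cannot parse justification rule for '%s': %s", k, rule),
              "stewardpair_validation_error")
    })
    bad <- setdiff(all.names(e), RULE_ALLOWED_NAMES)
    if (length(bad) > 0L) {
      sp_stop(sprintf(
        "justification rule for '%s' uses unknown symbol(s): %s (allowed: %s)",
        k, paste(bad, collapse = ", "), paste(RULE_VOCAB, collapse = ", ")),
        "stewardpair_validation_error")
    }
    e
  })
  names(exprs) <- names(rules)
  structure(list(weights = weights, rules = rules, rule_exprs = exprs),
            class = "guardrail_config")
}

# Pull a context flag as a logical vector, treating an absent column or NA as
# FALSE (the missing-as-absent rule applied at scoring time as a backstop; the
# reader applies and logs it at ingestion).
ctx_flag <- function(ctx, field) {
  v <- ctx[[field]]
  if (is.null(v)) return(rep(FALSE, max(1L, nrow(as.data.frame(ctx)))))
  v <- as.logical(v)
  v[is.na(v)] <- FALSE
  v
}

#' Severity justification proxy (SEVERE)
#'
#' TRUE when any of the five early severity/support indicators within 24 h is
#' documented: ICU admission/transfer, septic shock, vasopressor use,
#' mechanical ventilation, or respiratory failure. Absent fields count as
#' FALSE. Vectorised over the rows of a cohort/context data.frame.
#'
#' @param ctx an admission context (named list or data.frame of flags).
#' @return logical vector.
#' @export
severe_proxy <- function(ctx) {
  Reduce(`|`, lapply(SEVERE_FIELDS, ctx_flag, ctx = ctx))
}

#' Multidrug-resistance risk proxy (MDR_RISK)
#'
#' TRUE when any of: prior ESBL/CRE/VRE, systemic antibiotics in the prior 90
#' days, hospitalization in the prior 90 days, long-term care facility
#' residence, or healthcare-associated acquisition. Absent fields count as
#' FALSE. Vectorised.
#'
#' @inheritParams severe_proxy
#' @return logical vector.
#' @export
mdr_risk_proxy <- function(ctx) {
  Reduce(`|`, lapply(MDR_FIELDS, ctx_flag, ctx = ctx))
}

# Evaluate one component's justification rule on proxy vectors.
eval_rule <- function(cfg, component, severe, mdr_risk, prior_mrsa) {
  env <- list2env(list(SEVERE = severe, MDR_RISK = mdr_risk,
                       PRIOR_MRSA = prior_mrsa), parent = baseenv())
  out <- eval(cfg$rule_exprs[[component]], envir = env)
  as.logical(out)
}

# Class-flag presence for a list of regimens: 3 x n logical matrix
# (rows carb/aps/mrsa). Errors on any unmapped code.
class_presence <- function(regimen_list, catalog) {
  carb <- catalog$is_carbapenem
  aps <- catalog$is_antipseudomonal
  mrsa <- catalog$is_anti_mrsa
  codes <- rownames(catalog)
  vapply(regimen_list, function(r) {
    idx <- match(toupper(trimws(r$code)), codes)
    if (anyNA(idx)) {
      sp_stop(sprintf("unmapped antibiotic agent code: '%s'",
                      r$code[which(is.na(idx))[1L]]),
              "stewardpair_unmapped_agent",
              agent_code = r$code[which(is.na(idx))[1L]])
    }
    c(any(carb[idx]), any(aps[idx]), any(mrsa[idx]))
  }, logical(3L))
}

#' Component violation indicator
#'
#' 1 iff at least one agent in the regimen carries the component's class flag
#' and the component's justification rule evaluates FALSE on the admission
#' context; 0 otherwise.
#'
#' @param reg a [regimen()].
#' @param ctx admission context (named list/one-row data.frame of flags).
#' @param component one of \code{"carb"}, \code{"aps"}, \code{"mrsa"}.
#' @param cfg a [guardrail_config()].
#' @param catalog an \code{agent_catalog}.
#' @return integer 0/1.
#' @export
component_violation <- function(reg, ctx, component, cfg = guardrail_config(),
                                catalog = default_catalog()) {
  component <- match.arg(component, GUARDRAIL_COMPONENTS)
  present <- class_presence(list(reg), catalog)[match(component,
                                                      GUARDRAIL_COMPONENTS), 1L]
  justified <- eval_rule(cfg, component,
                         severe = severe_proxy(ctx)[1L],
                         mdr_risk = mdr_risk_proxy(ctx)[1L],
                         prior_mrsa = ctx_flag(ctx, "prior_mrsa_colonization")[1L])
  as.integer(present && !justified)
}

#' Assess one regimen against the contextual guardrails
#'
#' Computes the three component indicators, the any-violation flag, and the
#' weighted penalty \eqn{\sum_k w_k I_k}. With the default weights the penalty
#' takes values in \{0, 1, 2, 3, 4\}.
#'
#' @inheritParams component_violation
#' @return a \code{guardrail_assessment}: list with \code{I_carb},
#'   \code{I_APS}, \code{I_MRSA}, \code{any_violation}, \code{penalty}.
#' @export
assess_regimen <- function(reg, ctx, cfg = guardrail_config(),
                           catalog = default_catalog()) {
  I <- vapply(GUARDRAIL_COMPONENTS, function(k) {
    component_violation(reg, ctx, k, cfg, catalog)
  }, integer(1L))
  penalty <- sum(cfg$weights * I)
  structure(list(I_carb = I[["carb"]], I_APS = I[["aps"]],
                 I_MRSA = I[["mrsa"]],
                 any_violation = sum(I) >= 1L, penalty = penalty),
            class = "guardrail_assessment")
}

#' Paired penalty difference
#'
#' \eqn{\Delta\mathrm{Penalty}} = penalty(recommendation arm) minus
#' penalty(clinician arm); negative values favour the recommendation arm.
#' Accepts \code{guardrail_assessment} objects or bare penalties.
#'
#' @param llm,clin assessments (or numeric penalties) for the two arms.
#' @return signed numeric difference.
#' @export
delta_penalty <- function(llm, clin) {
  p <- function(x) if (is.list(x)) x$penalty else as.numeric(x)
  p(llm) - p(clin)
}

#' Any broad-spectrum class exposure
#'
#' TRUE iff any agent in the regimen carries any of the three class flags
#' (carbapenem, antipseudomonal beta-lactam, anti-MRSA). Context is not
#' consulted: this is the exposure composite, not a violation.
#'
#' @param reg a [regimen()].
#' @param catalog an \code{agent_catalog}.
#' @return logical scalar.
#' @export
broad_spectrum_any <- function(reg, catalog = default_catalog()) {
  any(class_presence(list(reg), catalog)[, 1L])
}

# Vectorised assessment of one arm over a whole cohort. Returns a data.frame
# with I_carb/I_aps/I_mrsa (integer), any_violation (logical), penalty
# (numeric), broad_spectrum (logical). This is the hot path for endpoints and
# simulation; the scalar assess_regimen() is the documented per-admission API.
assess_cohort_arm <- function(cohort, arm = c("clin", "llm"),
                              cfg = guardrail_config(),
                              catalog = default_catalog()) {
  arm <- match.arg(arm)
  regs <- cohort[[paste0(arm, "_regimen")]]
  pres <- class_presence(regs, catalog)  # 3 x n
  severe <- severe_proxy(cohort)
  mdr <- mdr_risk_proxy(cohort)
  pmrsa <- ctx_flag(cohort, "prior_mrsa_colonization")
  I <- sapply(GUARDRAIL_COMPONENTS, function(k) {
    just <- eval_rule(cfg, k, severe, mdr, pmrsa)
    as.integer(pres[match(k, GUARDRAIL_COMPONENTS), ] & !just)
  })
  I <- matrix(I, ncol = 3L, dimnames = list(NULL, GUARDRAIL_COMPONENTS))
  penalty <- as.numeric(I %*% cfg$weights[GUARDRAIL_COMPONENTS])
  data.frame(I_carb = I[, "carb"], I_aps = I[, "aps"], I_mrsa = I[, "mrsa"],
             any_violation = rowSums(I) >= 1L,
             penalty = penalty,
             broad_spectrum = colSums(pres) > 0L)
}
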