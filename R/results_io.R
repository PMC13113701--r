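# Serialisation of results bundles: full-precision JSON, a rounded summary
# CSV shaped like the headline endpoint table, and a plain-text log.

BUNDLE_SCHEMA_VERSION <- "stewardpair-bundle-1"

endpoint_to_list <- function(e) {
  out <- list(endpoint_id = e$endpoint_id, n = e$n)
  if (!is.null(e$table)) out$table <- unclass(e$table)
  if (!is.null(e$or_result)) out$or_result <- unclass(e$or_result)
  if (!is.null(e$delta_summary)) out$delta_summary <- unclass(e$delta_summary)
  if (!is.null(e$arm_rates)) out$arm_rates <- as.list(e$arm_rates)
  if (!is.null(e$totals)) out$totals <- as.list(e$totals)
  if (!is.null(e$computable)) out$computable <- e$computable
  if (!is.null(e$n_not_evaluable)) out$n_not_evaluable <- e$n_not_evaluable
  out
}

bundle_to_list <- function(bundle) {
  list(schema = BUNDLE_SCHEMA_VERSION,
       n = bundle$n,
       catalog_version = bundle$catalog_version,
       endpoints = lapply(bundle$endpoints, endpoint_to_list),
       holm_family = bundle$holm_family,
       concordance = unclass(bundle$concordance),
       qc = list(catalog = bundle$qc$catalog,
                 no_antibiotic = bundle$qc$no_antibiotic,
                 missing_as_absent = as.list(bundle$qc$missing_as_absent)))
}

#' Write a results bundle to disk
#'
#' Writes three artifacts into \code{dir}: \code{results.json} (full
#' precision), \code{summary.csv} (one row per endpoint with display rounding:
#' OR/RD to 3 decimals, p to 3 significant figures), and \code{log.txt}
#' (denominators, QC reports, and the per-field missing-as-absent counts).
#'
#' @param bundle a \code{results_bundle} from [run_all()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle_to_list(bundle), file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  write.csv(summarize_bundle(bundle), file.path(dir, "summary.csv"),
            row.names = FALSE, na = "")
  writeLines(render_log(bundle), file.path(dir, "log.txt"))
  invisible(dir)
}

summarize_bundle <- function(bundle) {
  rows <- lapply(bundle$endpoints, function(e) {
    if (!is.null(e$or_result)) {
      o <- e$or_result
      t <- e$table
      data.frame(
        endpoint = e$endpoint_id, n = e$n,
        clin = sprintf("%d/%d (%.1f%%)", t$n10 + t$n11, e$n,
                       100 * (t$n10 + t$n11) / e$n),
        llm = sprintf("%d/%d (%.1f%%)", t$n01 + t$n11, e$n,
                      100 * (t$n01 + t$n11) / e$n),
        discordant = sprintf("clin1/llm0: %d; clin0/llm1: %d", t$n10, t$n01),
        effect = sprintf("OR %.3f (95%% CI %.3f-%.3f); RD %.3f",
                         o$or_hat, o$ci_low, o$ci_high, o$rd),
        p_value = fmt_p(o$p_exact),
        median_ci = "", stringsAsFactors = FALSE)
    } else if (!is.null(e$delta_summary)) {
      s <- e$delta_summary
      data.frame(
        endpoint = e$endpoint_id, n = e$n, clin = "", llm = "",
        discordant = sprintf("neg: %d; pos: %d; zero: %d",
                             s$n_neg, s$n_pos, s$n_zero),
        effect = sprintf("median %.3g (IQR %.3g to %.3g); mean %.3g (SD %.3g)",
                         s$median, s$q1, s$q3, s$mean, s$sd),
        p_value = sprintf("Wilcoxon %s; sign %s", fmt_p(s$p_wilcoxon),
                          fmt_p(s$p_sign)),
        median_ci = sprintf("%.3g to %.3g", s$ci_median_low,
                            s$ci_median_high),
        stringsAsFactors = FALSE)
    } else {
      data.frame(endpoint = e$endpoint_id, n = e$n, clin = "", llm = "",
                 discordant = "", effect = "not computable", p_value = "",
                 median_ci = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

render_log <- function(bundle) {
  lines <- c(sprintf("stewardpair analysis log (N = %d, catalog %s)",
                     bundle$n, bundle$catalog_version %||% "unknown"),
             "", "Per-endpoint denominators (complete-case):")
  for (e in bundle$endpoints) {
    lines <- c(lines, sprintf("  %-28s n = %d", e$endpoint_id, e$n))
  }
  maa <- bundle$qc$missing_as_absent
  lines <- c(lines, "", "Missing-as-absent substitutions at ingestion:")
  if (length(maa) == 0L || sum(unlist(maa)) == 0) {
    lines <- c(lines, "  none")
  } else {
    for (f in names(maa)) {
      if (maa[[f]] > 0) lines <- c(lines, sprintf("  %-24s %d", f, maa[[f]]))
    }
  }
  lines <- c(lines, "", sprintf("Catalog QC: %d unmapped agent reference(s)",
                                nrow(bundle$qc$catalog)))
  na_qc <- bundle$qc$no_antibiotic
  lines <- c(lines, sprintf(
    "NO_ANTIBIOTIC QC: %d empty recommendation regimen(s), %d flagged",
    nrow(na_qc), sum(na_qc$flagged)))
  lines
}

#' Render a results bundle as a human-readable report
#'
#' Markdown-flavoured text: the endpoint table, the Holm family, concordance
#' counts and QC notes. Errors on a bundle whose schema tag is missing or
#' unknown.
#'
#' @param bundle_list a parsed \code{results.json} (list) or a
#'   \code{results_bundle}.
#' @return character vector of report lines.
#' @export
render_report <- function(bundle_list) {
  if (inherits(bundle_list, "results_bundle")) {
    bundle_list <- bundle_to_list(bundle_list)
  }
  if (is.null(bundle_list$schema) ||
      !identical(bundle_list$schema, BUNDLE_SCHEMA_VERSION)) {
    sp_stop(sprintf("unsupported results schema: %s",
                    bundle_list$schema %||% "<missing>"),
            "stewardpair_validation_error")
  }
  if (length(bundle_list$endpoints) == 0L) {
    sp_stop("results bundle contains no endpoints",
            "stewardpair_validation_error")
  }
  fmtnum <- function(x) if (is.null(x) || !length(x) || is.na(x)) "NA" else format(signif(x, 3))
  lines <- c(sprintf("# Paired stewardship benchmarking report (N = %d)",
                     bundle_list$n), "")
  lines <- c(lines, "## Endpoints", "")
  for (e in bundle_list$endpoints) {
    if (!is.null(e$or_result)) {
      o <- e$or_result
      lines <- c(lines, sprintf(
        "- %s (N = %d): matched OR %.3f (95%% CI %.3f-%.3f), RD %.3f, exact McNemar p = %s",
        e$endpoint_id, e$n, o$or_hat, o$ci_low, o$ci_high, o$rd,
        fmtnum(o$p_exact)))
    } else if (!is.null(e$delta_summary)) {
      s <- e$delta_summary
      lines <- c(lines, sprintf(
        "- %s (N = %d): median %s (IQR %s to %s), -/0/+ = %d/%d/%d, Wilcoxon p = %s, sign p = %s",
        e$endpoint_id, e$n, fmtnum(s$median), fmtnum(s$q1), fmtnum(s$q3),
        s$n_neg, s$n_zero, s$n_pos, fmtnum(s$p_wilcoxon), fmtnum(s$p_sign)))
    } else {
      lines <- c(lines, sprintf("- %s: not computable (0 evaluable admissions)",
                                e$endpoint_id))
    }
  }
  lines <- c(lines, "", "## Holm-adjusted paired-delta family (m = 6)", "")
  hf <- bundle_list$holm_family
  for (i in seq_len(NROW(hf))) {
    lines <- c(lines, sprintf("- %s: raw p = %s, Holm-adjusted p = %s",
                              hf$endpoint_id[i], fmtnum(hf$raw_p[i]),
                              fmtnum(hf$adjusted_p[i])))
  }
  cc <- bundle_list$concordance
  lines <- c(lines, "", "## Concordance", "",
             sprintf("- identical agent sets: %d/%d", cc$n_identical_set, cc$n),
             sprintf("- same primary agent: %d/%d", cc$n_same_primary_agent,
                     cc$n),
             sprintf("- any overlap: %d/%d", cc$n_any_overlap, cc$n),
             sprintf("- no overlap: %d/%d", cc$n_no_overlap, cc$n))
  na_qc <- bundle_list$qc$no_antibiotic
  lines <- c(lines, "", "## QC", "",
             sprintf("- unmapped agent references: %d",
                     NROW(bundle_list$qc$catalog)),
             sprintf("- NO_ANTIBIOTIC recommendations: %d (%d flagged)",
                     NROW(na_qc),
                     if (NROW(na_qc)) sum(na_qc$flagged) else 0L))
  lines
}
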