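# Antibiotic agent catalog: the locked dictionary every downstream mapping
# (class flags, AWaRe, DDD, cost) depends on.

#' Load and validate an antibiotic agent catalog
#'
#' Reads a delimited catalog file (CSV, or TSV when the header line contains a
#' tab) and validates every row: unique non-empty codes, boolean class flags
#' encoded 0/1, a known AWaRe class, a positive DDD reference (grams/day) and a
#' non-negative unit cost (EUR per day at DDD). Codes are upper-cased and
#' trimmed on load so lookups are case-insensitive.
#'
#' Carbapenems are pharmacologically antipseudomonal, but the guardrail
#' components are evaluated as disjoint indicators: a carbapenem row must set
#' only \code{is_carbapenem} so it never co-triggers the antipseudomonal
#' component. Set \code{allow_carb_aps_overlap = TRUE} to accept rows carrying
#' both flags (for testing the alternative convention).
#'
#' @param path path to a CSV/TSV file with columns \code{code, display_name,
#'   is_carbapenem, is_antipseudomonal, is_anti_mrsa, aware_class, ddd_ref_g,
#'   unit_cost_eur}.
#' @param version_tag free-text tag stored on the catalog.
#' @param allow_carb_aps_overlap allow rows flagged both carbapenem and
#'   antipseudomonal (default \code{FALSE}).
#' @return an \code{agent_catalog}: a data.frame keyed by \code{code} with the
#'   class flags as logicals.
#' @seealso [default_catalog()], [resolve_agent()], [catalog_qc()]
#' @export
load_catalog <- function(path, version_tag = basename(path),
                         allow_carb_aps_overlap = FALSE) {
  if (!file.exists(path)) {
    sp_stop(sprintf("catalog file not found: %s", path), "stewardpair_io_error")
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  strip.white = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    sp_stop(sprintf("catalog is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "stewardpair_validation_error")
  }
  as_catalog(raw[CATALOG_COLUMNS], version_tag = version_tag,
             allow_carb_aps_overlap = allow_carb_aps_overlap)
}

# Validate a raw catalog data.frame and stamp the class. Shared by
# load_catalog() and in-code catalog construction in tests.
as_catalog <- function(df, version_tag = "in-memory",
                       allow_carb_aps_overlap = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$code <- toupper(trimws(as.character(df$code)))
  bad_row <- function(i, what) {
    sp_stop(sprintf("catalog row %d (code '%s'): %s", i, df$code[i], what),
            "stewardpair_validation_error")
  }
  if (any(!nzchar(df$code))) {
    sp_stop(sprintf("catalog row %d has an empty code",
                    which(!nzchar(df$code))[1L]),
            "stewardpair_validation_error")
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0L) {
    sp_stop(sprintf("duplicate catalog code(s): %s",
                    paste(unique(dup), collapse = ", ")),
            "stewardpair_validation_error")
  }
  for (fl in c("is_carbapenem", "is_antipseudomonal", "is_anti_mrsa")) {
    v <- df[[fl]]
    ok <- (is.logical(v) & !is.na(v)) | (v %in% c(0, 1))
    if (any(!ok)) bad_row(which(!ok)[1L], sprintf("%s must be 0/1", fl))
    df[[fl]] <- as.logical(as.integer(v))
  }
  df$aware_class <- toupper(trimws(as.character(df$aware_class)))
  bad_aware <- which(!df$aware_class %in% AWARE_LEVELS)
  if (length(bad_aware) > 0L) {
    bad_row(bad_aware[1L], sprintf("unknown AWaRe label '%s' (expected %s)",
                                   df$aware_class[bad_aware[1L]],
                                   paste(AWARE_LEVELS, collapse = "/")))
  }
  df$ddd_ref_g <- as.numeric(df$ddd_ref_g)
  bad_ddd <- which(!is.finite(df$ddd_ref_g) | df$ddd_ref_g <= 0)
  if (length(bad_ddd) > 0L) bad_row(bad_ddd[1L], "ddd_ref_g must be > 0")
  df$unit_cost_eur <- as.numeric(df$unit_cost_eur)
  bad_cost <- which(!is.finite(df$unit_cost_eur) | df$unit_cost_eur < 0)
  if (length(bad_cost) > 0L) bad_row(bad_cost[1L], "unit_cost_eur must be >= 0")
  both <- which(df$is_carbapenem & df$is_antipseudomonal)
  if (length(both) > 0L && !allow_carb_aps_overlap) {
    bad_row(both[1L], paste0(
      "flagged both carbapenem and antipseudomonal; the guardrail components ",
      "are disjoint (set allow_carb_aps_overlap = TRUE to permit this)"))
  }
  rownames(df) <- df$code
  attr(df, "version_tag") <- version_tag
  class(df) <- c("agent_catalog", "data.frame")
  df
}

#' The catalog shipped with the package
#'
#' Roughly 25 common inpatient antibacterial agents with class flags, WHO
#' AWaRe class (2023 list) and DDD reference values in the WHO ATC/DDD style
#' (parenteral route where that is the typical inpatient form). Unit costs are
#' a synthetic price list for demonstration, not an institutional tariff.
#' All mappings are reference data and can be overridden by loading a user
#' catalog with [load_catalog()].
#'
#' @return an \code{agent_catalog}.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "agent_catalog.csv",
                           package = "stewardpair"),
               version_tag = "stewardpair-default-1")
}

#' Resolve an agent code against a catalog
#'
#' Lookup is case-insensitive and whitespace-trimmed. An unknown code raises a
#' condition of class \code{stewardpair_unmapped_agent} carrying the offending
#' code, which [catalog_qc()] consumes.
#'
#' @param catalog an \code{agent_catalog}.
#' @param code agent code (scalar character).
#' @return the matching catalog record as a named list.
#' @export
resolve_agent <- function(catalog, code) {
  key <- toupper(trimws(code))
  i <- match(key, rownames(catalog))
  if (is.na(i)) {
    sp_stop(sprintf("unmapped antibiotic agent code: '%s'", code),
            "stewardpair_unmapped_agent", agent_code = key)
  }
  as.list(catalog[i, , drop = FALSE])
}

#' Catalog quality-control over a cohort
#'
#' Lists every (admission id, arm, code) in the cohort whose agent code does
#' not resolve in the catalog. An empty report means the mapping QC passes;
#' the analysis pipeline refuses to compute endpoints otherwise.
#'
#' @param cohort a \code{steward_cohort} (see [read_cohort()]).
#' @param catalog an \code{agent_catalog}.
#' @return data.frame with columns \code{admission_id}, \code{arm},
#'   \code{code}; zero rows on pass.
#' @export
catalog_qc <- function(cohort, catalog) {
  known <- rownames(catalog)
  collect <- function(arm_col, arm) {
    codes <- lapply(cohort[[arm_col]], function(r) r$code)
    n_each <- lengths(codes)
    flat <- toupper(trimws(unlist(codes, use.names = FALSE)))
    if (length(flat) == 0L) {
      return(data.frame(admission_id = character(), arm = character(),
                        code = character(), stringsAsFactors = FALSE))
    }
    ids <- rep(cohort$admission_id, n_each)
    bad <- !(flat %in% known)
    data.frame(admission_id = ids[bad], arm = rep(arm, sum(bad)),
               code = flat[bad], stringsAsFactors = FALSE)
  }
  out <- rbind(collect("clin_regimen", "CLIN"), collect("llm_regimen", "LLM"))
  rownames(out) <- NULL
  out
}
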