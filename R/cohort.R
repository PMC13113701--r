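# Cohort container and file formats.
#
# A cohort is one row per admission: de-identified structured context flags,
# the two paired regimens (list-columns of regimen data.frames), the 72 h
# continuation flag, and the microbiology-evaluability block.

COHORT_BOOL_COLS <- c(CONTEXT_FLAGS, "female", "continued_72h",
                      "micro_evaluable")

#' Construct and validate a paired-admission cohort
#'
#' Normalises and validates a data.frame of admissions. Context flags absent
#' from the input or containing NA are coerced to FALSE (the missing-as-absent
#' rule); substitution counts per field are recorded in the
#' \code{"missing_as_absent"} attribute. Microbiology coverage fields must be
#' present (0/1) exactly when \code{micro_evaluable} is TRUE and NA otherwise.
#'
#' @param df data.frame with columns \code{admission_id}, the context flags,
#'   \code{clin_regimen} and \code{llm_regimen} (list-columns of
#'   [regimen()]s), \code{continued_72h}, \code{micro_evaluable},
#'   \code{clin_covered}, \code{llm_covered}, and optional covariates
#'   (\code{syndrome}, \code{age_years}, \code{female}, \code{year}).
#' @return a \code{steward_cohort}.
#' @export
steward_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$admission_id) || anyNA(df$admission_id)) {
    sp_stop("cohort requires a complete admission_id column",
            "stewardpair_validation_error")
  }
  df$admission_id <- as.character(df$admission_id)
  if (anyDuplicated(df$admission_id)) {
    sp_stop("duplicate admission_id in cohort", "stewardpair_validation_error")
  }
  for (col in c("clin_regimen", "llm_regimen")) {
    if (is.null(df[[col]]) || !is.list(df[[col]])) {
      sp_stop(sprintf("cohort requires list-column '%s'", col),
              "stewardpair_validation_error")
    }
  }
  substituted <- integer(0)
  for (col in COHORT_BOOL_COLS) {
    v <- df[[col]]
    if (is.null(v)) {
      substituted[col] <- nrow(df)
      df[[col]] <- rep(FALSE, nrow(df))
    } else {
      v <- as.logical(v)
      n_na <- sum(is.na(v))
      if (n_na > 0L) substituted[col] <- n_na
      v[is.na(v)] <- FALSE
      df[[col]] <- v
    }
  }
  for (col in c("clin_covered", "llm_covered")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_integer_, nrow(df))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  ev <- df$micro_evaluable
  miss_cov <- ev & (is.na(df$clin_covered) | is.na(df$llm_covered))
  if (any(miss_cov)) {
    sp_stop(sprintf(
      "admission %s is microbiology-evaluable but lacks a coverage field",
      df$admission_id[which(miss_cov)[1L]]),
      "stewardpair_validation_error")
  }
  df$clin_covered[!ev] <- NA_integer_
  df$llm_covered[!ev] <- NA_integer_
  if (any(ev & (!df$clin_covered %in% c(0L, 1L) |
                !df$llm_covered %in% c(0L, 1L)))) {
    sp_stop("coverage fields must be binary 0/1 on evaluable admissions",
            "stewardpair_validation_error")
  }
  attr(df, "missing_as_absent") <- substituted
  class(df) <- c("steward_cohort", "data.frame")
  df
}

#' @export
print.steward_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "steward_cohort: %d paired admissions\n",
    "  72 h continued-therapy subset: %d\n",
    "  microbiology-evaluable subset: %d\n",
    "  empty recommendation regimens (NO_ANTIBIOTIC): %d\n"),
    nrow(x), sum(x$continued_72h), sum(x$micro_evaluable),
    sum(vapply(x$llm_regimen, nrow, integer(1L)) == 0L)))
  invisible(x)
}

# "CODE@dose_g;CODE@dose_g" <-> regimen
encode_regimen <- function(r) {
  if (nrow(r) == 0L) return("")
  paste(sprintf("%s@%s", r$code, format(r$dose_g, trim = TRUE,
                                        scientific = FALSE)),
        collapse = ";")
}

decode_regimen <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(regimen())
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  pieces <- strsplit(parts, "@", fixed = TRUE)
  bad <- lengths(pieces) != 2L
  if (any(bad)) {
    sp_stop(sprintf("malformed regimen token '%s' (expected CODE@dose_g)",
                    parts[bad][1L]),
            "stewardpair_validation_error")
  }
  codes <- vapply(pieces, `[[`, "", 1L)
  doses <- suppressWarnings(as.numeric(vapply(pieces, `[[`, "", 2L)))
  if (anyNA(doses)) {
    sp_stop(sprintf("non-numeric dose in regimen token '%s'",
                    parts[which(is.na(doses))[1L]]),
            "stewardpair_validation_error")
  }
  regimen(codes, doses)
}

COHORT_SCALAR_COLS <- c("admission_id", CONTEXT_FLAGS, "syndrome",
                        "age_years", "female", "year", "continued_72h",
                        "micro_evaluable", "clin_covered", "llm_covered")

#' Read a cohort file (CSV or JSON)
#'
#' CSV: one row per admission, regimens encoded as semicolon-delimited
#' \code{CODE@dose_g} tokens in columns \code{clin_regimen} /
#' \code{llm_regimen}, booleans as 0/1 (blank or absent = FALSE, logged).
#' JSON: an array of admission objects with nested regimen records (as written
#' by [write_cohort()]). The format is chosen by file extension.
#'
#' @param path input file.
#' @return a \code{steward_cohort}; the \code{"missing_as_absent"} attribute
#'   counts missing-as-absent substitutions per context field.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    sp_stop(sprintf("cohort file not found: %s", path), "stewardpair_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                               simplifyVector = TRUE)
    df <- recs
    df$clin_regimen <- lapply(recs$clin_regimen, function(r) {
      if (is.null(r) || length(r) == 0L || NROW(r) == 0L) regimen()
      else regimen(r$code, r$dose_g)
    })
    df$llm_regimen <- lapply(recs$llm_regimen, function(r) {
      if (is.null(r) || length(r) == 0L || NROW(r) == 0L) regimen()
      else regimen(r$code, r$dose_g)
    })
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (col in c("clin_regimen", "llm_regimen")) {
      if (is.null(raw[[col]])) {
        sp_stop(sprintf("cohort file lacks required column '%s'", col),
                "stewardpair_io_error")
      }
    }
    df <- raw
    df$clin_regimen <- lapply(raw$clin_regimen, decode_regimen)
    df$llm_regimen <- lapply(raw$llm_regimen, decode_regimen)
    # blank cells in boolean columns arrive as NA; steward_cohort() applies
    # (and logs) missing-as-absent
    for (col in c("clin_covered", "llm_covered")) {
      if (!is.null(df[[col]])) {
        v <- df[[col]]
        v[v %in% c("", NA)] <- NA
        df[[col]] <- v
      }
    }
  }
  steward_cohort(df)
}

#' Write a cohort file (CSV or JSON, by extension)
#'
#' @param cohort a \code{steward_cohort}.
#' @param path output file; \code{.json} selects the nested JSON schema,
#'   anything else the flat CSV schema of [read_cohort()].
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- as.data.frame(cohort)[intersect(COHORT_SCALAR_COLS,
                                            names(cohort))]
    recs$clin_regimen <- lapply(cohort$clin_regimen, as.data.frame)
    recs$llm_regimen <- lapply(cohort$llm_regimen, as.data.frame)
    jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA,
                         na = "null", dataframe = "rows")
  } else {
    flat <- as.data.frame(cohort)[intersect(COHORT_SCALAR_COLS,
                                            names(cohort))]
    for (col in intersect(COHORT_BOOL_COLS, names(flat))) {
      flat[[col]] <- as.integer(flat[[col]])
    }
    flat$clin_regimen <- vapply(cohort$clin_regimen, encode_regimen, "")
    flat$llm_regimen <- vapply(cohort$llm_regimen, encode_regimen, "")
    write.csv(flat, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
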