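# Paired inference battery: exact McNemar, matched OR with continuity
# correction, sign test, Wilcoxon signed-rank, seeded bootstrap median CI,
# and Holm step-down adjustment.

#' Construct a paired 2x2 table
#'
#' Counts of joint paired binary outcomes. The first index is the clinician
#' outcome, the second the recommendation-arm outcome, 1 = event: \code{n01}
#' counts pairs with clinician = 0 and recommendation = 1, \code{n10} the
#' reverse. The discordant count is \code{n01 + n10}.
#'
#' @param n00,n01,n10,n11 non-negative integer counts.
#' @return a \code{paired_table}.
#' @export
paired_table <- function(n00, n01, n10, n11) {
  counts <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    sp_stop("paired table counts must be non-negative integers",
            "stewardpair_validation_error")
  }
  counts <- as.integer(counts)
  structure(list(n00 = counts[1L], n01 = counts[2L], n10 = counts[3L],
                 n11 = counts[4L]),
            class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  m <- matrix(c(x$n00, x$n01, x$n10, x$n11), 2L, byrow = TRUE,
              dimnames = list(clin = c("0", "1"), rec = c("0", "1")))
  cat(sprintf("Paired 2x2 table (N = %d, discordant = %d)\n",
              x$n00 + x$n01 + x$n10 + x$n11, x$n01 + x$n10))
  print(m)
  invisible(x)
}

#' Tally paired binary outcomes into a 2x2 table
#'
#' @param clin,llm equal-length binary (0/1 or logical) vectors: the event
#'   indicator per admission in the clinician and recommendation arms.
#' @return a \code{paired_table}; empty input gives the all-zero table.
#' @export
build_paired_table <- function(clin, llm) {
  clin <- as_binary(clin, "clin")
  llm <- as_binary(llm, "llm")
  if (length(clin) != length(llm)) {
    sp_stop("paired outcome vectors must have equal length",
            "stewardpair_validation_error")
  }
  paired_table(n00 = sum(clin == 0L & llm == 0L),
               n01 = sum(clin == 0L & llm == 1L),
               n10 = sum(clin == 1L & llm == 0L),
               n11 = sum(clin == 1L & llm == 1L))
}

as_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  x <- as.numeric(x)
  if (anyNA(x) || any(!x %in% c(0, 1))) {
    sp_stop(sprintf("'%s' must be binary (0/1) with no missing values", what),
            "stewardpair_validation_error")
  }
  as.integer(x)
}

#' Matched odds ratio with continuity correction
#'
#' For a paired 2x2 table, the matched OR is estimated from the discordant
#' counts with a 0.5 continuity correction,
#' \eqn{\hat{OR} = (n_{01}+0.5)/(n_{10}+0.5)}, with a Wald 95\% CI on the log
#' scale using standard error
#' \eqn{\sqrt{1/(n_{01}+0.5) + 1/(n_{10}+0.5)}}. Also returns the paired risk
#' difference (recommendation-arm event rate minus clinician event rate) and
#' the exact McNemar p-value. Values are full precision; round only for
#' display.
#'
#' @param t a [paired_table()].
#' @return a \code{matched_or_result}: list with \code{or_hat}, \code{ci_low},
#'   \code{ci_high}, \code{rd}, \code{p_exact}.
#' @export
matched_odds_ratio <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  N <- t$n00 + t$n01 + t$n10 + t$n11
  if (N == 0L) {
    sp_stop("risk difference undefined: table has N = 0",
            "stewardpair_validation_error")
  }
  a <- t$n01 + 0.5
  b <- t$n10 + 0.5
  or_hat <- a / b
  se <- sqrt(1 / a + 1 / b)
  rd <- (t$n01 + t$n11) / N - (t$n10 + t$n11) / N
  structure(list(or_hat = or_hat,
                 ci_low = exp(log(or_hat) - 1.96 * se),
                 ci_high = exp(log(or_hat) + 1.96 * se),
                 rd = rd,
                 p_exact = mcnemar_exact(t)),
            class = "matched_or_result")
}

#' Exact McNemar test
#'
#' Two-sided exact binomial test on discordant pairs: with
#' \eqn{d = n_{01} + n_{10}} and \eqn{k = \min(n_{01}, n_{10})},
#' \eqn{p = \min(1,\; 2 P[X \le k])} for \eqn{X \sim \mathrm{Bin}(d, 1/2)}
#' (the doubled-smaller-tail convention). With no discordant pairs, p = 1.
#'
#' @param t a [paired_table()].
#' @return p-value in (0, 1].
#' @export
mcnemar_exact <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  d <- t$n01 + t$n10
  if (d == 0L) return(1)
  min(1, 2 * pbinom(min(t$n01, t$n10), d, 0.5))
}

#' Exact sign test on paired deltas
#'
#' Zero differences are excluded; the test is the two-sided exact binomial on
#' the non-tied count \eqn{m = n_- + n_+} with \eqn{k = \min(n_-, n_+)}:
#' \eqn{p = \min(1, 2 P[X \le k])}, \eqn{X \sim \mathrm{Bin}(m, 1/2)}. With no
#' non-tied pairs the test carries no information and returns p = 1 with a
#' warning.
#'
#' @param deltas numeric vector of paired differences.
#' @return list with \code{p}, \code{n_neg}, \code{n_pos}, \code{n_zero}.
#' @export
sign_test <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (anyNA(deltas)) {
    sp_stop("deltas must not contain missing values",
            "stewardpair_validation_error")
  }
  n_neg <- sum(deltas < 0)
  n_pos <- sum(deltas > 0)
  n_zero <- sum(deltas == 0)
  m <- n_neg + n_pos
  if (m == 0L) {
    warning("sign test: all differences are zero; no information (p = 1)")
    return(list(p = 1, n_neg = n_neg, n_pos = n_pos, n_zero = n_zero))
  }
  p <- min(1, 2 * pbinom(min(n_neg, n_pos), m, 0.5))
  list(p = p, n_neg = n_neg, n_pos = n_pos, n_zero = n_zero)
}

#' Wilcoxon signed-rank test for paired deltas
#'
#' Zero differences are dropped (Wilcoxon's original handling) and tied
#' absolute magnitudes receive midranks. When the number of non-zero
#' differences is at most \code{exact_limit}, the exact two-sided p-value is
#' computed from the full sign-flip null distribution (dynamic programming on
#' doubled ranks, so midranks stay integral); otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used. Two-sided
#' throughout.
#'
#' @param deltas numeric vector of paired differences, at least one non-zero.
#' @param exact_limit maximum non-zero count for exact enumeration
#'   (default 25).
#' @return p-value in (0, 1].
#' @export
wilcoxon_signed_rank <- function(deltas, exact_limit = 25L) {
  deltas <- as.numeric(deltas)
  if (anyNA(deltas)) {
    sp_stop("deltas must not contain missing values",
            "stewardpair_validation_error")
  }
  nz <- deltas[deltas != 0]
  n <- length(nz)
  if (n == 0L) {
    sp_stop("Wilcoxon signed-rank is degenerate: all differences are zero",
            "stewardpair_degenerate_input")
  }
  r <- rank(abs(nz))  # midranks
  W <- sum(r[nz > 0])
  if (n <= exact_limit) {
    # Exact null: W2 = sum of doubled ranks of positive deltas over all 2^n
    # equiprobable sign assignments. Doubled midranks are integers, so the
    # distribution is a table over 0..sum(2r).
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (w in r2) {
      g <- f
      g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] + f[1L:(total + 1L - w)]
      f <- g
    }
    w2 <- sum(r2[nz > 0])
    mu2 <- total / 2
    dev <- abs(w2 - mu2)
    support <- 0:total
    p <- sum(f[abs(support - mu2) >= dev - 1e-9]) / 2^n
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# Run a block of code with a private RNG stream, restoring the caller's
# .Random.seed afterwards so seeded internals do not perturb user simulations.
with_private_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Seeded percentile bootstrap CI for the median
#'
#' Resamples admissions with replacement (\code{n_boot} replicates, default
#' 5000, default seed 7), computing the median of each resample, and returns
#' the 2.5\% and 97.5\% percentiles of the replicate medians. One seeded
#' generator draws n indices per replicate, replicates in order, so the
#' interval is reproducible for identical (input order, n_boot, seed). The
#' caller's RNG state is left untouched.
#'
#' @param deltas non-empty numeric vector.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed for the private bootstrap stream.
#' @return numeric \code{c(low, high)}.
#' @export
bootstrap_median_ci <- function(deltas, n_boot = 5000L, seed = 7L) {
  deltas <- as.numeric(deltas)
  n <- length(deltas)
  if (n == 0L) {
    sp_stop("bootstrap_median_ci: empty input", "stewardpair_validation_error")
  }
  meds <- with_private_rng(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(j) median(deltas[idx[, j]]), numeric(1L))
  })
  unname(quantile(meds, c(0.025, 0.975), type = 7))
}

#' Holm step-down adjustment
#'
#' Standard step-down: sort p-values ascending, multiply the i-th smallest by
#' (m - i + 1), enforce monotone non-decrease, cap at 1, return in the
#' original order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1] (NA allowed; NA
#'   entries are returned as NA and still count towards m).
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    sp_stop("p-values must lie in [0, 1]", "stewardpair_validation_error")
  }
  m <- length(p)
  out <- rep(NA_real_, m)
  idx <- which(ok)
  o <- idx[order(p[idx])]
  ranks <- seq_along(o)
  out[o] <- pmin(1, cummax((m - ranks + 1) * p[o]))
  out
}

#' Summary of a paired delta distribution
#'
#' Median and quartiles (linear interpolation, type 7), mean, sample SD
#' (n - 1), sign counts, sign-test and Wilcoxon p-values, and optionally the
#' seeded bootstrap CI for the median. If every delta is zero the Wilcoxon
#' test is degenerate and \code{p_wilcoxon} is NA (with a warning).
#'
#' @param deltas non-empty numeric vector of paired differences.
#' @param with_bootstrap compute the bootstrap median CI (default FALSE).
#' @param n_boot,seed bootstrap settings, see [bootstrap_median_ci()].
#' @return a \code{paired_delta_summary} list.
#' @export
delta_summary <- function(deltas, with_bootstrap = FALSE, n_boot = 5000L,
                          seed = 7L) {
  deltas <- as.numeric(deltas)
  if (length(deltas) == 0L) {
    sp_stop("delta_summary: empty input", "stewardpair_validation_error")
  }
  st <- suppressWarnings(sign_test(deltas))
  p_w <- if (all(deltas == 0)) {
    warning("delta_summary: all deltas zero; Wilcoxon p is NA")
    NA_real_
  } else {
    wilcoxon_signed_rank(deltas)
  }
  q <- unname(quantile(deltas, c(0.25, 0.5, 0.75), type = 7))
  ci <- if (with_bootstrap) bootstrap_median_ci(deltas, n_boot, seed) else c(NA_real_, NA_real_)
  structure(list(n = length(deltas),
                 n_neg = st$n_neg, n_pos = st$n_pos, n_zero = st$n_zero,
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 mean = mean(deltas),
                 sd = if (length(deltas) > 1L) sd(deltas) else NA_real_,
                 p_wilcoxon = p_w, p_sign = st$p,
                 ci_median_low = ci[1L], ci_median_high = ci[2L]),
            class = "paired_delta_summary")
}
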