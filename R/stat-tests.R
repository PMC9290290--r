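#' Two-sided Fisher exact test on a 2x2 table of read counts
#'
#' Exact conditional test of independence for a 2x2 contingency table,
#' the workhorse behind differential-expression calls on pooled counts and
#' the hybrid-vs-mid-parent pattern tests. The two-sided p-value uses the
#' probability-ordering definition: conditioning on the margins, it sums the
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed that of the observed table. This differs from doubling the
#' smaller tail for asymmetric margins, and matches `stats::fisher.test()`.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`. Vectors are recycled to a common length and
#'   a p-value is returned per table.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @details An all-zero table carries no information; its p-value is 1 and a
#'   warning is raised. Typical use pits a gene's pooled count against the
#'   remainder of the library in each of two conditions.
#' @examples
#' fisher_exact_counts(5, 5, 5, 5)   # balanced -> 1
#' fisher_exact_counts(10, 0, 0, 10) # 2 / choose(20, 10)
#' @export
fisher_exact_counts <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)) || any(!is.finite(cells))) {
    stop_hetexpr("all cells of a 2x2 table must be non-negative integers",
                 "hetexpr_invalid_table")
  }
  if (any(rowSums(cells) == 0)) {
    warn("all-zero 2x2 table(s): p-value set to 1")
  }
  vapply(seq_len(n), function(i) {
    .fisher_p_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

# single-table probability-ordering p via the hypergeometric density
.fisher_p_one <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2)
  hi <- min(c1, r1)
  dens <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(dens[dens <= p_obs * (1 + .prob_order_eps)]))
}

#' Two-sided exact binomial test
#'
#' Exact test of a binomial proportion against `p0`, used per SNP to test
#' allelic read counts in a hybrid against the 0.5 balanced-expression null.
#' Two-sided p-values use probability ordering: all outcomes whose point
#' probability does not exceed that of the observed count are summed
#' (matching `stats::binom.test()`). The mid-p variant subtracts half the
#' observed outcome's probability, trading exactness for reduced
#' conservatism on discrete counts.
#'
#' @param k Observed successes (e.g. reads carrying one parental allele).
#'   Vectorised; recycled against `n`.
#' @param n Number of trials (total reads at the SNP), `n >= 1`.
#' @param p0 Null proportion, default 0.5.
#' @param midp If `TRUE`, return the mid-p value.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' binom_two_sided(5, 10)          # 1
#' binom_two_sided(10, 10)         # 2 * 0.5^10
#' @export
binom_two_sided <- function(k, n, p0 = 0.5, midp = FALSE) {
  m <- max(length(k), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m)
  if (any(n < 1) || any(k < 0) || any(k > n) ||
      any(k != floor(k)) || any(n != floor(n))) {
    stop_hetexpr("need integer 0 <= k <= n with n >= 1",
                 "hetexpr_invalid_counts")
  }
  check_prob(p0, "p0")
  vapply(seq_len(m), function(i) {
    dens <- dbinom(0:n[i], n[i], p0)
    p_obs <- dens[k[i] + 1]
    p <- sum(dens[dens <= p_obs * (1 + .prob_order_eps)])
    if (midp) p <- p - 0.5 * p_obs
    min(1, p)
  }, numeric(1))
}

#' Adjust p-values for multiple testing (Benjamini-Hochberg / Yekutieli)
#'
#' Step-up false-discovery-rate control. BH assumes independence or positive
#' dependence across tests; BY adds the `sum(1/k)` penalty and is valid under
#' arbitrary dependence (used here for term-enrichment families, where the
#' gene sets overlap heavily). Thin wrapper over [stats::p.adjust()], which
#' implements exactly these step-up rules.
#'
#' @param p Data frame with a `p` column, or a bare numeric vector of
#'   p-values in \[0, 1\].
#' @param method `"BH"` or `"BY"`.
#' @return If `p` was a data frame, the same frame with `q` and
#'   `fdr_method` columns appended; otherwise a numeric vector of q-values.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))        # all 0.04
#' adjust_fdr(c(0.01, 0.04), method = "BY")     # 0.03 0.06
#' @export
adjust_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (is.data.frame(p)) {
    if (!"p" %in% names(p)) {
      stop_hetexpr("data-frame input must have a `p` column",
                   "hetexpr_missing_column")
    }
    pv <- p[["p"]]
  } else {
    pv <- p
  }
  if (any(is.na(pv))) {
    bad <- which(is.na(pv))
    stop_hetexpr(
      sprintf("NA/NaN p-values at positions: %s",
              paste(head(bad, 10), collapse = ", ")),
      "hetexpr_na_pvalue"
    )
  }
  check_prob(pv, "p")
  q <- p.adjust(pv, method = method)
  if (is.data.frame(p)) {
    p$q <- q
    p$fdr_method <- method
    p
  } else {
    q
  }
}

#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test (default) or Student's pooled-variance
#' test, computed from group means, standard deviations and sizes. Used for
#' trait comparisons where only summary rows (mean +/- SD per environment)
#' are available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param pooled If `TRUE`, use Student's pooled-variance test instead of
#'   Welch's.
#' @return A tibble with columns `t`, `df`, `p` (two-sided). Vectorised over
#'   its arguments.
#' @details If both SDs are zero the statistic is degenerate: equal means
#'   give `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#' @examples
#' welch_t(1, 1, 100, 0, 1, 100) # t = 1/sqrt(0.02), df = 198
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  m <- max(length(mean1), length(mean2))
  mean1 <- rep_len(mean1, m); sd1 <- rep_len(sd1, m); n1 <- rep_len(n1, m)
  mean2 <- rep_len(mean2, m); sd2 <- rep_len(sd2, m); n2 <- rep_len(n2, m)
  if (any(n1 < 2) || any(n2 < 2)) {
    stop_hetexpr("need n >= 2 in both groups", "hetexpr_invalid_counts")
  }
  if (any(sd1 < 0) || any(sd2 < 0)) {
    stop_hetexpr("standard deviations must be >= 0", "hetexpr_invalid_sd")
  }
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  # degenerate zero-variance cases
  zero <- se == 0
  t[zero & mean1 == mean2] <- 0
  t[zero & mean1 > mean2] <- Inf
  t[zero & mean1 < mean2] <- -Inf
  df[zero] <- n1[zero] + n2[zero] - 2
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), 0)
  p[zero & mean1 == mean2] <- 1
  tibble(t = t, df = df, p = p)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p) {
  check_prob(p[!is.na(p)], "p")
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
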