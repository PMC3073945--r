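#' Chi-square goodness of fit against model-derived expectations
#'
#' Pearson chi-square of observed class counts against expected class
#' probabilities: `X^2 = sum((O - E)^2 / E)` with `E = N * p`, `df = k - 1`,
#' upper-tail p-value. No continuity correction is applied at any count:
#' published segregation chi-squares in this literature use the uncorrected
#' statistic (the 140/328 vs 3:5 benchmark gives 11.489 uncorrected but
#' about 11.17 with the Yates correction).
#'
#' @param observed non-negative integer class counts.
#' @param expected_probs expected class probabilities, summing to 1.
#' @return A `chisq_gof` object: `statistic`, `df`, `p.value`, plus the
#'   observed and expected counts.
#' @examples
#' chisq_gof(c(140, 328), c(3, 5) / 8)   # X^2 = 11.489, p = 7e-04
#' chisq_gof(c(17, 63), c(1, 2) / 3)     # p = 0.0218
#' @export
chisq_gof <- function(observed, expected_probs) {
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  if (length(observed) != length(expected_probs)) {
    stop("observed and expected_probs must have the same length",
         call. = FALSE)
  }
  if (abs(sum(expected_probs) - 1) > 1e-9) {
    stop("expected_probs must sum to 1", call. = FALSE)
  }
  n <- sum(observed)
  if (n == 0) stop("no observations", call. = FALSE)
  expected <- n * expected_probs
  if (any(expected <= 0)) {
    stop("degenerate expectation: every expected count must be positive",
         call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat("Chi-square goodness of fit (no continuity correction)\n")
  cat(sprintf("  X-squared = %.3f, df = %d, p = %s\n",
              x$statistic, x$df, format_pval(x$p.value)))
  invisible(x)
}

# Wilson score interval for a binomial proportion; stable near 0 and 1,
# unlike the Wald interval which collapses at the small TEs seen in
# male co-transmission data.
wilson_ci <- function(x, n, conf.level = 0.95) {
  stopifnot(x >= 0, n > 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Transmission efficiency from resistant/sensitive counts
#'
#' The transmission efficiency (TE) of a mutant allele (or allele pair) is
#' the ratio of selection-resistant to selection-sensitive progeny from a
#' cross, `TE = R / S`; full co-transmission through a gamete gives TE = 1
#' for an outcross to wild type. Also reported as percent of total
#' seedlings, `100 R / (R + S)`. The confidence interval is a Wilson score
#' interval on the underlying proportion `R / (R + S)`, mapped to the TE
#' scale through `p / (1 - p)`.
#'
#' @param R,S counts of selection-resistant and selection-sensitive
#'   seedlings.
#' @param conf.level confidence level for the interval.
#' @return A `te_result`: `te`, `pct_of_total`, `n`, and `ci` (TE scale)
#'   with `ci_p` (proportion scale).
#' @examples
#' transmission_efficiency(161, 464)  # TE 0.347, 25.8% of total
#' @export
transmission_efficiency <- function(R, S, conf.level = 0.95) {
  if (R < 0 || S < 0 || R != round(R) || S != round(S)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- R + S
  if (n == 0) stop("no data: R and S are both zero", call. = FALSE)
  te <- if (S > 0) R / S else Inf
  ci_p <- wilson_ci(R, n, conf.level)
  structure(list(te = te, pct_of_total = 100 * R / n, n = n,
                 R = R, S = S,
                 ci = ci_p / (1 - ci_p), ci_p = ci_p,
                 conf.level = conf.level),
            class = "te_result")
}

#' @rdname transmission_efficiency
#' @param te a TE ratio.
#' @export
te_to_pct <- function(te) {
  stopifnot(te >= 0)
  ifelse(is.finite(te), 100 * te / (1 + te), 100)
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("Transmission efficiency: R/S = %d/%d\n", x$R, x$S))
  cat(sprintf("  TE = %s (%s%% of total seedlings, n = %d)\n",
              if (is.finite(x$te)) sprintf("%.4f", x$te) else "Inf",
              format(round(x$pct_of_total, 1)), x$n))
  cat(sprintf("  %d%% Wilson CI on TE: [%.4f, %s]\n",
              round(100 * x$conf.level), x$ci[["lower"]],
              if (is.finite(x$ci[["upper"]]))
                sprintf("%.4f", x$ci[["upper"]]) else "Inf"))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Unpaired t-test computed from published means, SDs and sample sizes.
#' Default is Welch's unequal-variance form with Welch-Satterthwaite
#' degrees of freedom, appropriate when groups report unequal SDs and n;
#' `pooled = TRUE` gives the classical equal-variance Student form.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param pooled use the pooled-variance (Student) form.
#' @return List with `t`, `df`, `p.value`, `estimate` (mean difference) and
#'   `method`.
#' @examples
#' # pollen-tube lengths (um): single mutant vs double mutant background
#' welch_t_summary(436.2, 136.0, 133, 178.3, 84.8, 209)
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      stop("undefined statistic: both SDs are zero and means are equal",
           call. = FALSE)
    }
    stop("undefined statistic: both SDs are zero", call. = FALSE)
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t-test, pooled variance"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t-test"
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df),
       estimate = mean1 - mean2, method = method)
}

#' Two-proportion comparison
#'
#' Pooled-variance z test comparing two independent binomial proportions
#' (e.g. karyogamy-defect frequencies in two genotypes), with per-group
#' Wilson intervals.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param conf.level confidence level for the Wilson intervals.
#' @return List with `z`, `p.value`, per-group proportions `p1`, `p2` and
#'   Wilson intervals `ci1`, `ci2`.
#' @examples
#' two_proportion_test(62, 327, 180, 418)
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf.level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2,
       ci1 = wilson_ci(x1, n1, conf.level),
       ci2 = wilson_ci(x2, n2, conf.level))
}

# report-precision helpers: p to 4 decimals, proportions to 1, matching the
# precision segregation tables are printed at; full precision kept internally
format_pval <- function(p) {
  if (p < 5e-5) "<0.0001" else sprintf("%.4f", p)
}

# half-up to one decimal, the convention of printed segregation tables
# (sprintf's round-half-even would print 17/80 as 21.2, not 21.3)
format_pct <- function(p) sprintf("%.1f", floor(1000 * p + 0.5) / 10)
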