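# Two-group comparisons as used throughout the figures: Welch's t test and
# the Mann-Whitney U test (exact by full enumeration for small samples,
# normal approximation with tie correction otherwise), two-sided, with the
# 0.05 significance convention.

# U statistic of group a against group b from mid-ranks (ties shared).
mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact two-sided p by full enumeration of all choose(m+n, m) assignments of
# the pooled mid-ranks; two-sided via |U - mn/2| as the test statistic, which
# handles ties correctly.
mw_exact_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  centre <- m * n / 2
  combos <- utils::combn(m + n, m)
  us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Normal approximation with tie-corrected variance and continuity correction.
mw_approx_p <- function(a, b) {
  m <- length(a); n <- length(b)
  u <- mw_u_stat(a, b)
  mu <- m * n / 2
  nt <- m + n
  ties <- table(c(a, b))
  sig2 <- m * n / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Compare two groups with a t or Mann-Whitney test
#'
#' Two-sided Welch (unequal-variance) t test or Mann-Whitney U test. The
#' Mann-Whitney p is exact (full enumeration of rank assignments, valid with
#' ties) when n_a + n_b <= \code{exact_max}, and the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param test "t" or "mann-whitney".
#' @param exact_max enumeration bound for the exact Mann-Whitney p.
#' @return object of class \code{stat_result}: test, statistic, p_value,
#'   n (group sizes), mean and sem per group, significant (at 0.05), method
#'   detail.
#' @export
compare_groups <- function(a, b, test = c("t", "mann-whitney"),
                           exact_max = 12) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  if (test == "t") {
    if (length(a) < 2 || length(b) < 2)
      wt_stop("Welch t needs n >= 2 per group", "validation_error", field = "a")
    if (stats::sd(c(a, b)) == 0)
      wt_stop("constant pooled data: t statistic undefined",
              "degenerate_variance_error")
    ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    stat <- unname(ht$statistic); p <- ht$p.value
    method <- "Welch two-sample t (two-sided)"
  } else {
    if (length(a) < 1 || length(b) < 1)
      wt_stop("Mann-Whitney needs n >= 1 per group", "validation_error",
              field = "a")
    stat <- mw_u_stat(a, b)
    if (length(a) + length(b) <= exact_max) {
      p <- mw_exact_p(a, b)
      method <- "Mann-Whitney U, exact (full enumeration)"
    } else {
      p <- mw_approx_p(a, b)
      method <- "Mann-Whitney U, normal approximation with tie correction"
    }
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 n = c(a = length(a), b = length(b)),
                 mean = c(a = mean(a), b = mean(b)),
                 sem = c(a = sem(a), b = sem(b)),
                 significant = p < 0.05, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n  groups: n = %d vs %d; mean +/- SEM: %.4g +/- %.4g vs %.4g +/- %.4g\n  statistic = %.4g, two-sided p = %.4g %s\n",
              x$method, x$n["a"], x$n["b"],
              x$mean["a"], x$sem["a"], x$mean["b"], x$sem["b"],
              x$statistic, x$p_value,
              if (x$significant) "(significant at 0.05)" else "(n.s.)"))
  invisible(x)
}
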