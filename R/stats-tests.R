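# Thin, uniform wrappers around the standard hypothesis tests used in the
# comparisons: every result comes back as a `test_result` with a two-sided
# p-value and an explicit degenerate flag instead of an error or a silent
# NA.

test_result <- function(test, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, n = NA_integer_, degenerate = FALSE,
                        note = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), n = n,
                 degenerate = degenerate, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate (%s), n = %d\n", x$test,
                x$note %||% "no variation", x$n))
  } else {
    cat(sprintf("%s: statistic = %.4g%s, p = %.4g, n = %d\n", x$test,
                x$statistic,
                if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
                x$p, x$n))
  }
  invisible(x)
}

#' Paired t test on a vector of differences
#'
#' \eqn{t = \bar d / (s_d / \sqrt n)} with \eqn{n - 1} degrees of freedom,
#' two-sided.  All-identical differences (zero variance) give a degenerate
#' result with an undefined p, reported as such rather than an error.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @return A \code{test_result}.
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (n < 2) stop_config("need at least 2 paired differences")
  if (stats::sd(d) == 0) {
    return(test_result("paired t", statistic = NA_real_, df = n - 1,
                       n = n, degenerate = TRUE,
                       note = sprintf("all differences equal %g", d[1])))
  }
  ht <- stats::t.test(d)
  test_result("paired t", statistic = ht$statistic, df = ht$parameter,
              p = ht$p.value, n = n)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped first (Wilcoxon's convention; the dropped
#' count is reported).  The p-value is exact for n <= 12 when the absolute
#' differences are untied, otherwise a normal approximation with midranks,
#' tie correction and continuity correction.
#'
#' @param differences Numeric vector of paired differences.
#' @return A \code{test_result}; \code{note} records dropped zeros.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[!is.na(differences)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  note <- if (n_zero) sprintf("%d zero difference(s) dropped", n_zero)
  if (n < 2) {
    return(test_result("Wilcoxon signed-rank", n = n, degenerate = TRUE,
                       note = paste(c(note, "fewer than 2 nonzero differences"),
                                    collapse = "; ")))
  }
  exact <- n <= 12 && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("Wilcoxon signed-rank", statistic = ht$statistic,
              p = ht$p.value, n = n, note = note)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact p when the smaller sample has at most 8
#' observations and the data are untied, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples.
#' @return A \code{test_result}.
#' @export
rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop_config("both samples must be non-empty")
  exact <- min(length(a), length(b)) <= 8 &&
    !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result("Wilcoxon rank-sum", statistic = ht$statistic,
              p = ht$p.value, n = length(a) + length(b))
}

#' Chi-square test of independence with Fisher escalation
#'
#' Pearson chi-square without continuity correction.  When the table is
#' 2x2 and any expected cell falls below 5, the test escalates
#' automatically to Fisher's exact test (two-sided by summing the
#' probabilities of tables no more likely than the observed one).  Larger
#' tables with low expected counts keep the chi-square with a warning.
#'
#' @param tab Contingency table (matrix of non-negative integer counts).
#' @param escalate Escalate 2x2 tables with expected counts < 5 to Fisher
#'   (default TRUE).
#' @return A \code{test_result}.
#' @export
chi_square <- function(tab, escalate = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop_config("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(test_result("chi-square", n = sum(tab), degenerate = TRUE,
                       note = "empty margin"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (escalate && any(expected < 5)) {
    if (all(dim(tab) == 2)) return(fisher_exact(tab))
    warning("expected cell count < 5 in a table larger than 2x2; chi-square retained")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("chi-square", statistic = ht$statistic, df = ht$parameter,
              p = ht$p.value, n = sum(tab))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all tables
#' (with the observed margins) no more likely than the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A \code{test_result}.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2))
    stop_config("fisher_exact handles 2x2 tables only")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(test_result("Fisher exact", n = sum(tab), degenerate = TRUE,
                       note = "empty margin"))
  }
  ht <- stats::fisher.test(tab)
  test_result("Fisher exact", statistic = unname(ht$estimate),
              p = ht$p.value, n = sum(tab),
              note = "statistic is the conditional odds-ratio MLE")
}
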