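#' Wilson score interval for a binomial proportion
#'
#' Closed-form interval obtained by inverting the score test
#' \eqn{|\hat p - p| / \sqrt{p(1-p)/n} = z}.  The interval midpoint
#' \deqn{m = \frac{\hat p + z^2/(2n)}{1 + z^2/n}}
#' is a weighted average of the observed rate and 1/2 with weights
#' \eqn{n} and \eqn{z^2}: it shrinks small-sample rates toward 0.5, which
#' is what makes it usable for ranking facilities whose observed event
#' rates sit at or near 0.  Vectorized over \code{k} and \code{n}.
#'
#' @param k Event count(s), \code{0 <= k <= n}.
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level in (0, 1); default 0.95
#'   (z = 1.96).
#' @return Data frame with columns \code{k}, \code{n}, \code{phat},
#'   \code{lower}, \code{midpoint}, \code{upper}, \code{z}.
#' @examples
#' wilson_interval(5, 50)            # lower/mid/upper ~ 0.043 / 0.129 / 0.214
#' wilson_interval(0, 10)$midpoint   # ~ 0.139: zero events still ranked
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (length(confidence) != 1 || confidence <= 0 || confidence >= 1)
    stop_config("confidence must be a single value in (0, 1)")
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop_config("need 0 <= k <= n and n >= 1")
  z <- stats::qnorm((1 + confidence) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  mid <- (phat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  data.frame(k = k, n = n, phat = phat,
             lower = pmax(0, mid - half),
             midpoint = mid,
             upper = pmin(1, mid + half),
             z = z)
}

#' Facility-level Wilson estimates of the SAE rate
#'
#' Aggregates an encounter table to per-facility serious adverse event
#' counts and computes the Wilson score interval for each facility.
#'
#' @param encounters Encounter table with \code{facility_id} and a logical
#'   outcome column.
#' @param outcome Name of the outcome column (default \code{"sae"}).
#' @param confidence Confidence level of the intervals.
#' @return Data frame with one row per facility: \code{facility_id},
#'   \code{k}, \code{n}, \code{phat}, \code{lower}, \code{midpoint},
#'   \code{upper}, \code{z}.
#' @export
facility_wilson <- function(encounters, outcome = "sae", confidence = 0.95) {
  assert_columns(encounters, c("facility_id", outcome), "encounters")
  y <- encounters[[outcome]]
  if (anyNA(y)) stop_config("outcome column '%s' contains NA", outcome)
  k <- tapply(as.numeric(y), encounters$facility_id, sum)
  n <- tapply(y, encounters$facility_id, length)
  w <- wilson_interval(as.vector(k), as.vector(n), confidence)
  cbind(data.frame(facility_id = names(k), stringsAsFactors = FALSE),
        w, row.names = NULL)
}

#' Rank facilities by Wilson midpoint and assign quality quartiles
#'
#' Facilities are sorted by ascending interval midpoint (ties broken by
#' larger sample size first -- more evidence wins -- then by facility id)
#' and ranked 1..F.  Quartile boundaries fall at ranks
#' \code{ceiling(F/4)}, \code{ceiling(F/2)} and \code{ceiling(3F/4)}, so
#' quartile sizes differ by at most one.  Quartile 1 is the BEST quartile
#' (lowest estimated SAE rate); a "higher-quality" facility is one with a
#' strictly smaller quartile number.
#'
#' @param estimates Per-facility Wilson estimates from [facility_wilson()].
#' @return The estimates with \code{rank} and \code{quartile} columns,
#'   sorted by rank; class \code{quality_table}.
#' @export
rank_and_quartile <- function(estimates) {
  if (nrow(estimates) < 4)
    stop_config("need at least 4 facilities to form quartiles")
  ord <- order(estimates$midpoint, -estimates$n, estimates$facility_id)
  out <- estimates[ord, , drop = FALSE]
  F <- nrow(out)
  out$rank <- seq_len(F)
  cuts <- ceiling(F * (1:3) / 4)
  # rank <= ceil(F/4) -> 1, <= ceil(F/2) -> 2, <= ceil(3F/4) -> 3, else 4
  out$quartile <- 1L + (out$rank > cuts[1]) + (out$rank > cuts[2]) +
    (out$rank > cuts[3])
  rownames(out) <- NULL
  class(out) <- c("quality_table", "data.frame")
  out
}

#' @export
print.quality_table <- function(x, ...) {
  cat(sprintf("Facility quality table: %d facilities, quartile 1 = best\n",
              nrow(x)))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Rank the training cohort's facilities
#'
#' One-call wrapper: Wilson estimates on the training cohort, then ranking
#' and quartile assignment.
#'
#' @inheritParams facility_wilson
#' @return A \code{quality_table}.
#' @export
facility_quality <- function(encounters, outcome = "sae", confidence = 0.95) {
  rank_and_quartile(facility_wilson(encounters, outcome, confidence))
}

#' Summarize Wilson shrinkage against reported rates and volume
#'
#' Per-facility view of how the Wilson midpoint relates to the raw reported
#' SAE rate and to facility volume, mirroring the graphical secondary
#' analyses one would run to check that the shrinkage behaves sensibly
#' (the gap |midpoint - phat| shrinks with volume).  Reports the Pearson
#' correlation between midpoint and raw rate, and the median and
#' interquartile interval of both the raw-rate and midpoint distributions
#' across facilities.
#'
#' @param estimates Per-facility Wilson estimates ([facility_wilson()]),
#'   computed with or without low-volume facilities depending on the
#'   analysis.
#' @return List with \code{table} (facility_id, n, phat, midpoint,
#'   shrinkage_gap), \code{cor_midpoint_phat} (NA with a flag when fewer
#'   than two facilities), and \code{distribution} (median and IQI of raw
#'   rates and midpoints, in percent).
#' @export
quality_vs_volume_summary <- function(estimates) {
  if (!nrow(estimates)) stop_config("no facility estimates supplied")
  if (is.null(estimates$facility_id))
    estimates$facility_id <- sprintf("F%03d", seq_len(nrow(estimates)))
  tab <- data.frame(
    facility_id = estimates$facility_id,
    n = estimates$n,
    phat = estimates$phat,
    midpoint = estimates$midpoint,
    shrinkage_gap = abs(estimates$midpoint - estimates$phat),
    stringsAsFactors = FALSE
  )
  degenerate <- nrow(tab) < 2 || stats::sd(tab$phat) == 0 ||
    stats::sd(tab$midpoint) == 0
  r <- if (degenerate) NA_real_ else stats::cor(tab$midpoint, tab$phat)
  qs <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
    c(median = q[1], iqi_lower = q[2], iqi_upper = q[3]) * 100
  }
  list(table = tab,
       cor_midpoint_phat = r,
       cor_defined = !degenerate,
       distribution = rbind(reported_rate_pct = qs(tab$phat),
                            midpoint_pct = qs(tab$midpoint)))
}
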