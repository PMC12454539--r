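# Baseline-characteristic tables, paired outcome summaries and small-cell
# suppression for exported tables.

#' Mask small categorical counts
#'
#' Renders \code{"n (pct\%)"} cells, replacing any count between 1 and
#' \code{threshold - 1} with a masked token, the usual data-use convention
#' for administrative claims exports.  Zero counts are shown (a zero
#' reveals nothing about individuals).
#'
#' @param n Count vector.
#' @param total Group size.
#' @param threshold Suppression threshold (default 11: counts < 11 masked).
#' @param token Replacement string.
#' @return Character vector of display cells.
#' @export
mask_small_cells <- function(n, total, threshold = 11, token = "-") {
  out <- sprintf("%d (%.1f)", n, 100 * n / total)
  out[n > 0 & n < threshold] <- token
  out
}

fmt_median_iqi <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, na.rm = TRUE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Baseline characteristics comparison table
#'
#' Builds the familiar two-group clinical table: continuous variables as
#' median (interquartile interval) compared with the rank-sum test (or the
#' signed-rank test for paired, facility-dependent variables such as
#' facility volume or patient-facility distance), categorical variables as
#' n (\%) compared with chi-square (escalating to Fisher at low expected
#' counts), and categorical cells below the suppression threshold masked.
#'
#' @param group_a,group_b Data frames sharing the variable schema.  For a
#'   paired comparison the rows must be aligned.
#' @param variables Character vector of column names to compare.
#' @param group_labels Labels of the two columns.
#' @param paired Are the two groups paired row-by-row?
#' @param paired_vars Variables not inherent to the patient (facility
#'   volume, distance, ...) which get the signed-rank test when
#'   \code{paired} is on.
#' @param threshold Small-cell suppression threshold (default 11).
#' @return Data frame of class \code{summary_table}: one row per variable
#'   (continuous) or per level (categorical), with display cells, the test
#'   used and its two-sided p-value on each variable's first row.
#' @export
build_baseline_table <- function(group_a, group_b, variables,
                                 group_labels = c("Group A", "Group B"),
                                 paired = FALSE,
                                 paired_vars = character(),
                                 threshold = 11) {
  missing_a <- setdiff(variables, names(group_a))
  missing_b <- setdiff(variables, names(group_b))
  if (length(missing_a) || length(missing_b))
    stop_config("variable(s) absent from both groups' schema: %s",
                paste(union(missing_a, missing_b), collapse = ", "))
  rows <- list()
  for (v in variables) {
    a <- group_a[[v]]; b <- group_b[[v]]
    if (is.numeric(a) && is.numeric(b)) {
      tr <- if (paired && v %in% paired_vars) {
        if (length(a) != length(b))
          stop_config("paired comparison of '%s' needs aligned groups", v)
        wilcoxon_signed_rank(a - b)
      } else {
        rank_sum(a, b)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "",
        a = fmt_median_iqi(a), b = fmt_median_iqi(b),
        test = tr$test, p = tr$p, degenerate = tr$degenerate,
        stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(c(as.character(a), as.character(b))))
      na <- table(factor(as.character(a), levels = lev))
      nb <- table(factor(as.character(b), levels = lev))
      tab <- rbind(as.vector(na), as.vector(nb))
      tr <- chi_square(t(tab))
      block <- data.frame(
        variable = v, level = lev,
        a = mask_small_cells(as.vector(na), length(a), threshold),
        b = mask_small_cells(as.vector(nb), length(b), threshold),
        test = c(tr$test, rep("", length(lev) - 1)),
        p = c(tr$p, rep(NA_real_, length(lev) - 1)),
        degenerate = c(tr$degenerate, rep(NA, length(lev) - 1)),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "a"] <- group_labels[1]
  names(out)[names(out) == "b"] <- group_labels[2]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Paired outcome summary of a referral simulation
#'
#' For every predicted outcome, compares the original predictions against
#' the simulated ones (alternative-facility predictions for movers,
#' unchanged for stayers) over the whole test cohort -- the cohort-level
#' contrast of interest -- and over the mover subset.  Reports means, the
#' mean difference with a t-based 95\% confidence interval, and the paired
#' t and Wilcoxon signed-rank p-values.  With no movers all differences
#' are zero and the tests are flagged degenerate rather than computed.
#'
#' @param sim A [run_referral_simulation()] result.
#' @param conf_level Confidence level of the mean-difference interval.
#' @return Object of class \code{simulation_report}: a data frame with one
#'   row per (outcome, scope) and the simulation counts as attributes.
#' @export
summarize_simulation <- function(sim, conf_level = 0.95) {
  s <- attr(sim, "summary")
  outcomes <- sub("^pred_orig_", "",
                  grep("^pred_orig_", names(sim), value = TRUE))
  one <- function(o, scope, idx) {
    po <- sim[[paste0("pred_orig_", o)]][idx]
    pa <- sim[[paste0("pred_alt_", o)]][idx]
    d <- pa - po
    degen <- length(d) < 2 || stats::sd(d) == 0
    if (!degen) {
      tt <- stats::t.test(d, conf.level = conf_level)
      sr <- wilcoxon_signed_rank(d)
      ci <- tt$conf.int
      p_t <- tt$p.value
      p_sr <- sr$p
    } else {
      ci <- c(NA_real_, NA_real_); p_t <- NA_real_; p_sr <- NA_real_
    }
    data.frame(outcome = o, scope = scope, n = length(d),
               mean_original = mean(po), mean_simulated = mean(pa),
               mean_diff = mean(d),
               ci_lower = ci[1], ci_upper = ci[2],
               p_paired_t = p_t, p_signed_rank = p_sr,
               degenerate = degen, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(
    lapply(outcomes, one, scope = "all", idx = seq_len(nrow(sim))),
    lapply(outcomes, one, scope = "movers", idx = which(sim$moved))))
  rownames(res) <- NULL
  attr(res, "counts") <- s[c("n", "n_moved", "n_stayed", "share_moved",
                             "n_unranked_origin", "discordant_mover_share")]
  class(res) <- c("simulation_report", "data.frame")
  res
}

#' @export
print.simulation_report <- function(x, digits = 4, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Simulated referral outcomes: %d patients, %d moved (%.1f%%)\n",
              cnt$n, cnt$n_moved, 100 * cnt$share_moved))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Render a table as Markdown
#'
#' @param x A \code{summary_table} or \code{simulation_report} (any data
#'   frame).
#' @param digits Significant digits for numeric cells.
#' @return Character vector of Markdown lines.
#' @export
format_markdown <- function(x, digits = 4) {
  df <- as.data.frame(x)
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) format(signif(col, digits)) else as.character(col)
  }, character(nrow(df)))
  cells <- rbind(cells)
  cells[is.na(df)] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write the standard report files for a simulation
#'
#' Writes \code{outcomes_summary.csv}, \code{outcomes_summary.json},
#' \code{sim_results.csv} and Markdown renderings into a directory.
#' Exports contain only masked display cells where masking applies.
#'
#' @param sim A [run_referral_simulation()] result.
#' @param dir Output directory.
#' @param report Optional precomputed [summarize_simulation()] result.
#' @return Invisibly, the paths written.
#' @export
write_simulation_report <- function(sim, dir, report = summarize_simulation(sim)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(dir, "sim_results.csv"),
             summary_csv = file.path(dir, "outcomes_summary.csv"),
             summary_json = file.path(dir, "outcomes_summary.json"),
             summary_md = file.path(dir, "outcomes_summary.md"))
  utils::write.csv(as.data.frame(sim), paths["results"], row.names = FALSE)
  utils::write.csv(as.data.frame(report), paths["summary_csv"],
                   row.names = FALSE)
  jsonlite::write_json(list(counts = attr(report, "counts"),
                            outcomes = as.data.frame(report)),
                       paths["summary_json"], auto_unbox = TRUE, digits = NA)
  writeLines(format_markdown(report), paths["summary_md"])
  invisible(paths)
}
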