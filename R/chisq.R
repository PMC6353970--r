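#' Chi-squared comparison of variance percentages
#'
#' Compares two or three variance percentages (the per-marginalization
#' shares of total signal variance, 0-100) with a Pearson chi-squared test
#' on a groups x 2 contingency table of "percentage points captured" versus
#' "points not captured" out of a common base (default 100 points per
#' group). The base encodes the interpretive assumption that each percentage
#' is treated as a count out of 100; the test is the across-/within-task
#' comparison applied to the variance-split bar charts.
#'
#' @param percentages numeric vector of 2 or 3 values in `[0, 100]`.
#' @param base counts per group (default 100; below 10 the table degenerates
#'   and an error is raised).
#' @param labels optional character labels of the compared groups.
#' @param alpha significance level (default 0.05).
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return An object of class `"variance_comparison"`: `labels`,
#'   `percentages`, `table`, `chi2`, `dof`, `p_value`, `significant`,
#'   `alpha`.
#' @examples
#' chi2_compare(c(24, 11))      # significant at 0.05
#' chi2_compare(c(11, 15, 19))  # not significant
#' @export
chi2_compare <- function(percentages, base = 100L, labels = NULL,
                         alpha = 0.05, correct = FALSE) {
  abort_if(!length(percentages) %in% 2:3,
           "2 or 3 percentages can be compared")
  abort_if(any(percentages < 0 | percentages > 100),
           "percentages must lie in [0, 100]")
  abort_if(base < 10, "base below 10 gives a degenerate count table")
  captured <- round(percentages * base / 100)
  tab <- cbind(captured = captured, rest = base - captured)
  if (is.null(labels)) labels <- sprintf("group%d", seq_along(percentages))
  rownames(tab) <- labels
  test <- stats::chisq.test(tab, correct = correct)
  structure(list(
    labels = labels,
    percentages = percentages,
    table = tab,
    chi2 = unname(test$statistic),
    dof = unname(test$parameter),
    p_value = unname(test$p.value),
    significant = unname(test$p.value) < alpha,
    alpha = alpha
  ), class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf("Chi-squared comparison of variance percentages: %s\n",
              paste(sprintf("%s=%g%%", x$labels, x$percentages),
                    collapse = ", ")))
  cat(sprintf("  chi2 = %.3f, df = %d, p = %.4f (%s at alpha = %g)\n",
              x$chi2, x$dof, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' All pairwise and joint chi-squared comparisons of a variance table
#'
#' Convenience wrapper: given per-task percentages of the task-parameter and
#' visual-condition marginalizations, runs the across-task comparisons
#' (parameter vs parameter pairwise, visual across all tasks jointly) and
#' the within-task parameter-vs-visual comparisons.
#'
#' @param splits named list, one entry per task, each a named numeric vector
#'   with at least `parameter` and `visual` percentages.
#' @param base,alpha,correct passed to [chi2_compare()].
#' @return A data frame with one row per comparison: `comparison`, `groups`,
#'   `percentages`, `chi2`, `dof`, `p_value`, `significant`.
#' @export
compare_variance_table <- function(splits, base = 100L, alpha = 0.05,
                                   correct = FALSE) {
  stopifnot(is.list(splits), length(splits) >= 2L)
  tasks <- names(splits)
  rows <- list()
  add <- function(comparison, labels, pct) {
    r <- chi2_compare(pct, base = base, labels = labels, alpha = alpha,
                      correct = correct)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison,
      groups = paste(labels, collapse = " vs "),
      percentages = paste(pct, collapse = "/"),
      chi2 = r$chi2, dof = r$dof, p_value = r$p_value,
      significant = r$significant, stringsAsFactors = FALSE)
  }
  # visual condition across all tasks, jointly
  add("visual_across_tasks", tasks,
      vapply(splits, function(s) unname(s[["visual"]]), numeric(1)))
  # task parameter across tasks, pairwise
  if (length(tasks) >= 2L) {
    combs <- utils::combn(tasks, 2, simplify = FALSE)
    for (cb in combs)
      add(sprintf("parameter_%s_vs_%s", cb[1], cb[2]), cb,
          vapply(splits[cb], function(s) unname(s[["parameter"]]), numeric(1)))
  }
  # within each task: visual vs parameter
  for (tk in tasks)
    add(sprintf("within_%s", tk), c("visual", "parameter"),
        c(unname(splits[[tk]][["visual"]]),
          unname(splits[[tk]][["parameter"]])))
  do.call(rbind, rows)
}
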