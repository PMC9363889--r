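# Group-level aggregation and hypothesis tests. The statistical
# routines delegate to base R (wilcox.test, t.test, aov/TukeyHSD); this
# module's contract is the mapping from repertoire comparisons to test
# choice, pairing and two-sidedness.

#' Mean, SD and n of a metric by group
#'
#' Sample SD uses the n - 1 denominator; groups with a single value
#' report SD as NA (undefined), never 0.
#'
#' @param df a data.frame (e.g. overlap or summary table).
#' @param metric name of the numeric column to aggregate.
#' @param by name of the grouping column.
#' @return data.frame: group, n, mean, sd.
#' @export
aggregate_stats <- function(df, metric, by) {
  if (!metric %in% names(df)) stop2("unknown metric column '%s'", metric)
  if (!by %in% names(df)) stop2("unknown grouping column '%s'", by)
  v <- df[[metric]]; g <- as.character(df[[by]])
  groups <- unique(g)
  out <- data.frame(
    group = groups,
    n = vapply(groups, function(k) sum(g == k), 0L),
    mean = vapply(groups, function(k) mean(v[g == k]), 0),
    sd = vapply(groups, function(k) {
      x <- v[g == k]
      if (length(x) < 2L) NA_real_ else stats::sd(x)
    }, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Two-group comparison (Mann-Whitney U or paired t test)
#'
#' Both tests are two-sided; significance is declared at p < 0.05. The
#' Mann-Whitney statistic reported is U for the first group (the number
#' of (a, b) pairs with a > b, i.e. `wilcox.test`'s W). A paired test
#' with zero variance in the differences is flagged degenerate and
#' reports no p-value rather than fabricating one.
#'
#' @param values_a,values_b numeric vectors; for `paired_t` they must be
#'   aligned pairs of equal length.
#' @param test `"mann_whitney_u"` (unpaired) or `"paired_t"`.
#' @param group_a,group_b,metric labels carried into the output row.
#' @return one-row data.frame: metric, group_a, group_b, test, n_a, n_b,
#'   n_pairs, mean_a, sd_a, mean_b, sd_b, statistic, p_value,
#'   significant, degenerate.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney_u", "paired_t"),
                           group_a = "a", group_b = "b", metric = NA) {
  test <- match.arg(test)
  if (!length(values_a) || !length(values_b))
    stop2("compare_groups: empty group")
  statistic <- NA_real_; p <- NA_real_; degenerate <- FALSE
  n_pairs <- NA_integer_
  if (test == "paired_t") {
    if (length(values_a) != length(values_b))
      stop2("paired test requires equal-length, aligned vectors (%d vs %d)",
            length(values_a), length(values_b))
    d <- values_a - values_b
    n_pairs <- length(d)
    if (length(d) < 2L || stats::sd(d) == 0) {
      degenerate <- TRUE
    } else {
      ht <- stats::t.test(values_a, values_b, paired = TRUE)
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, alternative = "two.sided"))
    statistic <- unname(ht$statistic); p <- ht$p.value
  }
  data.frame(
    metric = metric, group_a = group_a, group_b = group_b, test = test,
    n_a = length(values_a), n_b = length(values_b), n_pairs = n_pairs,
    mean_a = mean(values_a),
    sd_a = if (length(values_a) > 1L) stats::sd(values_a) else NA_real_,
    mean_b = mean(values_b),
    sd_b = if (length(values_b) > 1L) stats::sd(values_b) else NA_real_,
    statistic = statistic, p_value = p,
    significant = !is.na(p) & p < 0.05,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' One-way ANOVA with Tukey's multiple comparison
#'
#' @param values numeric vector.
#' @param groups grouping labels (3 or more groups expected).
#' @param metric label carried into the output.
#' @return list with `anova_p` (overall F-test p-value) and `tukey`, a
#'   data.frame of pairwise contrasts (group_a, group_b, diff, p_adj,
#'   significant).
#' @export
anova_tukey <- function(values, groups, metric = NA) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop2("anova_tukey needs >= 2 groups")
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    metric = metric,
    group_a = vapply(pair, `[`, "", 1L),
    group_b = vapply(pair, `[`, "", 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < 0.05,
    stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL
  list(anova_p = anova_p, tukey = tukey)
}
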