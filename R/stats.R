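#' Compare a metric across groups
#'
#' Per-group mean and standard error of the mean (SEM) with a one-way ANOVA
#' and pairwise post hoc comparisons, the standard analysis pattern for
#' per-image metrics across experimental groups. Post hoc is either Tukey's
#' honestly-significant-difference test or pairwise t tests with
#' Benjamini-Hochberg adjustment.
#'
#' Degenerate inputs are handled explicitly rather than left to numeric
#' noise: when the within-group variance is exactly zero, identical group
#' means give `F = 0, p = 1`, and distinct means give `F = Inf` with p
#' capped at 0.
#'
#' @param values Numeric vector of per-observation values.
#' @param groups Group label per observation (>= 2 groups, >= 2 observations
#'   each).
#' @param posthoc `"tukey"` (default) or `"bh"`.
#' @return A `group_comparison`: `summary` (data frame: group, n, mean,
#'   sem), `f`, `p`, `df`, `posthoc` (data frame: comparison, p_adj),
#'   `posthoc_method`.
#' @export
compare_groups <- function(values, groups, posthoc = c("tukey", "bh")) {
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need >= 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2L)) {
    stopf("every group needs >= 2 observations (got: %s)",
          paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  }
  df <- data.frame(value = values, group = groups)
  smry <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)))
  }))
  k <- nlevels(groups); N <- length(values)
  ss_within <- sum((values - ave(values, groups))^2)
  ss_between <- sum(n_per * (tapply(values, groups, mean) - mean(values))^2)
  if (ss_within < 1e-12 * max(1, ss_between)) {
    ## zero within-group variance: F degenerates
    if (ss_between < 1e-12) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0  # documented cap
    }
    ph <- data.frame(comparison = character(0), p_adj = numeric(0))
  } else {
    fit <- aov(value ~ group, data = df)
    tab <- summary(fit)[[1]]
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (posthoc == "tukey") {
      tk <- TukeyHSD(fit)$group
      ph <- data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                       row.names = NULL)
    } else {
      pt <- pairwise.t.test(values, groups, p.adjust.method = "BH")$p.value
      cmp <- which(!is.na(pt), arr.ind = TRUE)
      ph <- data.frame(
        comparison = paste(rownames(pt)[cmp[, 1]], colnames(pt)[cmp[, 2]],
                           sep = "-"),
        p_adj = pt[cmp], row.names = NULL)
    }
  }
  structure(list(summary = smry, f = f, p = p,
                 df = c(between = k - 1L, within = N - k),
                 posthoc = ph, posthoc_method = posthoc),
            class = "group_comparison")
}

#' Per-timepoint group comparisons of a metric
#'
#' At each timepoint, runs a one-way ANOVA across groups plus post hoc
#' pairwise comparisons — each day tested separately, without correction
#' across days (an optional Benjamini-Hochberg adjustment over the family of
#' per-day ANOVA p-values is available via `adjust_across`). Timepoints
#' with fewer than two groups are skipped with a warning.
#'
#' @param results Data frame with at least the metric column plus `group`
#'   and `timepoint` columns.
#' @param metric Name of the metric column.
#' @param group_col,time_col Column names (defaults `"group"`,
#'   `"timepoint"`).
#' @param posthoc `"tukey"` or `"bh"`.
#' @param adjust_across Apply BH across timepoints' ANOVA p-values
#'   (default FALSE, matching per-day testing).
#' @return Data frame: timepoint, f, p (and `p_adj` if `adjust_across`),
#'   plus a `comparisons` attribute listing pairwise post hoc results per
#'   timepoint.
#' @export
group_timecourse <- function(results, metric, group_col = "group",
                             time_col = "timepoint",
                             posthoc = c("tukey", "bh"),
                             adjust_across = FALSE) {
  posthoc <- match.arg(posthoc)
  for (col in c(metric, group_col, time_col)) {
    if (!col %in% names(results)) stopf("missing column '%s'", col)
  }
  tps <- unique(results[[time_col]])
  rows <- list(); comps <- list()
  for (tp in tps) {
    sub <- results[results[[time_col]] == tp, ]
    gs <- unique(sub[[group_col]])
    if (length(gs) < 2L) {
      warning(sprintf("timepoint '%s' has < 2 groups; skipped", tp),
              call. = FALSE)
      next
    }
    cg <- compare_groups(sub[[metric]], sub[[group_col]], posthoc = posthoc)
    rows[[length(rows) + 1L]] <- data.frame(timepoint = tp, f = cg$f, p = cg$p)
    comps[[as.character(tp)]] <- cg$posthoc
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(timepoint = character(0), f = numeric(0), p = numeric(0))
  }
  if (adjust_across && nrow(out)) out$p_adj <- stats::p.adjust(out$p, "BH")
  attr(out, "comparisons") <- comps
  out
}
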