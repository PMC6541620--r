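#' Box-and-whisker summary statistics per condition
#'
#' Median, 25th and 75th percentiles (linear-interpolation quartiles,
#' `quantile` type 7) and the minimum / maximum whiskers — the summary
#' underlying per-cell box plots.
#'
#' @param values Numeric vector of per-cell measurements.
#' @param conditions Matching vector of condition labels.
#' @return Data frame with `condition`, `n`, `median`, `p25`, `p75`, `min`,
#'   `max`.
#' @export
summarize_groups <- function(values, conditions) {
  if (length(values) != length(conditions))
    stop("summarize_groups: values and conditions differ in length")
  sp <- split(values, factor(conditions, levels = unique(conditions)))
  if (any(!vapply(sp, length, integer(1))))
    stop("summarize_groups: empty group")
  out <- do.call(rbind, lapply(names(sp), function(g) {
    v <- sp[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(condition = g, n = length(v), median = q[2], p25 = q[1],
               p75 = q[3], min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Rank-based multiple-comparison z tests on the pooled ranks, with the
#' standard tie correction; by default each condition is compared against the
#' control only, with Bonferroni adjustment over the comparisons made.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param control Control label; `NULL` compares all pairs.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`, Dunn's classical correction).
#' @return Data frame with `comparison`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, control = NULL,
                      p_adjust = "bonferroni") {
  groups <- as.character(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  n_tot <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n_tot - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  labs <- names(mean_rank)
  pairs <- if (is.null(control)) utils::combn(labs, 2, simplify = FALSE)
  else {
    if (!control %in% labs) stop("dunn_test: control group '", control,
                                 "' not present")
    lapply(setdiff(labs, control), function(g) c(control, g))
  }
  res <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    data.frame(comparison = paste(pr[1], "vs", pr[2]), z = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = p_adjust)
  rownames(res) <- NULL
  res
}

#' Compare measurement groups the way motility/imaging panels are reported
#'
#' Three designs:
#' * `"kruskal_dunn"` — Kruskal-Wallis omnibus test followed by Dunn's
#'   multiple-comparison test against the control group.
#' * `"mann_whitney"` — two-tailed Mann-Whitney U tests of each group
#'   against the control (Bonferroni-adjusted when more than one).
#' * `"two_way"` — two-factor ANOVA (e.g. condition x timepoint for wound
#'   series) post-tested with Bonferroni-adjusted pairwise t tests against
#'   the control within each level of the second factor.
#'
#' @param values Numeric vector of measurements.
#' @param groups Condition labels.
#' @param control Control condition label.
#' @param design `"kruskal_dunn"`, `"mann_whitney"` or `"two_way"`.
#' @param factor2 Second factor (required for `design = "two_way"`).
#' @return List of class `group_comparison` with `design`, `omnibus`
#'   (htest or ANOVA table) and `posthoc` (data frame).
#' @export
compare_groups <- function(values, groups, control,
                           design = c("kruskal_dunn", "mann_whitney",
                                      "two_way"),
                           factor2 = NULL) {
  design <- match.arg(design)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("compare_groups: need at least 2 groups")
  if (any(sizes < 2)) stop("compare_groups: every group needs >= 2 values")
  if (!control %in% groups) stop("compare_groups: control group '", control,
                                 "' not present")
  out <- switch(design,
    kruskal_dunn = {
      omni <- stats::kruskal.test(values, factor(groups))
      list(omnibus = omni, posthoc = dunn_test(values, groups, control))
    },
    mann_whitney = {
      others <- setdiff(unique(groups), control)
      ph <- do.call(rbind, lapply(others, function(g) {
        ht <- stats::wilcox.test(values[groups == control],
                                 values[groups == g],
                                 alternative = "two.sided", exact = NULL)
        data.frame(comparison = paste(control, "vs", g),
                   U = unname(ht$statistic), p_value = ht$p.value,
                   stringsAsFactors = FALSE)
      }))
      ph$p_adjusted <- stats::p.adjust(ph$p_value, "bonferroni")
      list(omnibus = NULL, posthoc = ph)
    },
    two_way = {
      if (is.null(factor2))
        stop("compare_groups: two_way design needs factor2")
      f1 <- factor(groups); f2 <- factor(as.character(factor2))
      omni <- stats::aov(values ~ f1 * f2)
      others <- setdiff(levels(f1), control)
      ph <- do.call(rbind, lapply(levels(f2), function(lv) {
        do.call(rbind, lapply(others, function(g) {
          a <- values[groups == control & f2 == lv]
          b <- values[groups == g & f2 == lv]
          if (length(a) < 2 || length(b) < 2) return(NULL)
          ht <- stats::t.test(a, b)
          data.frame(factor2 = lv, comparison = paste(control, "vs", g),
                     t = unname(ht$statistic), p_value = ht$p.value,
                     stringsAsFactors = FALSE)
        }))
      }))
      ph$p_adjusted <- pmin(ph$p_value * nrow(ph), 1)
      list(omnibus = omni, posthoc = ph)
    })
  structure(c(list(design = design, control = control), out),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison (", x$design, "), control = ", x$control, "\n",
      sep = "")
  if (!is.null(x$omnibus)) {
    if (inherits(x$omnibus, "htest"))
      cat(sprintf("omnibus: %s, p = %.4g\n", x$omnibus$method,
                  x$omnibus$p.value))
    else print(summary(x$omnibus))
  }
  print(x$posthoc)
  invisible(x)
}
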