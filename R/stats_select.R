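# Shapiro-Wilk p-value of one group; degenerate samples (constant, or too
# large for the test) are treated as non-normal (p = 0).
shapiro_p <- function(v) {
  if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
  tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
}

#' Univariate group-difference test for one feature
#'
#' Every group is first screened with a Shapiro-Wilk normality test at
#' `gate_alpha`. If all groups look normal, a parametric test is used:
#' one-way ANOVA for the four-group comparison, a two-sided two-sample
#' t-test (pooled variance by default) for the two-group comparison.
#' Otherwise the rank-based analogue is used: Kruskal-Wallis or a two-sided
#' Mann-Whitney U test.
#'
#' @param values_by_group Named list of numeric vectors, one per group, each
#'   with at least 3 values.
#' @param mode `"two_group"` or `"four_group"` (any number of groups >= 2 is
#'   accepted in `"four_group"` mode).
#' @param gate_alpha Normality-gate significance level (default 0.05).
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance test in the parametric two-group branch.
#' @return List with `chosen_test` (one of `"ANOVA"`, `"t-test"`,
#'   `"Kruskal-Wallis"`, `"Mann-Whitney"`), `p_value`, and `normality_p`
#'   (per-group Shapiro-Wilk p-values).
#' @export
feature_pvalue <- function(values_by_group,
                           mode = c("two_group", "four_group"),
                           gate_alpha = 0.05, welch = FALSE) {
  mode <- match.arg(mode)
  sizes <- lengths(values_by_group)
  if (any(sizes < 3))
    stop("insufficient group size: every group needs >= 3 values",
         call. = FALSE)
  if (mode == "two_group" && length(values_by_group) != 2)
    stop("two_group mode needs exactly 2 groups", call. = FALSE)
  if (mode == "four_group" && length(values_by_group) < 2)
    stop("four_group mode needs >= 2 groups", call. = FALSE)

  all_vals <- unlist(values_by_group, use.names = FALSE)
  sw <- vapply(values_by_group, shapiro_p, numeric(1))
  normal <- all(sw >= gate_alpha)
  if (length(unique(all_vals)) == 1) {
    warning("zero variance in all groups; p set to 1", call. = FALSE)
    test <- if (mode == "two_group") "Mann-Whitney" else "Kruskal-Wallis"
    return(list(chosen_test = test, p_value = 1, normality_p = sw))
  }
  g1 <- values_by_group[[1]]
  if (mode == "two_group") {
    g2 <- values_by_group[[2]]
    if (normal) {
      res <- t.test(g1, g2, var.equal = !welch, alternative = "two.sided")
      list(chosen_test = "t-test", p_value = res$p.value, normality_p = sw)
    } else {
      res <- wilcox.test(g1, g2, alternative = "two.sided", exact = FALSE)
      list(chosen_test = "Mann-Whitney", p_value = res$p.value,
           normality_p = sw)
    }
  } else {
    grp <- factor(rep(names(values_by_group) %||%
                        seq_along(values_by_group), sizes))
    if (normal) {
      res <- oneway.test(all_vals ~ grp, var.equal = TRUE)
      list(chosen_test = "ANOVA", p_value = res$p.value, normality_p = sw)
    } else {
      res <- kruskal.test(all_vals, grp)
      list(chosen_test = "Kruskal-Wallis", p_value = res$p.value,
           normality_p = sw)
    }
  }
}

#' Feature selection by univariate significance
#'
#' Applies [feature_pvalue()] to every feature column of a cohort feature
#' table and keeps features with `p < alpha`. In `"two_group"` mode the
#' comparison is controls versus all disease labels pooled; in
#' `"four_group"` mode the four labels are compared directly. No
#' multiple-testing correction is applied by default (raw p < alpha);
#' `adjust = "BH"` switches to Benjamini-Hochberg adjusted p-values.
#'
#' @param table Feature table from [build_feature_table()] or
#'   [read_feature_table()].
#' @param mode `"two_group"` or `"four_group"`.
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param welch Passed to [feature_pvalue()].
#' @return Data frame sorted by ascending p-value with columns `feature`,
#'   `chosen_test`, `p_value`, `selected`; attribute `"alpha"` records the
#'   threshold.
#' @export
select_features <- function(table, mode = c("two_group", "four_group"),
                            alpha = 0.05, adjust = c("none", "BH"),
                            welch = FALSE) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  tm <- table_matrix(table)
  grp <- selection_groups(tm$label, mode)
  if (length(unique(grp)) < 2)
    stop("need at least 2 groups present", call. = FALSE)
  nm <- colnames(tm$x)
  res <- lapply(nm, function(f) {
    byg <- split(tm$x[, f], grp)
    r <- suppressWarnings(feature_pvalue(byg, mode = mode, welch = welch))
    data.frame(feature = f, chosen_test = r$chosen_test,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$selected <- p < alpha
  out <- out[order(out$p_value, out$feature, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

# Map cohort labels onto comparison groups.
selection_groups <- function(labels, mode) {
  if (mode == "two_group")
    factor(ifelse(labels == "control", "control", "disease"),
           levels = c("control", "disease"))
  else
    factor(labels, levels = intersect(GROUP_LABELS, unique(labels)))
}
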