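#' Normality-gated two-group comparison for one ion
#'
#' Compares the log10 peak areas of one ion between two groups the way the
#' screening study's statistics were run: Shapiro-Wilk normality is checked
#' in each group, and if both groups pass (p > `alpha`) an independent-samples
#' t-test (Welch by default) is used; otherwise the Mann-Whitney U test.
#' Tests are two-sided. A group with zero variance cannot be normal in the
#' operative sense (Shapiro-Wilk is undefined on constant data), so it fails
#' the gate and the Mann-Whitney branch is taken.
#'
#' @param table A log10-scale [peak_table()].
#' @param manifest Sample manifest (`sample`, `group`).
#' @param ion Length-2 numeric `c(mz, rt)`.
#' @param group_a,group_b Group labels; each may be a vector of labels, which
#'   are pooled into one class.
#' @param alpha Normality-gate level (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return One-row tibble of class `lmi_group_comparison`: `mz`, `rt`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `shapiro_p_a`, `shapiro_p_b`,
#'   `test_used` (`"t_test"` or `"mann_whitney"`), `statistic`, `p_value`.
#' @export
compare_groups <- function(table, manifest, ion, group_a, group_b,
                           alpha = 0.05, var_equal = FALSE) {
  if (!identical(table_scale(table), "log10")) {
    rlang::abort("group comparisons are run on log10 areas")
  }
  validate_manifest(manifest)
  i <- find_ion(table, ion)
  v <- area_matrix(table)[i, ]
  grp <- manifest$group[match(sample_ids(table), manifest$sample)]
  a <- v[grp %in% group_a]
  b <- v[grp %in% group_b]
  if (length(a) < 3 || length(b) < 3) {
    rlang::abort("each group needs at least 3 samples for the normality gate")
  }
  sw <- function(x) {
    if (stats::var(x) == 0) return(0)   # constant data: gate fails
    stats::shapiro.test(x)$p.value
  }
  p_a <- sw(a)
  p_b <- sw(b)
  if (p_a > alpha && p_b > alpha) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    test_used <- "t_test"
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test_used <- "mann_whitney"
    # fully tied data degenerates the normal approximation; no evidence at all
    if (is.nan(ht$p.value)) ht$p.value <- 1
  }
  out <- tibble::tibble(
    mz = ion[1], rt = ion[2],
    group_a = paste(group_a, collapse = "+"),
    group_b = paste(group_b, collapse = "+"),
    n_a = length(a), n_b = length(b),
    shapiro_p_a = p_a, shapiro_p_b = p_b,
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
  class(out) <- c("lmi_group_comparison", class(out))
  out
}
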