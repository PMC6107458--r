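#' Sensitivity and specificity of a threshold classifier
#'
#' Applies a single cut-off to per-sample scores. Under orientation
#' `positive_high` a sample is called positive iff its score is strictly
#' greater than the threshold; under `positive_low`, strictly less.
#' Sensitivity is TP/(TP+FN), specificity TN/(TN+FP).
#'
#' @param values Numeric per-sample scores.
#' @param labels Logical vector, `TRUE` for positive-class samples.
#' @param threshold Cut-off on the score scale.
#' @param orientation `"positive_high"` (default) or `"positive_low"`.
#' @return One-row tibble: `sensitivity`, `specificity`, `tp`, `fn`, `tn`,
#'   `fp`.
#' @examples
#' # 51 positives with 10 false negatives, 39 negatives with 2 false positives
#' v <- c(rep(5, 41), rep(3, 10), rep(3, 37), rep(5, 2))
#' l <- rep(c(TRUE, FALSE), c(51, 39))
#' confusion_stats(v, l, threshold = 4)   # 0.8039, 0.9487
#' @export
confusion_stats <- function(values, labels,
                            threshold,
                            orientation = c("positive_high", "positive_low")) {
  orientation <- match.arg(orientation)
  check_two_classes(values, labels)
  pos <- values[labels]
  neg <- values[!labels]
  called_pos_p <- if (orientation == "positive_high") pos > threshold else pos < threshold
  called_pos_n <- if (orientation == "positive_high") neg > threshold else neg < threshold
  tp <- sum(called_pos_p); fn <- length(pos) - tp
  fp <- sum(called_pos_n); tn <- length(neg) - fp
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

check_two_classes <- function(values, labels) {
  if (length(values) != length(labels)) {
    rlang::abort("`values` and `labels` must have equal length")
  }
  if (!is.logical(labels)) rlang::abort("`labels` must be logical")
  if (anyNA(labels) || !any(labels) || all(labels)) {
    rlang::abort("both classes must be present")
  }
  if (any(!is.finite(values))) rlang::abort("scores must be finite")
  invisible(TRUE)
}

# Grid of candidate thresholds: the pooled data range rounded outward to the
# increment. t_k = k * increment, so equal increments give bit-identical grids
# everywhere (including the C++ sweep).
grid_thresholds <- function(values, increment) {
  if (!is.numeric(increment) || increment <= 0) {
    rlang::abort("`increment` must be positive")
  }
  k_lo <- floor(min(values) / increment + 1e-9)
  k_hi <- ceiling(max(values) / increment - 1e-9)
  (k_lo:k_hi) * increment
}

#' Exhaustive grid search for the best discrimination threshold
#'
#' Evaluates every candidate threshold on a fixed grid (data range rounded
#' outward, step `increment`, default 0.01) under both orientations and keeps
#' the set maximizing sensitivity + specificity. When several grid thresholds
#' tie at the optimum, the reported threshold is their arithmetic mean; the
#' extremes of the tie set are reported alongside. When discrimination is
#' perfect (sensitivity = specificity = 1) the width `gap = tie_max - tie_min`
#' measures how robustly the classes separate; otherwise `gap` is `NA`.
#'
#' The reported `sensitivity`/`specificity` are re-evaluated at the averaged
#' threshold, so they always agree with [confusion_stats()] at that cut-off;
#' `optimum` is the best sensitivity + specificity attained on the grid.
#' If both orientations attain the optimum, `positive_high` is reported.
#'
#' @inheritParams confusion_stats
#' @param increment Grid step on the score scale.
#' @return One-row tibble: `orientation`, `best_threshold`, `tie_min`,
#'   `tie_max`, `gap`, `sensitivity`, `specificity`, `optimum`.
#' @examples
#' threshold_search(c(5, 5, 3, 3), c(TRUE, TRUE, FALSE, FALSE))
#' @export
threshold_search <- function(values, labels, increment = 0.01) {
  check_two_classes(values, labels)
  grid <- grid_thresholds(values, increment)
  sp <- sort(values[labels])
  sn <- sort(values[!labels])
  np <- length(sp); nn <- length(sn)

  le_p <- findInterval(grid, sp)                     # #{pos <= t}
  le_n <- findInterval(grid, sn)                     # #{neg <= t}
  lt_p <- findInterval(grid, sp, left.open = TRUE)   # #{pos <  t}
  lt_n <- findInterval(grid, sn, left.open = TRUE)   # #{neg <  t}

  sum_high <- (np - le_p) / np + le_n / nn   # call positive iff score > t
  sum_low <- lt_p / np + (nn - lt_n) / nn    # call positive iff score < t

  best_high <- max(sum_high)
  best_low <- max(sum_low)
  if (best_high >= best_low) {
    orientation <- "positive_high"
    opt <- grid[sum_high == best_high]
    optimum <- best_high
  } else {
    orientation <- "positive_low"
    opt <- grid[sum_low == best_low]
    optimum <- best_low
  }
  best_threshold <- mean(opt)
  cs <- confusion_stats(values, labels, best_threshold, orientation)
  tibble::tibble(
    orientation = orientation,
    best_threshold = best_threshold,
    tie_min = opt[1],
    tie_max = opt[length(opt)],
    gap = if (optimum == 2) opt[length(opt)] - opt[1] else NA_real_,
    sensitivity = cs$sensitivity,
    specificity = cs$specificity,
    optimum = optimum
  )
}

#' Fisher's discriminant ratio
#'
#' Univariate class separability: squared difference of class means divided by
#' the sum of the class sample variances (n - 1 denominator). Invariant under
#' shifting or rescaling both classes together; zero iff the means are equal.
#' With distinct means but zero variance in both classes the ratio is
#' infinite and `Inf` is returned with a warning.
#'
#' @param pos_values,neg_values Numeric vectors, at least 2 values each.
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' fisher_discriminant_ratio(c(3, 5), c(1, 3))  # (4-2)^2 / (2+2) = 1
#' @export
fisher_discriminant_ratio <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2) {
    rlang::abort("need at least 2 values per class")
  }
  num <- (mean(pos_values) - mean(neg_values))^2
  den <- stats::var(pos_values) + stats::var(neg_values)
  if (num == 0) return(0)
  if (den == 0) {
    rlang::warn("zero within-class variance with distinct means: ratio is infinite")
    return(Inf)
  }
  num / den
}

#' Screen and rank every ion by single-ion discrimination
#'
#' Runs [threshold_search()] on the log10 peak areas of every ion for the
#' given comparison, attaches Fisher's discriminant ratio, and ranks: best
#' sensitivity + specificity first, then wider perfect-separation gap (ions
#' without one last), then larger Fisher ratio, then `(mz, rt)` ascending for
#' a deterministic order.
#'
#' @param table A log10-scale [peak_table()].
#' @param manifest Sample manifest tibble (`sample`, `group`).
#' @param comparison A [comparison()].
#' @param increment Threshold grid step (log10-area units).
#' @param perfect_only If `TRUE`, keep only ions whose grid optimum is
#'   sensitivity = specificity = 1.
#' @return A tibble of class `lmi_single_screen`, one row per ion: `mz`, `rt`,
#'   `orientation`, `best_threshold`, `max_threshold`, `min_threshold`, `gap`,
#'   `sensitivity`, `specificity`, `optimum`, `fisher_ratio`.
#' @export
rank_single_ions <- function(table, manifest, comparison,
                             increment = 0.01, perfect_only = FALSE) {
  validate_peak_table(table)
  if (!identical(table_scale(table), "log10")) {
    rlang::abort("single-ion screening expects a log10-scale table")
  }
  cls <- comparison_classes(table, manifest, comparison)
  m <- area_matrix(table)[, cls$samples, drop = FALSE]
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    ts <- threshold_search(v, cls$is_pos, increment)
    ts$fisher_ratio <- fisher_discriminant_ratio(v[cls$is_pos], v[!cls$is_pos])
    ts
  })
  out <- dplyr::bind_cols(table[, c("mz", "rt")], dplyr::bind_rows(res))
  out <- dplyr::rename(out, max_threshold = "tie_max", min_threshold = "tie_min")
  out <- dplyr::relocate(out, "max_threshold", "min_threshold",
                         .after = "best_threshold")
  out <- dplyr::arrange(out, dplyr::desc(.data$optimum), dplyr::desc(.data$gap),
                        dplyr::desc(.data$fisher_ratio), .data$mz, .data$rt)
  if (perfect_only) out <- dplyr::filter(out, .data$optimum == 2)
  structure(out,
    comparison = comparison, increment = increment,
    n_pos = sum(cls$is_pos), n_neg = sum(!cls$is_pos),
    class = c("lmi_single_screen", class(tibble::tibble()))
  )
}
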