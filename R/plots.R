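#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one ion's log10 areas by class, with its separating thresholds
#'
#' The display mirrors how perfectly discriminating ions are usually shown:
#' per-sample log10 areas jittered within class, with horizontal lines at the
#' maximum and minimum optimal thresholds from [threshold_search()].
#'
#' @inheritParams rank_single_ions
#' @param ion Length-2 numeric `c(mz, rt)`.
#' @return A ggplot object.
#' @export
plot_ion <- function(table, manifest, comparison, ion, increment = 0.01) {
  if (!identical(table_scale(table), "log10")) {
    rlang::abort("plot_ion expects a log10-scale table")
  }
  cls <- comparison_classes(table, manifest, comparison)
  v <- area_matrix(table)[find_ion(table, ion), cls$samples]
  ts <- threshold_search(v, cls$is_pos, increment)
  df <- tibble::tibble(
    class = factor(ifelse(cls$is_pos, "positive", "negative"),
                   levels = c("positive", "negative")),
    log_area = unname(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$log_area)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(ts$tie_min, ts$tie_max),
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Ion mz %.4f, RT %.2f min", ion[1], ion[2]),
      subtitle = sprintf("%s | sens %.1f%%, spec %.1f%%", comparison$name,
                         100 * ts$sensitivity, 100 * ts$specificity),
      x = NULL, y = "log10 peak area"
    )
}

#' @describeIn plot_ion Ranked single-ion screen: sensitivity + specificity of
#'   the top ions.
#' @param object Screen result.
#' @param top_n Ions shown.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.lmi_single_screen <- function(object, top_n = 25, ...) {
  df <- utils::head(tibble::as_tibble(unclass_screen(object)), top_n)
  df$ion <- sprintf("%.4f/%.2f", df$mz, df$rt)
  df$ion <- factor(df$ion, levels = rev(df$ion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$optimum, y = .data$ion)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 2, linetype = "dotted") +
    ggplot2::labs(x = "sensitivity + specificity at best threshold",
                  y = "ion (mz / RT)",
                  title = attr(object, "comparison")$name)
}

#' @describeIn plot_ion Pair screen: sensitivity vs specificity of selected
#'   ordered pairs.
#' @exportS3Method ggplot2::autoplot
autoplot.lmi_pair_screen <- function(object, ...) {
  df <- tibble::as_tibble(unclass_screen(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s (%s)", attr(object, "comparison")$name,
                                  attr(object, "method")))
}
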