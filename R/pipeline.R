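#' Configure an end-to-end screening run
#'
#' @param table Path to a peak-table TSV, or a [peak_table()] (raw scale).
#' @param manifest Path to a manifest TSV, or a manifest tibble.
#' @param comparisons Non-empty named list of [comparison()] objects.
#' @param out_dir Output directory (created if needed).
#' @param increment Threshold grid step.
#' @param pair_methods Pair-score methods to screen (see [pair_scores()]).
#' @param min_sensitivity,min_specificity Pair selection criterion.
#' @param normalize Apply [normalize_total_area()] before the log transform.
#' @param stats_top_n Number of top-ranked ions per comparison to pass to the
#'   group-comparison stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table, manifest, comparisons, out_dir,
                            increment = 0.01,
                            pair_methods = c("ratio_of_logs", "log_of_ratio"),
                            min_sensitivity = 0.90, min_specificity = 0.90,
                            normalize = FALSE, stats_top_n = 5L) {
  if (!length(comparisons)) {
    rlang::abort("`comparisons` must be non-empty")
  }
  if (!all(vapply(comparisons, inherits, logical(1), "comparison"))) {
    rlang::abort("`comparisons` must be a list of comparison() objects")
  }
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    names(comparisons) <- vapply(
      comparisons, function(x) gsub("[^A-Za-z0-9]+", "_", x$name), character(1)
    )
  }
  pair_methods <- match.arg(pair_methods, several.ok = TRUE)
  for (p in c(table, manifest)) {
    if (is.character(p) && !file.exists(p)) {
      rlang::abort(sprintf("file not found: %s", p))
    }
  }
  structure(
    list(
      table = table, manifest = manifest, comparisons = comparisons,
      out_dir = out_dir, increment = increment, pair_methods = pair_methods,
      min_sensitivity = min_sensitivity, min_specificity = min_specificity,
      normalize = normalize, stats_top_n = as.integer(stats_top_n)
    ),
    class = "pipeline_config"
  )
}

#' Run the full screening pipeline
#'
#' Stages: read/validate inputs, optional total-area normalization, log10
#' transform, then per comparison a single-ion screen, an ordered-pair screen
#' per configured pair method, and normality-gated group comparisons for the
#' top-ranked ions. Each stage's table is written under `out_dir`
#' (`single_<comparison>.tsv`, `pairs_<comparison>_<method>.tsv`,
#' `stats_<comparison>.tsv`) together with a JSON run manifest echoing the
#' configuration and the screening bookkeeping (ions screened, ordered pairs
#' screened and skipped, hits). Output is deterministic given inputs and
#' configuration. A failing stage aborts with the stage name, and an
#' `INCOMPLETE` marker file is left in `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `single` and `pairs` (per-comparison results),
#'   `stats`, and `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  writeLines("pipeline run in progress", marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("pipeline failed at stage: %s", name), marker)
      rlang::abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                   parent = e)
    })
  }

  table <- stage("read_table", {
    t <- if (is.character(config$table)) read_peak_table(config$table) else config$table
    validate_peak_table(t)
    t
  })
  manifest <- stage("read_manifest", {
    m <- if (is.character(config$manifest)) read_manifest(config$manifest) else config$manifest
    validate_manifest(m)
    m
  })
  if (config$normalize) {
    table <- stage("normalize", normalize_total_area(table))
  }
  ltab <- stage("log_transform", log_transform(table))

  singles <- list()
  pairs <- list()
  stats_rows <- list()
  counts <- list()
  for (cname in names(config$comparisons)) {
    cmp <- config$comparisons[[cname]]
    s <- stage(paste0("single_ion[", cname, "]"), {
      rank_single_ions(ltab, manifest, cmp, increment = config$increment)
    })
    singles[[cname]] <- s
    cat(render_results_table(s, "table2"),
        file = file.path(config$out_dir, sprintf("single_%s.tsv", cname)))
    pr_counts <- list()
    for (method in config$pair_methods) {
      p <- stage(paste0("pair_screen[", cname, ",", method, "]"), {
        screen_pairs(ltab, manifest, cmp, method = method,
                     min_sensitivity = config$min_sensitivity,
                     min_specificity = config$min_specificity,
                     increment = config$increment)
      })
      pairs[[paste(cname, method, sep = ".")]] <- p
      cat(render_results_table(p, "table3_4"),
          file = file.path(config$out_dir, sprintf("pairs_%s_%s.tsv", cname, method)))
      pr_counts[[method]] <- list(
        pairs_screened = attr(p, "n_pairs_screened"),
        pairs_skipped = attr(p, "n_pairs_skipped"),
        hits = nrow(p)
      )
    }
    st <- stage(paste0("group_stats[", cname, "]"), {
      top <- utils::head(s, config$stats_top_n)
      purrr::map(seq_len(nrow(top)), function(i) {
        compare_groups(ltab, manifest, c(top$mz[i], top$rt[i]),
                       cmp$positive, cmp$negative)
      })
    })
    st <- dplyr::bind_rows(st)
    if (nrow(st)) st$comparison <- cmp$name
    stats_rows[[cname]] <- st
    readr::write_tsv(st, file.path(config$out_dir, sprintf("stats_%s.tsv", cname)),
                     progress = FALSE)
    counts[[cname]] <- list(
      ions_screened = nrow(s),
      perfect_ions = sum(s$optimum == 2),
      pair_methods = pr_counts
    )
  }

  run_manifest <- list(
    package = "lmiscreen",
    version = as.character(utils::packageVersion("lmiscreen")),
    increment = config$increment,
    pair_methods = config$pair_methods,
    min_sensitivity = config$min_sensitivity,
    min_specificity = config$min_specificity,
    normalize = config$normalize,
    n_ions = nrow(table),
    n_samples = length(sample_ids(table)),
    comparisons = counts
  )
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(marker)
  invisible(list(single = singles, pairs = pairs,
                 stats = dplyr::bind_rows(stats_rows),
                 run_manifest = run_manifest))
}

#' Render a screening result as a delimited report table
#'
#' `"table2"` renders a single-ion screen with the separating-threshold
#' columns (maximum, minimum, their difference) and Fisher's discriminant
#' ratio; `"table3_4"` renders a pair screen with the numerator/minuend and
#' denominator/subtrahend ion coordinates. Sensitivity and specificity are
#' rendered as percentages with two decimals, rounded half-up (0.9020 becomes
#' `"90.20%"`).
#'
#' @param results An `lmi_single_screen` or `lmi_pair_screen` tibble.
#' @param style `"table2"` or `"table3_4"`.
#' @return A single string of tab-separated lines (header first).
#' @export
render_results_table <- function(results, style = c("table2", "table3_4")) {
  style <- match.arg(style)
  pct <- function(x) sprintf("%.2f%%", floor(x * 10000 + 0.5) / 100)
  num <- function(x) vapply(x, function(v) format(v, digits = 15), character(1))
  if (style == "table2") {
    if (!inherits(results, "lmi_single_screen")) {
      rlang::abort("style `table2` renders a single-ion screen")
    }
    df <- data.frame(
      mz = num(results$mz), rt = num(results$rt),
      max_threshold = num(results$max_threshold),
      min_threshold = num(results$min_threshold),
      difference = num(results$max_threshold - results$min_threshold),
      fisher_ratio = num(results$fisher_ratio),
      sensitivity = pct(results$sensitivity),
      specificity = pct(results$specificity),
      orientation = results$orientation,
      check.names = FALSE
    )
  } else {
    if (!inherits(results, "lmi_pair_screen")) {
      rlang::abort("style `table3_4` renders a pair screen")
    }
    df <- data.frame(
      mz_a = num(results$mz_a), rt_a = num(results$rt_a),
      mz_b = num(results$mz_b), rt_b = num(results$rt_b),
      method = results$method,
      threshold = num(results$threshold),
      sensitivity = pct(results$sensitivity),
      specificity = pct(results$specificity),
      check.names = FALSE
    )
  }
  paste0(
    paste(
      c(paste(names(df), collapse = "\t"),
        if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))),
      collapse = "\n"
    ),
    "\n"
  )
}

# Parse a rendered report back into a tibble (percent columns become
# fractions again, to the rendered precision).
parse_rendered <- function(text) {
  df <- readr::read_tsv(I(text), col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in names(df)) {
    v <- df[[col]]
    if (all(grepl("%$", v)) && nrow(df)) {
      df[[col]] <- as.numeric(sub("%$", "", v)) / 100
    } else {
      n <- suppressWarnings(as.numeric(v))
      if (!anyNA(n) || !nrow(df)) df[[col]] <- n
    }
  }
  df
}
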