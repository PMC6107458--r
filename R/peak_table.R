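#' Construct a peak table
#'
#' A peak table is the ions-by-samples matrix exported by LC-MS peak-finding
#' software: one row per low-mass ion (LMI), identified by its mass-to-charge
#' ratio `mz` and retention time `rt` (minutes), and one numeric peak-area
#' column per sample. It is represented as a tibble with columns `mz`, `rt`,
#' then the sample columns, and carries two attributes: `scale` (`"raw"` peak
#' areas or `"log10"` transformed values) and `provenance` (a named character
#' vector of free-form acquisition / peak-finding metadata).
#'
#' An ion is identified by the `(mz, rt)` pair, never by `mz` alone: distinct
#' ions can share a mass value and differ only in retention time.
#'
#' @param x A data frame with numeric columns `mz`, `rt` and one numeric
#'   column per sample.
#' @param scale `"raw"` or `"log10"`.
#' @param provenance Named character vector of acquisition metadata.
#' @return A `peak_table` (a tibble subclass).
#' @examples
#' pt <- peak_table(tibble::tibble(
#'   mz = c(283.2018, 305.1860), rt = c(10.17, 10.17),
#'   S1 = c(1200, 40), S2 = c(900, 0)
#' ))
#' pt
#' @export
peak_table <- function(x, scale = c("raw", "log10"), provenance = character()) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  out <- structure(x,
    scale = scale,
    provenance = provenance,
    class = c("peak_table", class(x))
  )
  validate_peak_table(out)
  out
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf(
    "# A peak table: %d ions x %d samples (scale: %s)\n",
    nrow(x), length(sample_ids(x)), table_scale(x)
  ))
  NextMethod()
  invisible(x)
}

#' Sample identifiers of a peak table
#'
#' @param table A [peak_table()].
#' @return Character vector of sample column names (everything but `mz`, `rt`).
#' @export
sample_ids <- function(table) {
  setdiff(names(table), c("mz", "rt"))
}

#' @rdname sample_ids
#' @export
table_scale <- function(table) {
  attr(table, "scale") %||% "raw"
}

#' Peak areas as a numeric matrix
#'
#' @param table A [peak_table()].
#' @return Numeric matrix (ions x samples); columns named by sample ID.
#' @export
area_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, sample_ids(table), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

validate_peak_table <- function(table) {
  cols <- names(table)
  if (!all(c("mz", "rt") %in% cols)) {
    rlang::abort("a peak table needs `mz` and `rt` columns")
  }
  if (!is.numeric(table$mz) || !is.numeric(table$rt)) {
    rlang::abort("`mz` and `rt` must be numeric")
  }
  if (any(table$mz <= 0)) rlang::abort("`mz` must be positive")
  if (any(table$rt < 0)) rlang::abort("`rt` must be non-negative")
  key <- paste(format(table$mz, digits = 15), format(table$rt, digits = 15))
  if (anyDuplicated(key)) {
    dup <- table[duplicated(key), c("mz", "rt")]
    rlang::abort(sprintf(
      "duplicate (mz, rt) ion identity: %s",
      paste(sprintf("(%g, %g)", dup$mz, dup$rt), collapse = ", ")
    ))
  }
  samples <- sample_ids(table)
  if (anyDuplicated(samples)) rlang::abort("sample identifiers must be unique")
  for (s in samples) {
    v <- table[[s]]
    if (!is.numeric(v)) rlang::abort(sprintf("sample column `%s` is not numeric", s))
    if (anyNA(v)) {
      rlang::abort(sprintf(
        "missing area in sample `%s`, row %d", s, which(is.na(v))[1]
      ))
    }
    if (identical(table_scale(table), "raw") && any(v < 0)) {
      i <- which(v < 0)[1]
      rlang::abort(sprintf(
        "negative peak area %g in sample `%s`, row %d (ion mz=%g, rt=%g)",
        v[i], s, i, table$mz[i], table$rt[i]
      ))
    }
  }
  invisible(table)
}

#' Read a peak table from a delimited text file
#'
#' The expected layout is the one peak-finding software exports: a header row
#' `mz`, `rt`, then one column per sample, one data row per ion. Optional
#' leading comment lines `# scale=raw|log10` and `# provenance=key: value; ...`
#' carry the scale marker and acquisition metadata written by
#' [write_peak_table()]; a file without a scale marker is read as raw areas.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; tab by default, `","` is accepted.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, delim = "\t") {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  header <- parse_header_comments(path)
  raw <- readr::read_delim(
    path,
    delim = delim, comment = "#", col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("mz", "rt") %in% names(raw))) {
    rlang::abort("peak-table file must have `mz` and `rt` columns first")
  }
  out <- raw
  for (col in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      rlang::abort(sprintf(
        "non-numeric value \"%s\" in column `%s`, row %d",
        raw[[col]][bad[1]], col, bad[1]
      ))
    }
    out[[col]] <- v
  }
  peak_table(out,
    scale = header$scale %||% "raw",
    provenance = header$provenance %||% character()
  )
}

parse_header_comments <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  scale <- NULL
  provenance <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    body <- sub("^#\\s*", "", line)
    if (grepl("^scale=", body)) {
      scale <- sub("^scale=", "", body)
      if (!scale %in% c("raw", "log10")) {
        rlang::abort(sprintf("unknown scale marker `%s`", scale))
      }
    } else if (grepl("^provenance=", body)) {
      items <- strsplit(sub("^provenance=", "", body), "; ", fixed = TRUE)[[1]]
      kv <- strsplit(items, ": ", fixed = TRUE)
      provenance <- stats::setNames(
        vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1)),
        vapply(kv, `[[`, character(1), 1)
      )
    }
  }
  list(scale = scale, provenance = provenance)
}

#' Write a peak table to a delimited text file
#'
#' Writes comment lines carrying the scale marker and provenance, then the
#' tab-separated table. [read_peak_table()] restores an identical table, so
#' raw- and log10-scale files cannot be confused.
#'
#' @param table A [peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  validate_peak_table(table)
  lines <- sprintf("# scale=%s", table_scale(table))
  prov <- attr(table, "provenance")
  if (length(prov)) {
    lines <- c(lines, sprintf(
      "# provenance=%s",
      paste(sprintf("%s: %s", names(prov), unname(prov)), collapse = "; ")
    ))
  }
  writeLines(lines, path)
  readr::write_tsv(as.data.frame(table), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Log10-transform peak areas with the zero-area rule
#'
#' Converts a raw-scale peak table to common logarithms. A peak area of
#' exactly 0 (a dropout) is set to 1 before taking the logarithm, so its
#' transformed value is 0; no other value is modified. In particular, areas in
#' (0, 1) pass through `log10` unchanged and become negative.
#'
#' @param table A raw-scale [peak_table()].
#' @return A log10-scale `peak_table`.
#' @examples
#' pt <- peak_table(tibble::tibble(mz = 100, rt = 1, S1 = 0, S2 = 1000))
#' area_matrix(log_transform(pt))   # 0 and 3
#' @export
log_transform <- function(table) {
  validate_peak_table(table)
  if (!identical(table_scale(table), "raw")) {
    rlang::abort("table is already on the log10 scale")
  }
  out <- table
  for (s in sample_ids(table)) {
    v <- table[[s]]
    v[v == 0] <- 1
    out[[s]] <- log10(v)
  }
  attr(out, "scale") <- "log10"
  out
}

#' Total-area-sums normalization
#'
#' Rescales every sample column by one scalar so that all samples have the
#' same total peak area, equal to the mean of the original per-sample totals.
#' Relative areas within a sample (and so per-sample ion rank order) are
#' preserved. Applied on the raw scale, before [log_transform()].
#'
#' @param table A raw-scale [peak_table()].
#' @return A raw-scale `peak_table` with equal column sums.
#' @export
normalize_total_area <- function(table) {
  validate_peak_table(table)
  if (!identical(table_scale(table), "raw")) {
    rlang::abort("total-area normalization is defined on raw areas")
  }
  samples <- sample_ids(table)
  totals <- vapply(samples, function(s) sum(table[[s]]), numeric(1))
  if (any(totals == 0)) {
    rlang::abort(sprintf(
      "sample `%s` has zero total area; scaling factor undefined",
      samples[which(totals == 0)[1]]
    ))
  }
  target <- mean(totals)
  out <- table
  for (i in seq_along(samples)) {
    out[[samples[i]]] <- table[[samples[i]]] * (target / totals[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
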