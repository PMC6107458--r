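#' Read or write a cohort manifest
#'
#' A manifest maps each sample identifier to exactly one group label (e.g.
#' `PC`, `BTC`, `CRC`, `OVC`, `control`, `PC_HRG`, `BTC_HRG`). Stored as a
#' two-column TSV (`sample`, `group`).
#'
#' @param path Path to a TSV file with columns `sample` and `group`.
#' @return A tibble with character columns `sample` and `group`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  if (!all(c("sample", "group") %in% names(manifest))) {
    rlang::abort("manifest needs `sample` and `group` columns")
  }
  if (anyDuplicated(manifest$sample)) {
    rlang::abort("each sample may carry exactly one group label")
  }
  invisible(manifest)
}

#' Define a two-class comparison
#'
#' A comparison names the positive-class and negative-class group labels for a
#' discrimination screen, e.g. cancers of interest versus everything else.
#' The study contrasts shipped by [default_comparisons()] are
#' PC/BTC vs control/CRC/OVC, PC vs BTC, and PC/BTC vs their high-risk groups.
#'
#' @param positive Character vector of positive-class group labels.
#' @param negative Character vector of negative-class group labels; disjoint
#'   from `positive`.
#' @param name Optional display name.
#' @return A `comparison` object.
#' @examples
#' comparison(c("PC", "BTC"), c("control", "CRC", "OVC"))
#' @export
comparison <- function(positive, negative, name = NULL) {
  positive <- as.character(positive)
  negative <- as.character(negative)
  if (!length(positive) || !length(negative)) {
    rlang::abort("both classes of a comparison must be non-empty")
  }
  if (length(intersect(positive, negative))) {
    rlang::abort("positive and negative groups must be disjoint")
  }
  name <- name %||% paste(
    paste(positive, collapse = "+"), "vs", paste(negative, collapse = "+")
  )
  structure(
    list(positive = positive, negative = negative, name = name),
    class = "comparison"
  )
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s\n", x$name))
  invisible(x)
}

#' @rdname comparison
#' @return `default_comparisons()`: a named list of the three study contrasts.
#' @export
default_comparisons <- function() {
  list(
    cancer_vs_other = comparison(c("PC", "BTC"), c("control", "CRC", "OVC"),
                                 "PC+BTC vs control+CRC+OVC"),
    pc_vs_btc = comparison("PC", "BTC", "PC vs BTC"),
    cancer_vs_hrg = comparison(c("PC", "BTC"), c("PC_HRG", "BTC_HRG"),
                               "PC+BTC vs PC_HRG+BTC_HRG")
  )
}

# Resolve a comparison against a peak table + manifest: samples in either
# class (joined by name, so column order never matters) and their class flags.
comparison_classes <- function(table, manifest, comparison) {
  validate_manifest(manifest)
  stopifnot(inherits(comparison, "comparison"))
  samples <- sample_ids(table)
  missing <- setdiff(samples, manifest$sample)
  if (length(missing)) {
    rlang::abort(sprintf(
      "samples absent from manifest: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  grp <- manifest$group[match(samples, manifest$sample)]
  keep <- grp %in% c(comparison$positive, comparison$negative)
  samples <- samples[keep]
  is_pos <- grp[keep] %in% comparison$positive
  if (!any(is_pos) || all(is_pos)) {
    rlang::abort(sprintf(
      "comparison `%s` selects zero samples in one class", comparison$name
    ))
  }
  list(samples = samples, is_pos = is_pos)
}
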