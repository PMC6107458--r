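#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy screening results
#'
#' `tidy()` returns the result rows as a plain tibble; `glance()` returns a
#' one-row summary of the screen.
#'
#' @param x An `lmi_single_screen`, `lmi_pair_screen`, or
#'   `lmi_group_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @name lmiscreen-tidiers
NULL

#' @rdname lmiscreen-tidiers
#' @exportS3Method generics::tidy
tidy.lmi_single_screen <- function(x, ...) {
  tibble::as_tibble(unclass_screen(x))
}

#' @rdname lmiscreen-tidiers
#' @exportS3Method generics::tidy
tidy.lmi_pair_screen <- function(x, ...) {
  tibble::as_tibble(unclass_screen(x))
}

#' @rdname lmiscreen-tidiers
#' @exportS3Method generics::tidy
tidy.lmi_group_comparison <- function(x, ...) {
  tibble::as_tibble(unclass_screen(x))
}

#' @rdname lmiscreen-tidiers
#' @exportS3Method generics::glance
glance.lmi_single_screen <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison")$name,
    n_ions = nrow(x),
    n_perfect = sum(x$optimum == 2),
    best_optimum = if (nrow(x)) max(x$optimum) else NA_real_,
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg")
  )
}

#' @rdname lmiscreen-tidiers
#' @exportS3Method generics::glance
glance.lmi_pair_screen <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison")$name,
    method = attr(x, "method"),
    n_hits = nrow(x),
    pairs_screened = attr(x, "n_pairs_screened"),
    pairs_skipped = attr(x, "n_pairs_skipped"),
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg")
  )
}

unclass_screen <- function(x) {
  for (a in c("comparison", "method", "increment", "min_sensitivity",
              "min_specificity", "n_pairs_screened", "n_pairs_skipped",
              "n_pos", "n_neg")) {
    attr(x, a) <- NULL
  }
  class(x) <- class(tibble::tibble())
  x
}
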