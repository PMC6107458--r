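#' Per-sample dual-ion discriminant scores
#'
#' Two pair scores are defined on log10 peak areas (after the zero-area rule):
#' `log_of_ratio` is `log10(a) - log10(b)` — the logarithm of the raw-area
#' ratio — and `ratio_of_logs` is `log10(a) / log10(b)`. The first ion plays
#' the minuend / numerator role, the second the subtrahend / denominator.
#' `log_of_ratio` is antisymmetric under swapping the two ions and, on
#' all-positive tables, invariant under total-area normalization;
#' `ratio_of_logs` is neither.
#'
#' `ratio_of_logs` is undefined whenever the denominator ion's log10 area is 0
#' for some sample (a raw area of exactly 1, or a zero-area dropout mapped to
#' 1 by the zero rule); this raises an error of class
#' `lmiscreen_undefined_ratio`. During screening such ordered pairs are
#' skipped and counted (or the offending samples dropped, by policy).
#'
#' @param table A log10-scale [peak_table()].
#' @param ion_a,ion_b Length-2 numeric vectors `c(mz, rt)` identifying the two
#'   (distinct) ions.
#' @param method `"log_of_ratio"` or `"ratio_of_logs"`.
#' @return Tibble with one row per sample: `sample`, `score`.
#' @examples
#' pt <- log_transform(peak_table(tibble::tibble(
#'   mz = c(100, 200), rt = c(1, 2), S1 = c(1000, 100)
#' )))
#' pair_scores(pt, c(100, 1), c(200, 2), "ratio_of_logs")$score  # 1.5
#' pair_scores(pt, c(100, 1), c(200, 2), "log_of_ratio")$score   # 1.0
#' @export
pair_scores <- function(table, ion_a, ion_b,
                        method = c("log_of_ratio", "ratio_of_logs")) {
  method <- match.arg(method)
  if (!identical(table_scale(table), "log10")) {
    rlang::abort("pair scores are defined on the log10 table")
  }
  ia <- find_ion(table, ion_a)
  ib <- find_ion(table, ion_b)
  if (ia == ib) rlang::abort("the two ions of a pair must differ")
  m <- area_matrix(table)
  la <- m[ia, ]
  lb <- m[ib, ]
  score <- if (method == "log_of_ratio") {
    la - lb
  } else {
    if (any(lb == 0)) {
      rlang::abort(
        sprintf(
          "ratio_of_logs undefined: denominator ion (mz=%g, rt=%g) has log10 area 0 in sample `%s`",
          ion_b[1], ion_b[2], sample_ids(table)[which(lb == 0)[1]]
        ),
        class = "lmiscreen_undefined_ratio"
      )
    }
    la / lb
  }
  tibble::tibble(sample = sample_ids(table), score = unname(score))
}

find_ion <- function(table, ion) {
  i <- which(table$mz == ion[1] & table$rt == ion[2])
  if (length(i) != 1) {
    rlang::abort(sprintf("ion (mz=%g, rt=%g) not found in table", ion[1], ion[2]))
  }
  i
}

#' Enumerate ordered ion pairs
#'
#' Every unordered combination of two ions is examined twice, once per role
#' assignment, giving N(N-1) ordered pairs in deterministic lexicographic
#' order by the `(mz, rt)` of the first then second ion.
#'
#' `enumerate_ordered_pairs()` materializes the pairs and is meant for small
#' ion lists; at full scale (thousands of ions) the screen iterates the same
#' order internally without materializing, and `count_ordered_pairs()` tallies
#' the enumeration with a streaming block counter.
#'
#' @param ions A data frame with columns `mz`, `rt` (e.g. a peak table).
#' @return Tibble with columns `mz_a`, `rt_a`, `mz_b`, `rt_b`.
#' @examples
#' enumerate_ordered_pairs(tibble::tibble(mz = c(1, 2, 3), rt = 0))
#' count_ordered_pairs(6724)  # 45212652
#' @export
enumerate_ordered_pairs <- function(ions) {
  if (nrow(ions) < 2) rlang::abort("need at least 2 ions")
  ord <- order(ions$mz, ions$rt)
  mz <- ions$mz[ord]
  rt <- ions$rt[ord]
  n <- length(mz)
  a <- rep(seq_len(n), each = n)
  b <- rep(seq_len(n), times = n)
  keep <- a != b
  tibble::tibble(
    mz_a = mz[a[keep]], rt_a = rt[a[keep]],
    mz_b = mz[b[keep]], rt_b = rt[b[keep]]
  )
}

#' @rdname enumerate_ordered_pairs
#' @param n_ions Number of ions.
#' @param chunk_size Ions per counted block.
#' @export
count_ordered_pairs <- function(n_ions, chunk_size = 4096L) {
  n_ions <- as.numeric(n_ions)
  if (n_ions < 2) return(0)
  total <- 0
  i <- 1
  while (i <= n_ions) {
    j <- min(i + chunk_size - 1, n_ions)
    total <- total + (j - i + 1) * (n_ions - 1)  # each first ion pairs with all others
    i <- j + 1
  }
  total
}

#' Exhaustive ordered-pair discrimination screen
#'
#' For every ordered ion pair, computes the chosen pair score for all
#' comparison samples, runs the grid threshold search ([threshold_search()]
#' semantics, implemented as a compiled sort-and-sweep proven equivalent), and
#' keeps pairs whose sensitivity and specificity at the best (tie-averaged)
#' threshold both reach the selection criterion. Results stream through a
#' fixed-size accumulator; the full N(N-1) score set is never materialized.
#'
#' @inheritParams rank_single_ions
#' @param method Pair score, see [pair_scores()].
#' @param min_sensitivity,min_specificity Selection criterion; both must be
#'   met (default 0.90 each).
#' @param zero_denominator Policy for `ratio_of_logs` pairs whose denominator
#'   log10 area is 0 in some sample: `"skip_pair"` (default; the ordered pair
#'   is skipped and counted) or `"drop_sample"` (offending samples are dropped
#'   for that pair; the pair is skipped if a class empties).
#' @return A tibble of class `lmi_pair_screen`, one row per selected ordered
#'   pair — first ion is numerator/minuend, second denominator/subtrahend —
#'   sorted by sensitivity + specificity descending then pair order.
#'   Attributes `n_pairs_screened` and `n_pairs_skipped` carry the bookkeeping.
#' @export
screen_pairs <- function(table, manifest, comparison,
                         method = c("log_of_ratio", "ratio_of_logs"),
                         min_sensitivity = 0.90, min_specificity = 0.90,
                         increment = 0.01,
                         zero_denominator = c("skip_pair", "drop_sample")) {
  method <- match.arg(method)
  zero_denominator <- match.arg(zero_denominator)
  validate_peak_table(table)
  if (!identical(table_scale(table), "log10")) {
    rlang::abort("pair screening expects a log10-scale table")
  }
  if (nrow(table) < 2) rlang::abort("need at least 2 ions")
  cls <- comparison_classes(table, manifest, comparison)

  ord <- order(table$mz, table$rt)
  mz <- table$mz[ord]
  rt <- table$rt[ord]
  m <- area_matrix(table)[ord, cls$samples, drop = FALSE]

  res <- cpp_screen_pairs(
    m, cls$is_pos,
    method_code = if (method == "log_of_ratio") 0L else 1L,
    min_sens = min_sensitivity, min_spec = min_specificity,
    increment = increment,
    zero_policy = if (zero_denominator == "skip_pair") 0L else 1L
  )
  out <- tibble::tibble(
    mz_a = mz[res$a], rt_a = rt[res$a],
    mz_b = mz[res$b], rt_b = rt[res$b],
    method = method,
    orientation = c("positive_high", "positive_low")[res$orientation + 1L],
    threshold = res$threshold,
    sensitivity = res$sensitivity,
    specificity = res$specificity,
    optimum = res$optimum
  )
  out <- dplyr::arrange(out,
    dplyr::desc(.data$sensitivity + .data$specificity),
    .data$mz_a, .data$rt_a, .data$mz_b, .data$rt_b
  )
  structure(out,
    comparison = comparison, method = method, increment = increment,
    min_sensitivity = min_sensitivity, min_specificity = min_specificity,
    n_pairs_screened = res$n_screened, n_pairs_skipped = res$n_skipped,
    n_pos = sum(cls$is_pos), n_neg = sum(!cls$is_pos),
    class = c("lmi_pair_screen", class(tibble::tibble()))
  )
}
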