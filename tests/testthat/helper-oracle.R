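# Independent brute-force oracles. These re-derive the reference semantics
# with direct elementwise comparisons (sum(pos > t) etc.) and never share
# code with the package implementation.

oracle_grid <- function(values, increment) {
  k_lo <- floor(min(values) / increment + 1e-9)
  k_hi <- ceiling(max(values) / increment - 1e-9)
  (k_lo:k_hi) * increment
}

oracle_threshold_search <- function(values, labels, increment = 0.01) {
  grid <- oracle_grid(values, increment)
  pos <- values[labels]
  neg <- values[!labels]
  sum_at <- function(t, orient) {
    if (orient == "positive_high") {
      sum(pos > t) / length(pos) + sum(neg <= t) / length(neg)
    } else {
      sum(pos < t) / length(pos) + sum(neg >= t) / length(neg)
    }
  }
  s_high <- vapply(grid, sum_at, numeric(1), orient = "positive_high")
  s_low <- vapply(grid, sum_at, numeric(1), orient = "positive_low")
  if (max(s_high) >= max(s_low)) {
    orientation <- "positive_high"
    opt <- grid[s_high == max(s_high)]
    optimum <- max(s_high)
  } else {
    orientation <- "positive_low"
    opt <- grid[s_low == max(s_low)]
    optimum <- max(s_low)
  }
  thr <- mean(opt)
  sens <- if (orientation == "positive_high") {
    sum(pos > thr) / length(pos)
  } else {
    sum(pos < thr) / length(pos)
  }
  spec <- if (orientation == "positive_high") {
    sum(neg <= thr) / length(neg)
  } else {
    sum(neg >= thr) / length(neg)
  }
  list(
    orientation = orientation, best_threshold = thr,
    tie_min = min(opt), tie_max = max(opt),
    gap = if (optimum == 2) max(opt) - min(opt) else NA_real_,
    sensitivity = sens, specificity = spec, optimum = optimum
  )
}

# naive double loop + grid search over ordered pairs, on a log10 matrix with
# rows sorted lexicographically by (mz, rt)
oracle_screen_pairs <- function(logmat, is_pos, method,
                                min_sens = 0.9, min_spec = 0.9,
                                increment = 0.01) {
  n <- nrow(logmat)
  hits <- list()
  screened <- 0
  skipped <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (method == "ratio_of_logs") {
        if (any(logmat[b, ] == 0)) {
          skipped <- skipped + 1
          next
        }
        sc <- logmat[a, ] / logmat[b, ]
      } else {
        sc <- logmat[a, ] - logmat[b, ]
      }
      screened <- screened + 1
      r <- oracle_threshold_search(sc, is_pos, increment)
      if (r$sensitivity >= min_sens && r$specificity >= min_spec) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          a = a, b = b, orientation = r$orientation,
          threshold = r$best_threshold,
          sensitivity = r$sensitivity, specificity = r$specificity,
          optimum = r$optimum
        )
      }
    }
  }
  list(hits = dplyr::bind_rows(hits), screened = screened, skipped = skipped)
}

random_peak_table <- function(n_ions, n_samples, zero_frac = 0,
                              scale = "raw") {
  areas <- matrix(10^stats::rnorm(n_ions * n_samples, mean = 4, sd = 1),
                  nrow = n_ions)
  if (zero_frac > 0) {
    areas[stats::runif(length(areas)) < zero_frac] <- 0
  }
  df <- tibble::as_tibble(as.data.frame(areas))
  names(df) <- sprintf("S%02d", seq_len(n_samples))
  tbl <- peak_table(
    dplyr::bind_cols(
      tibble::tibble(
        mz = round(seq(100, 900, length.out = n_ions) +
                     stats::runif(n_ions, 0, 0.05), 4),
        rt = round(stats::runif(n_ions, 0, 20), 2)
      ),
      df
    ),
    scale = "raw",
    provenance = c(source = "random fixture")
  )
  if (scale == "log10") log_transform(tbl) else tbl
}
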