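make_log_table <- function(areas, samples = NULL) {
  n <- nrow(areas)
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(areas)))
  df <- tibble::as_tibble(as.data.frame(areas))
  names(df) <- samples
  log_transform(peak_table(dplyr::bind_cols(
    tibble::tibble(mz = 100 + seq_len(n), rt = seq_len(n)), df
  )))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pair scores follow the two dual-ion definitions", {
  lt <- make_log_table(matrix(c(1000, 100), nrow = 2))
  a <- c(101, 1); b <- c(102, 2)
  expect_equal(pair_scores(lt, a, b, "ratio_of_logs")$score, 3 / 2)
  expect_equal(pair_scores(lt, a, b, "log_of_ratio")$score, 3 - 2)
  # antisymmetry of the difference score under role swap
  expect_equal(pair_scores(lt, b, a, "log_of_ratio")$score, -(3 - 2))
})

test_that("log-of-ratio antisymmetry holds on random tables", {
  withr::local_seed(41)
  lt <- random_peak_table(6, 8, zero_frac = 0.15, scale = "log10")
  ions <- tibble::as_tibble(lt)[, c("mz", "rt")]
  for (i in 1:5) {
    ab <- sample(nrow(ions), 2)
    s1 <- pair_scores(lt, unlist(ions[ab[1], ]), unlist(ions[ab[2], ]))$score
    s2 <- pair_scores(lt, unlist(ions[ab[2], ]), unlist(ions[ab[1], ]))$score
    expect_equal(s1, -s2)
  }
})

test_that("a zero denominator log-area makes ratio_of_logs undefined", {
  # raw area 1 has log10 = 0, exactly the dropout value after the zero rule
  lt <- make_log_table(matrix(c(1000, 100, 500, 1), nrow = 2, byrow = TRUE))
  expect_error(
    pair_scores(lt, c(101, 1), c(102, 2), "ratio_of_logs"),
    class = "lmiscreen_undefined_ratio"
  )
  # the difference score is still defined
  expect_equal(pair_scores(lt, c(101, 1), c(102, 2), "log_of_ratio")$score,
               c(3 - log10(500), 2 - 0))
})

test_that("ordered-pair enumeration yields N(N-1) pairs in lexicographic order", {
  ions3 <- tibble::tibble(mz = c(3, 1, 2), rt = 0)
  pairs3 <- enumerate_ordered_pairs(ions3)
  expect_equal(nrow(pairs3), 6)
  expect_equal(pairs3$mz_a, c(1, 1, 2, 2, 3, 3))

  ions2 <- tibble::tibble(mz = c(10, 20), rt = c(1, 2))
  pairs2 <- enumerate_ordered_pairs(ions2)
  expect_equal(nrow(pairs2), 2)
  expect_equal(pairs2$mz_a, c(10, 20))
  expect_equal(pairs2$mz_b, c(20, 10))

  expect_error(enumerate_ordered_pairs(ions2[1, ]), "at least 2")
})

test_that("the streaming pair counter matches the closed form", {
  for (n in c(2, 3, 17, 500, 6724)) {
    expect_equal(count_ordered_pairs(n), 2 * choose(n, 2))
    expect_equal(count_ordered_pairs(n), n * (n - 1))
  }
  expect_equal(count_ordered_pairs(10, chunk_size = 3L), 90)
})

test_that("screen_pairs equals the naive double-loop oracle on small instances", {
  withr::local_seed(55)
  manifest_for <- function(tbl, n_pos) {
    s <- sample_ids(tbl)
    tibble::tibble(sample = s,
                   group = rep(c("PC", "control"),
                               c(n_pos, length(s) - n_pos)))
  }
  cmp <- comparison("PC", "control")
  for (i in 1:4) {
    tbl <- random_peak_table(sample(5:12, 1), 12, zero_frac = 0.1,
                             scale = "log10")
    man <- manifest_for(tbl, 6)
    ord <- order(tbl$mz, tbl$rt)
    logmat <- area_matrix(tbl)[ord, , drop = FALSE]
    for (method in c("log_of_ratio", "ratio_of_logs")) {
      got <- screen_pairs(tbl, man, cmp, method = method,
                          min_sensitivity = 0.7, min_specificity = 0.7)
      want <- oracle_screen_pairs(logmat, man$group == "PC", method,
                                  min_sens = 0.7, min_spec = 0.7)
      expect_equal(attr(got, "n_pairs_screened"), want$screened)
      expect_equal(attr(got, "n_pairs_skipped"), want$skipped)
      expect_equal(nrow(got), nrow(want$hits))
      if (nrow(got)) {
        key <- function(mz_a, rt_a, mz_b, rt_b) paste(mz_a, rt_a, mz_b, rt_b)
        got_sorted <- dplyr::arrange(tibble::as_tibble(got), mz_a, rt_a, mz_b, rt_b)
        want_tab <- tibble::tibble(
          mz_a = tbl$mz[ord][want$hits$a], rt_a = tbl$rt[ord][want$hits$a],
          mz_b = tbl$mz[ord][want$hits$b], rt_b = tbl$rt[ord][want$hits$b],
          orientation = want$hits$orientation,
          threshold = want$hits$threshold,
          sensitivity = want$hits$sensitivity,
          specificity = want$hits$specificity,
          optimum = want$hits$optimum
        )
        want_sorted <- dplyr::arrange(want_tab, mz_a, rt_a, mz_b, rt_b)
        expect_equal(
          got_sorted[, names(want_sorted)], want_sorted, tolerance = 1e-12,
          ignore_attr = TRUE
        )
      }
    }
  }
})

test_that("reversing a log-of-ratio pair flips orientation and negates the threshold", {
  withr::local_seed(66)
  tbl <- random_peak_table(5, 10, scale = "log10")
  man <- tibble::tibble(sample = sample_ids(tbl),
                        group = rep(c("PC", "control"), each = 5))
  all_pairs <- screen_pairs(tbl, man, comparison("PC", "control"),
                            method = "log_of_ratio",
                            min_sensitivity = 0, min_specificity = 0)
  expect_equal(nrow(all_pairs), 20)  # every ordered pair returned
  df <- tibble::as_tibble(all_pairs)
  rev_of <- dplyr::left_join(
    df,
    df,
    by = c("mz_a" = "mz_b", "rt_a" = "rt_b", "mz_b" = "mz_a", "rt_b" = "rt_a"),
    suffix = c("", ".rev")
  )
  # the best attainable sum is always shared between the two orderings
  expect_equal(rev_of$optimum, rev_of$optimum.rev)
  # when the reversal flips orientation (the generic case; the exception is a
  # tie between orientations, resolved toward positive_high on both sides)
  # the thresholds negate and the performance carries over exactly
  flipped <- rev_of$orientation != rev_of$orientation.rev
  expect_gt(mean(flipped), 0.5)
  expect_equal(rev_of$sensitivity[flipped], rev_of$sensitivity.rev[flipped])
  expect_equal(rev_of$specificity[flipped], rev_of$specificity.rev[flipped])
  expect_equal(rev_of$threshold[flipped], -rev_of$threshold.rev[flipped],
               tolerance = 1e-9)
})

test_that("returned pairs re-evaluate to their reported performance exactly", {
  cohort <- generate_cohort(synthetic_config(
    group_sizes = c(PC = 30, control = 30), n_null_ions = 30,
    planted_pairs = list(planted_pair("PC", 1.4, 1, 0.1)), seed = 77
  ))
  lt <- log_transform(cohort$table)
  man <- cohort$manifest
  hits <- screen_pairs(lt, man, comparison("PC", "control"),
                       method = "log_of_ratio",
                       min_sensitivity = 0.8, min_specificity = 0.8)
  expect_gt(nrow(hits), 0)
  grp <- man$group[match(sample_ids(lt), man$sample)]
  for (i in seq_len(min(nrow(hits), 10))) {
    sc <- pair_scores(lt, c(hits$mz_a[i], hits$rt_a[i]),
                      c(hits$mz_b[i], hits$rt_b[i]), "log_of_ratio")
    cs <- confusion_stats(sc$score, grp == "PC", hits$threshold[i],
                          hits$orientation[i])
    expect_identical(cs$sensitivity, hits$sensitivity[i])
    expect_identical(cs$specificity, hits$specificity[i])
  }
})

test_that("an impossible selection criterion returns an empty result", {
  withr::local_seed(88)
  tbl <- random_peak_table(4, 8, scale = "log10")
  man <- tibble::tibble(sample = sample_ids(tbl),
                        group = rep(c("PC", "control"), each = 4))
  out <- screen_pairs(tbl, man, comparison("PC", "control"),
                      min_sensitivity = 1.01, min_specificity = 1.01)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_pairs_screened"), 12)
})

test_that("the drop_sample policy salvages ratio pairs with zero denominators", {
  areas <- matrix(c(
    1000, 2000, 10, 20,
    100,  1,    50, 60
  ), nrow = 2, byrow = TRUE)
  lt <- make_log_table(areas)
  man <- tibble::tibble(sample = sample_ids(lt),
                        group = c("PC", "PC", "control", "control"))
  cmp <- comparison("PC", "control")
  skip <- screen_pairs(lt, man, cmp, method = "ratio_of_logs",
                       min_sensitivity = 0, min_specificity = 0)
  # ion 2 has a zero log area, so both ordered pairs with it as denominator
  # are skipped
  expect_equal(attr(skip, "n_pairs_skipped"), 1)
  drop <- screen_pairs(lt, man, cmp, method = "ratio_of_logs",
                       min_sensitivity = 0, min_specificity = 0,
                       zero_denominator = "drop_sample")
  expect_equal(attr(drop, "n_pairs_skipped"), 0)
  expect_equal(attr(drop, "n_pairs_screened"), 2)
})
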