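#' Configure a synthetic serum LMI cohort
#'
#' Builds the configuration for [generate_cohort()]. The generator emulates
#' the statistical structure the screening pipeline assumes: per-ion log10
#' peak areas are normal within group (so raw areas are log-normal, matching
#' the logarithmic analysis scale), null ions are identically distributed
#' across groups, planted single-ion markers carry a mean shift in the
#' positive groups, and planted pair markers share a per-sample latent scale
#' so that neither member ion separates alone while their difference score
#' does. Zero-area dropouts exercise the 0-to-1 log rule downstream.
#'
#' Default group sizes mirror the study cohort (PC 51, BTC 39, control 100,
#' CRC 100, OVC 30, plus high-risk groups PC_HRG 21 and BTC_HRG 25).
#'
#' @param group_sizes Named integer vector, samples per group.
#' @param n_null_ions Number of undifferentiated background ions.
#' @param planted_singles List of [planted_single()] marker descriptions.
#' @param planted_pairs List of [planted_pair()] marker descriptions.
#' @param dropout_rate Probability, applied independently per raw area, of
#'   replacing it with 0.
#' @param baseline_mean,baseline_sd Location and spread of null-ion log10
#'   areas (log10-area units).
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(group_sizes = c(PC = 51L, BTC = 39L, control = 100L,
                                             CRC = 100L, OVC = 30L,
                                             PC_HRG = 21L, BTC_HRG = 25L),
                             n_null_ions = 500L,
                             planted_singles = list(),
                             planted_pairs = list(),
                             dropout_rate = 0,
                             baseline_mean = 4,
                             baseline_sd = 0.5,
                             seed = 1L) {
  stopifnot(
    length(group_sizes) > 0, !is.null(names(group_sizes)), all(group_sizes >= 0),
    n_null_ions >= 0, dropout_rate >= 0, dropout_rate < 1, baseline_sd > 0
  )
  for (p in c(planted_singles, planted_pairs)) {
    missing <- setdiff(p$positive_groups, names(group_sizes))
    if (length(missing)) {
      rlang::abort(sprintf(
        "planted marker references unknown group(s): %s",
        paste(missing, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      group_sizes = group_sizes, n_null_ions = as.integer(n_null_ions),
      planted_singles = planted_singles, planted_pairs = planted_pairs,
      dropout_rate = dropout_rate, baseline_mean = baseline_mean,
      baseline_sd = baseline_sd, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Planted marker descriptions
#'
#' `planted_single()` describes an ion whose log10 area is shifted by `delta`
#' in the positive groups, with within-group standard deviation `sigma`.
#' `planted_pair()` describes two ions sharing a per-sample latent scale
#' `u ~ Normal(0, tau)`: the first ion's log10 area is
#' `baseline + u + delta * positive + noise(sigma)`, the second's
#' `baseline + u + noise(sigma)`. When `tau` is large relative to `sigma`,
#' each ion alone overlaps across classes but the difference score
#' (distributed `Normal(+/- delta, sqrt(2) * sigma)`) separates.
#'
#' @param positive_groups Group labels forming the positive class.
#' @param delta Mean shift (log10-area units).
#' @param sigma Residual within-group standard deviation (log10-area units).
#' @param tau Latent per-sample scale standard deviation (log10-area units).
#' @return A marker description list.
#' @export
planted_single <- function(positive_groups, delta, sigma) {
  stopifnot(sigma > 0)
  list(positive_groups = as.character(positive_groups),
       delta = delta, sigma = sigma)
}

#' @rdname planted_single
#' @export
planted_pair <- function(positive_groups, delta, tau, sigma) {
  stopifnot(sigma > 0, tau > 0)
  list(positive_groups = as.character(positive_groups),
       delta = delta, tau = tau, sigma = sigma)
}

#' Generate a synthetic cohort
#'
#' Draws a raw-scale peak table, matching manifest, and a ground-truth
#' registry of the planted markers, deterministically from `config$seed`.
#' Log10 areas are drawn per the marker model (see [synthetic_config()]),
#' exponentiated to raw areas, then independently zeroed with probability
#' `dropout_rate`. Synthetic `(mz, rt)` coordinates are arbitrary unique
#' labels; planted markers are placed at random row positions among the nulls.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `table` (raw [peak_table()]), `manifest`
#'   (tibble `sample`, `group`), and `truth` (tibble with one row per planted
#'   ion: `marker`, `role`, `mz`, `rt`, and the marker parameters).
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   group_sizes = c(PC = 10, control = 10), n_null_ions = 20,
#'   planted_singles = list(planted_single("PC", delta = 2, sigma = 0.2)),
#'   seed = 42
#' ))
#' cohort$truth
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_samp <- length(groups)
  if (n_samp == 0) rlang::abort("config yields zero samples")
  samples <- sprintf("%s_%03d", groups, stats::ave(seq_len(n_samp), groups,
                                                   FUN = seq_along))
  n_single <- length(config$planted_singles)
  n_pair <- length(config$planted_pairs)
  n_ions <- config$n_null_ions + n_single + 2L * n_pair
  if (n_ions == 0) rlang::abort("config yields zero ions")

  withr::with_seed(config$seed, {
    # log10-area matrix, generated marker-block by marker-block in fixed order
    L <- matrix(0, nrow = n_ions, ncol = n_samp)
    row_order <- sample.int(n_ions)          # planted rows scattered among nulls
    next_row <- 0L
    take_row <- function() {
      next_row <<- next_row + 1L
      row_order[next_row]
    }

    for (i in seq_len(config$n_null_ions)) {
      L[take_row(), ] <- stats::rnorm(n_samp, config$baseline_mean,
                                      config$baseline_sd)
    }

    truth <- list()
    for (k in seq_len(n_single)) {
      p <- config$planted_singles[[k]]
      r <- take_row()
      shift <- p$delta * (groups %in% p$positive_groups)
      L[r, ] <- config$baseline_mean + shift + stats::rnorm(n_samp, 0, p$sigma)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        marker = sprintf("single_%d", k), role = "single", row = r,
        delta = p$delta, sigma = p$sigma, tau = NA_real_,
        positive_groups = paste(p$positive_groups, collapse = "+")
      )
    }
    for (k in seq_len(n_pair)) {
      p <- config$planted_pairs[[k]]
      r1 <- take_row(); r2 <- take_row()
      u <- stats::rnorm(n_samp, 0, p$tau)
      shift <- p$delta * (groups %in% p$positive_groups)
      L[r1, ] <- config$baseline_mean + u + shift + stats::rnorm(n_samp, 0, p$sigma)
      L[r2, ] <- config$baseline_mean + u + stats::rnorm(n_samp, 0, p$sigma)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        marker = sprintf("pair_%d", k), role = c("pair_shifted", "pair_partner"),
        row = c(r1, r2), delta = p$delta, sigma = p$sigma, tau = p$tau,
        positive_groups = paste(p$positive_groups, collapse = "+")
      )
    }

    areas <- 10^L
    if (config$dropout_rate > 0) {
      drop <- matrix(
        stats::runif(length(areas)) < config$dropout_rate,
        nrow = n_ions
      )
      areas[drop] <- 0
    }
  })

  # arbitrary unique ion coordinates
  mz <- round(100 + (seq_len(n_ions) - 1L) * 0.1731, 4)
  rt <- round(1 + ((seq_len(n_ions) - 1L) %% 97) * 0.19, 2)

  tbl <- tibble::as_tibble(as.data.frame(areas))
  names(tbl) <- samples
  table <- peak_table(
    dplyr::bind_cols(tibble::tibble(mz = mz, rt = rt), tbl),
    scale = "raw",
    provenance = c(generator = "lmiscreen synthetic cohort",
                   seed = as.character(config$seed))
  )
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(marker = character(), role = character(), row = integer(),
                   delta = double(), sigma = double(), tau = double(),
                   positive_groups = character())
  truth$mz <- mz[truth$row]
  truth$rt <- rt[truth$row]
  truth$row <- NULL

  list(
    table = table,
    manifest = tibble::tibble(sample = samples, group = groups),
    truth = dplyr::relocate(truth, "marker", "role", "mz", "rt")
  )
}
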