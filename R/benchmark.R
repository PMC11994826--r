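#' Mean and standard deviation over repeated runs
#'
#' Aggregates a long metrics table over its `run` column, reporting the
#' arithmetic mean and the sample (n-1) standard deviation of each metric per
#' `(image, channel, objective, K, algorithm)` cell.
#'
#' @param results A tibble as produced by [benchmark_optimizers()], with
#'   grouping columns `image`, `channel`, `objective`, `K`, `algorithm`, a
#'   `run` column and numeric metric columns.
#' @param metrics Character vector of metric columns to aggregate.
#' @return A tibble with `<metric>_mean` and `<metric>_sd` columns and an
#'   `n_runs` count per cell.
#' @export
aggregate_runs <- function(results,
                           metrics = intersect(c("fitness", "rmse", "psnr", "ssim"),
                                               names(results))) {
  stopifnot(length(metrics) > 0)
  if (nrow(results) == 0L) stop("no rows to aggregate", call. = FALSE)
  keys <- intersect(c("image", "channel", "objective", "K", "algorithm"),
                    names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    )
}

#' Friedman ranks for one case
#'
#' Ranks the algorithms competing on one case (one image x K cell): rank 1 is
#' the best score, and tied scores receive the average of the tied rank
#' positions, the standard Friedman treatment.
#'
#' @param scores Numeric vector, one score per algorithm.
#' @param higher_is_better If `TRUE` (quality metrics), larger scores rank
#'   better; set `FALSE` for error-type scores.
#' @return Numeric vector of ranks summing to `A(A+1)/2`.
#' @examples
#' friedman_rank(c(15.34, 14.53, 13.62, 13.62, 13.47, 13.35))
#' @export
friedman_rank <- function(scores, higher_is_better = TRUE) {
  stopifnot(length(scores) >= 2)
  if (higher_is_better) rank(-scores, ties.method = "average")
  else rank(scores, ties.method = "average")
}

#' Friedman rank summary and test statistic
#'
#' Combines per-case ranks into rank sums, mean ranks, final ordinal ranks
#' (tied mean ranks share the better ordinal) and the Friedman chi-squared
#' statistic `12n / (A(A+1)) * sum_j (Rbar_j - (A+1)/2)^2` with its p-value
#' (`A - 1` degrees of freedom). The statistic is invariant under any
#' monotone transformation of the underlying scores because it only sees
#' ranks.
#'
#' @param ranks A matrix or data frame of ranks, one row per case and one
#'   column per algorithm (e.g. rows of [friedman_rank()] outputs).
#' @return A list with `table` (tibble: `algorithm`, `rank_sum`, `mean_rank`,
#'   `final_rank`), `statistic`, `p_value`, `n_cases`, `n_algorithms`.
#' @export
friedman_summary <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (is.null(colnames(ranks))) {
    colnames(ranks) <- paste0("algorithm_", seq_len(ncol(ranks)))
  }
  n <- nrow(ranks)
  A <- ncol(ranks)
  stopifnot(n >= 1, A >= 2)
  rank_sum <- colSums(ranks)
  mean_rank <- rank_sum / n
  statistic <- 12 * n / (A * (A + 1)) * sum((mean_rank - (A + 1) / 2)^2)
  list(
    table = tibble::tibble(
      algorithm = colnames(ranks),
      rank_sum = unname(rank_sum),
      mean_rank = unname(mean_rank),
      final_rank = rank(mean_rank, ties.method = "min")
    ),
    statistic = statistic,
    p_value = pchisq(statistic, df = A - 1, lower.tail = FALSE),
    n_cases = n,
    n_algorithms = A
  )
}

#' The package's optimizer, as a pluggable benchmark entry
#'
#' Benchmark optimizers are functions `(h, k, objective, config, seed)`
#' returning a list with `thresholds` and `fitness`; any optimizer honoring
#' that contract can be raced in [benchmark_optimizers()].
#'
#' @param h A [channel_histogram()].
#' @param k Threshold count.
#' @param objective `"otsu"` or `"kapur"`.
#' @param config An [rsa_config()].
#' @param seed Integer seed.
#' @return List with `thresholds` and `fitness`.
#' @export
optimizer_rsa_gbest <- function(h, k, objective, config = rsa_config(), seed) {
  fit <- rsa_optimize(h, k, objective, config = config, seed = seed)
  list(thresholds = fit$thresholds, fitness = fit$fitness)
}

#' Seeded random-search baseline optimizer
#'
#' Draws `population * iterations` uniform threshold vectors and keeps the
#' best -- a deliberately naive baseline so the benchmark harness always has a
#' second contender to rank against.
#'
#' @inheritParams optimizer_rsa_gbest
#' @return List with `thresholds` and `fitness`.
#' @export
optimizer_random_search <- function(h, k, objective, config = rsa_config(), seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- length(h$probabilities)
  fobj <- objective_fun(h, objective)
  best_fit <- -Inf
  best_t <- NULL
  for (i in seq_len(config$population * config$iterations)) {
    t <- decode_thresholds(runif(k, 1, L - 1), L = L)
    f <- fobj(t)
    if (f > best_fit) {
      best_fit <- f
      best_t <- t
    }
  }
  list(thresholds = best_t, fitness = best_fit)
}

#' Race optimizers over images, threshold counts and repeated runs
#'
#' The full benchmark protocol: every registered optimizer is run on every
#' image channel, for every threshold count `K`, `runs` times with distinct
#' deterministic seeds derived from `base_seed`. Each run records the decoded
#' thresholds, the achieved objective value and the reconstruction quality
#' metrics.
#'
#' @param images Named list of [image_buffer()]s (or file paths).
#' @param optimizers Named list of optimizer functions (see
#'   [optimizer_rsa_gbest()] for the contract).
#' @param objective `"otsu"` or `"kapur"`.
#' @param K Integer vector of threshold counts (default 2..6).
#' @param config An [rsa_config()]; its `runs` field sets the repetition
#'   count unless `runs` is given.
#' @param runs Number of repeated runs per cell.
#' @param base_seed Integer; run seeds are `base_seed + 0, 1, 2, ...` in a
#'   fixed traversal order, so the whole benchmark is reproducible.
#' @return A tibble with columns `image`, `channel`, `objective`, `K`,
#'   `algorithm`, `run`, `seed`, `thresholds`, `fitness`, `rmse`, `psnr`,
#'   `ssim`.
#' @export
benchmark_optimizers <- function(images, optimizers, objective = "otsu",
                                 K = 2:6, config = rsa_config(),
                                 runs = config$runs, base_seed = 1L) {
  stopifnot(length(images) >= 1, length(optimizers) >= 1,
            !is.null(names(optimizers)))
  if (is.null(names(images))) names(images) <- paste0("image_", seq_along(images))
  counter <- 0L
  rows <- list()
  for (img_name in names(images)) {
    img <- images[[img_name]]
    if (is.character(img)) img <- load_image(img)
    chans <- split_channels(img)
    for (ch_name in names(chans)) {
      h <- compute_histogram(chans[[ch_name]], channel_id = ch_name)
      for (k in K) {
        for (alg in names(optimizers)) {
          for (r in seq_len(runs)) {
            seed <- as.integer(base_seed) + counter
            counter <- counter + 1L
            res <- optimizers[[alg]](h, k, objective, config, seed)
            seg <- apply_thresholds(chans[[ch_name]], res$thresholds)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              image = img_name, channel = ch_name, objective = objective,
              K = as.integer(k), algorithm = alg, run = r, seed = seed,
              thresholds = paste(res$thresholds, collapse = " "),
              fitness = res$fitness,
              rmse = rmse(chans[[ch_name]], seg$reconstruction),
              psnr = psnr(chans[[ch_name]], seg$reconstruction),
              ssim = ssim(chans[[ch_name]], seg$reconstruction)
            )
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Friedman ranking of a benchmark table
#'
#' Reproduces the rank-table layout of the benchmark protocol: each case is
#' one `image x K` cell (channels averaged first for color images), algorithms
#' are ranked within each case on the run-mean of the chosen metric, and the
#' per-case ranks are folded into rank sums, mean ranks, final ranks and the
#' Friedman statistic.
#'
#' @param results Tibble from [benchmark_optimizers()].
#' @param metric Which metric to rank on (`"psnr"`, `"ssim"`, `"fitness"` or
#'   `"rmse"`).
#' @param higher_is_better `TRUE` for quality metrics; automatically flipped
#'   for `"rmse"`.
#' @return A list as from [friedman_summary()], plus `case_ranks`, a tibble of
#'   the per-case ranks.
#' @export
rank_benchmark <- function(results, metric = "psnr",
                           higher_is_better = metric != "rmse") {
  stopifnot(metric %in% names(results))
  means <- results |>
    dplyr::group_by(.data$image, .data$K, .data$algorithm) |>
    dplyr::summarise(score = mean(.data[[metric]]), .groups = "drop")
  wide <- means |>
    tidyr::pivot_wider(names_from = "algorithm", values_from = "score") |>
    dplyr::arrange(.data$image, .data$K)
  algs <- setdiff(names(wide), c("image", "K"))
  if (anyNA(wide[algs])) {
    stop("every case must score the same algorithm set", call. = FALSE)
  }
  rank_mat <- t(apply(as.matrix(wide[algs]), 1L, friedman_rank,
                      higher_is_better = higher_is_better))
  colnames(rank_mat) <- algs
  out <- friedman_summary(rank_mat)
  out$case_ranks <- dplyr::bind_cols(wide[c("image", "K")],
                                     tibble::as_tibble(rank_mat))
  out$metric <- metric
  out
}
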