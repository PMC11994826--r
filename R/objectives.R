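#' Construct a validated threshold vector
#'
#' `m - 1` strictly increasing integer thresholds in `[1, L-1]` partition the
#' `L` gray levels into `m` classes by the half-open rule: level `p` belongs to
#' class `i` iff `t_i <= p < t_{i+1}`, with `t_0 = 0` and `t_m = L`.
#'
#' @param values Strictly increasing integers in `[1, L-1]`.
#' @param L Number of gray levels (256 for 8-bit).
#' @return An integer vector of class `threshold_vector`.
#' @export
threshold_vector <- function(values, L = 256L) {
  v <- as.integer(values)
  if (length(v) < 1L) stop("need at least one threshold", call. = FALSE)
  if (anyNA(v)) stop("thresholds must not be NA", call. = FALSE)
  if (any(v < 1L) || any(v > L - 1L)) {
    stop("thresholds must lie in [1, ", L - 1L, "]", call. = FALSE)
  }
  if (any(diff(v) <= 0L)) stop("thresholds must be strictly increasing", call. = FALSE)
  structure(v, class = "threshold_vector", L = as.integer(L))
}

#' Class index for every gray level
#'
#' @param t A [threshold_vector()] (or plain increasing integer vector).
#' @param L Number of gray levels.
#' @return Integer vector of length `L`: the 0-based class of each level
#'   `0..L-1`.
#' @examples
#' table(partition_levels(threshold_vector(128L)))
#' @export
partition_levels <- function(t, L = 256L) {
  findInterval(0:(L - 1L), as.integer(t))
}

#' Per-class decomposition of a histogram under a threshold vector
#'
#' Computes, for each of the `m` classes, the probability mass
#' `omega_i = sum p_j`, the class mean `mu_i = sum j p_j / omega_i`, the Shannon
#' entropy of the normalized within-class distribution
#' `H_i = -sum (p_j/omega_i) log(p_j/omega_i)`, the between-class variance
#' contribution `sigma_i = omega_i (mu_i - mu_T)^2` and the within-class
#' variance `omega_i * Var_i`. Empty classes contribute zero everywhere.
#'
#' @param h A [channel_histogram()].
#' @param t A [threshold_vector()].
#' @return A tibble with one row per class: `class`, `from`, `to` (inclusive
#'   level range), `omega`, `mu`, `sigma_b`, `entropy`, `within`; the global
#'   mean is attached as attribute `mu_T`.
#' @export
class_decomposition <- function(h, t) {
  stopifnot(inherits(h, "channel_histogram"))
  p <- h$probabilities
  L <- length(p)
  lev <- 0:(L - 1L)
  cls <- partition_levels(t, L)
  mu_T <- sum(lev * p)
  m <- length(t) + 1L
  bounds <- c(0L, as.integer(t), L)
  rows <- lapply(seq_len(m), function(i) {
    sel <- cls == (i - 1L)
    pj <- p[sel]
    lj <- lev[sel]
    omega <- sum(pj)
    if (omega > 0) {
      mu <- sum(lj * pj) / omega
      q <- pj[pj > 0] / omega
      entropy <- -sum(q * log(q))
      sigma_b <- omega * (mu - mu_T)^2
      within <- sum(pj * (lj - mu)^2)
    } else {
      mu <- NA_real_; entropy <- 0; sigma_b <- 0; within <- 0
    }
    tibble::tibble(
      class = i - 1L, from = bounds[i], to = bounds[i + 1L] - 1L,
      omega = omega, mu = mu, sigma_b = sigma_b,
      entropy = entropy, within = within
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mu_T") <- mu_T
  out
}

#' Otsu between-class variance of a threshold vector
#'
#' The objective maximized by Otsu multilevel thresholding:
#' `sigma_B = sum_i omega_i (mu_i - mu_T)^2`. Empty classes contribute 0.
#'
#' @param h A [channel_histogram()].
#' @param t A [threshold_vector()].
#' @return A non-negative scalar, at most the total histogram variance.
#' @export
otsu_score <- function(h, t) {
  sum(class_decomposition(h, t)$sigma_b)
}

#' Kapur entropy of a threshold vector
#'
#' The sum of per-class Shannon entropies (natural log) of the normalized
#' within-class gray-level distributions. Zero-probability levels and empty
#' classes contribute 0.
#'
#' @inheritParams otsu_score
#' @return A non-negative scalar.
#' @export
kapur_score <- function(h, t) {
  sum(class_decomposition(h, t)$entropy)
}

#' Score function for a named objective
#'
#' @param h A [channel_histogram()].
#' @param objective `"otsu"` or `"kapur"`; both are maximized.
#' @return A function mapping an integer threshold vector to its score. The
#'   returned closure uses precomputed prefix sums, so it is cheap enough to
#'   sit inside an optimizer loop.
#' @export
objective_fun <- function(h, objective = c("otsu", "kapur")) {
  objective <- match.arg(objective)
  seg <- segment_scores(h, objective)
  L <- length(h$probabilities)
  function(t) {
    b <- c(0L, as.integer(t), L)
    sum(seg[cbind(b[-length(b)] + 1L, b[-1L] + 1L)])
  }
}

# Precompute the score contribution of every contiguous level segment [a, b),
# 0 <= a < b <= L, as an (L+1) x (L+1) matrix indexed [a+1, b+1]. Both
# objectives are additive over classes, so any threshold vector's score is a
# sum of k+1 segment entries; this is what makes exhaustive enumeration cheap.
segment_scores <- function(h, objective = c("otsu", "kapur")) {
  objective <- match.arg(objective)
  p <- h$probabilities
  L <- length(p)
  lev <- 0:(L - 1L)
  cp <- c(0, cumsum(p))              # cp[b+1] = sum p[0..b-1]
  cjp <- c(0, cumsum(lev * p))
  plogp <- ifelse(p > 0, p * log(p), 0)
  cplp <- c(0, cumsum(plogp))
  mu_T <- cjp[L + 1L]
  S <- matrix(0, L + 1L, L + 1L)
  for (a in 0:(L - 1L)) {
    b <- (a + 1L):L
    omega <- cp[b + 1L] - cp[a + 1L]
    pos <- omega > 0
    val <- numeric(length(b))
    if (objective == "otsu") {
      mu <- (cjp[b + 1L] - cjp[a + 1L])[pos] / omega[pos]
      val[pos] <- omega[pos] * (mu - mu_T)^2
    } else {
      sp <- (cplp[b + 1L] - cplp[a + 1L])[pos]
      val[pos] <- log(omega[pos]) - sp / omega[pos]
    }
    S[a + 1L, b + 1L] <- val
  }
  S
}

#' Exhaustive search for the optimal threshold vector
#'
#' Enumerates every strictly increasing `k`-tuple of thresholds in `[1, L-1]`
#' and returns the tuple maximizing the chosen objective. Ties are broken by
#' the lexicographically smallest tuple. This is the verification oracle the
#' stochastic optimizer is checked against; the enumeration budget caps the
#' tuple count at about 3 million (`k <= 3` for 256 levels, larger `k` for
#' reduced-level histograms).
#'
#' @param h A [channel_histogram()].
#' @param k Number of thresholds.
#' @param objective `"otsu"` or `"kapur"`.
#' @return A list with `thresholds` (a [threshold_vector()]), `score`, and
#'   `n_evaluated` (number of tuples enumerated).
#' @export
exhaustive_search <- function(h, k, objective = c("otsu", "kapur")) {
  objective <- match.arg(objective)
  stopifnot(k >= 1)
  L <- length(h$probabilities)
  n_tuples <- choose(L - 1L, k)
  if (n_tuples > 3.5e6) {
    stop("enumeration budget exceeded: choose(", L - 1L, ", ", k, ") = ",
         format(n_tuples, big.mark = ","), " tuples", call. = FALSE)
  }
  S <- segment_scores(h, objective)
  tail_score <- S[2:L, L + 1L]       # tail_score[t] = score of [t, L), t = 1..L-1
  best_score <- -Inf
  best_t <- NULL
  # depth-first in lexicographic order with strict improvement keeps the
  # lexicographically smallest maximizer
  recurse <- function(prev, depth, acc, prefix) {
    if (depth == k) {
      cand <- (prev + 1L):(L - 1L)
      totals <- acc + S[prev + 1L, cand + 1L] + tail_score[cand]
      i <- which.max(totals)
      if (totals[i] > best_score) {
        best_score <<- totals[i]
        best_t <<- c(prefix, cand[i])
      }
    } else {
      for (t in (prev + 1L):(L - 1L - (k - depth))) {
        recurse(t, depth + 1L, acc + S[prev + 1L, t + 1L], c(prefix, t))
      }
    }
  }
  recurse(0L, 1L, 0, integer(0))
  list(
    thresholds = threshold_vector(best_t, L = L),
    score = best_score,
    n_evaluated = n_tuples
  )
}
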