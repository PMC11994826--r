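# Independent definition-level oracles used to verify the package's
# implementations. Deliberately written as naive per-element loops over the
# textbook definitions, sharing no code with the package internals.

# per-pixel tally of a single-channel image
oracle_tally <- function(pixels) {
  counts <- numeric(256)
  for (v in as.vector(pixels)) counts[v + 1] <- counts[v + 1] + 1
  counts
}

# class index of each level under thresholds t (0-based classes)
oracle_classes <- function(t, L) {
  cls <- integer(L)
  for (p in 0:(L - 1)) {
    c <- 0
    for (ti in t) if (p >= ti) c <- c + 1
    cls[p + 1] <- c
  }
  cls
}

# Otsu between-class variance from the omega/mu definitions
oracle_otsu <- function(p, t) {
  L <- length(p)
  cls <- oracle_classes(t, L)
  levs <- 0:(L - 1)
  mu_T <- sum(levs * p)
  s <- 0
  for (c in 0:length(t)) {
    sel <- cls == c
    omega <- sum(p[sel])
    if (omega > 0) {
      mu <- sum(levs[sel] * p[sel]) / omega
      s <- s + omega * (mu - mu_T)^2
    }
  }
  s
}

# Kapur entropy from the per-class H definition (natural log)
oracle_kapur <- function(p, t) {
  L <- length(p)
  cls <- oracle_classes(t, L)
  s <- 0
  for (c in 0:length(t)) {
    sel <- cls == c
    omega <- sum(p[sel])
    if (omega > 0) {
      for (pj in p[sel]) {
        if (pj > 0) s <- s - (pj / omega) * log(pj / omega)
      }
    }
  }
  s
}

# brute-force arg-max over all k-tuples via combn (small L only)
oracle_best <- function(p, k, score_fun) {
  L <- length(p)
  tuples <- utils::combn(1:(L - 1), k)
  scores <- apply(tuples, 2, function(t) score_fun(p, t))
  i <- which.max(scores)
  list(thresholds = tuples[, i], score = scores[i])
}

# random histogram on the first `levels` bins of a 256-bin support
random_histogram <- function(levels = 256, total = 5000) {
  counts <- numeric(256)
  counts[seq_len(levels)] <- stats::rmultinom(1, total, runif(levels))[, 1]
  if (sum(counts) == 0) counts[1] <- 1
  channel_histogram(counts)
}

random_increasing_thresholds <- function(k, L = 256) {
  sort(sample(1:(L - 1), k))
}
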