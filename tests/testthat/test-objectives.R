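test_that("partition_levels implements the half-open class rule", {
  cls <- partition_levels(threshold_vector(128L), 256)
  expect_equal(cls[1:128], rep(0L, 128))     # levels 0..127
  expect_equal(cls[129:256], rep(1L, 128))   # levels 128..255

  sizes <- table(partition_levels(threshold_vector(c(1L, 255L)), 256))
  expect_equal(as.vector(sizes), c(1, 254, 1))

  four <- table(partition_levels(threshold_vector(c(64L, 128L, 192L)), 256))
  expect_equal(as.vector(four), rep(64, 4))
})

test_that("threshold_vector enforces its invariants", {
  expect_error(threshold_vector(c(10, 10)), "strictly increasing")
  expect_error(threshold_vector(c(50, 20)), "strictly increasing")
  expect_error(threshold_vector(0), "\\[1, 255\\]")
  expect_error(threshold_vector(256), "\\[1, 255\\]")
})

test_that("otsu_score matches closed forms and the definition oracle", {
  # all mass at one level: zero variance whatever the threshold
  h0 <- delta_histogram(100, 1, total = 50)
  expect_equal(otsu_score(h0, threshold_vector(128L)), 0)

  # two equal deltas at 0 and 255: omega1*omega2*(mu1-mu2)^2 = 0.25 * 255^2
  h2 <- delta_histogram(c(0, 255), c(0.5, 0.5), total = 100)
  expect_equal(otsu_score(h2, threshold_vector(128L)), 127.5^2)

  # seeded random 16-level histogram vs independent recomputation
  set.seed(101)
  for (i in 1:10) {
    h <- random_histogram(levels = 16)
    t <- c(5L, 11L)
    expect_equal(otsu_score(h, threshold_vector(t)),
                 oracle_otsu(h$probabilities, t), tolerance = 1e-12)
  }
})

test_that("kapur_score matches closed forms and the definition oracle", {
  hu <- channel_histogram(rep(1, 256))
  expect_equal(kapur_score(hu, threshold_vector(128L)), 2 * log(128),
               tolerance = 1e-12)

  h0 <- delta_histogram(42, 1, total = 10)
  expect_equal(kapur_score(h0, threshold_vector(100L)), 0)

  set.seed(202)
  for (i in 1:10) {
    h <- random_histogram(levels = 256)
    t <- c(64L, 192L)
    expect_equal(kapur_score(h, threshold_vector(t)),
                 oracle_kapur(h$probabilities, t), tolerance = 1e-12)
  }
})

test_that("kapur_score is invariant under histogram count scaling", {
  set.seed(5)
  counts <- rmultinom(1, 3000, runif(256))[, 1] + 0
  t <- threshold_vector(c(80L, 160L))
  expect_equal(kapur_score(channel_histogram(counts), t),
               kapur_score(channel_histogram(counts * 7), t),
               tolerance = 1e-12)
})

test_that("between-class variance respects the law of total variance", {
  set.seed(9)
  px <- matrix(sample(0:255, 50 * 40, replace = TRUE, prob = runif(256)), 50, 40)
  h <- compute_histogram(image_buffer(px))
  t <- threshold_vector(c(60L, 130L, 200L))
  dec <- class_decomposition(h, t)
  total_var <- mean((as.vector(px) - mean(px))^2)  # direct pixel-level
  expect_equal(sum(dec$sigma_b) + sum(dec$within), total_var, tolerance = 1e-6)
  expect_lte(otsu_score(h, t), total_var + 1e-9)
  # class masses sum to one, masses weight means to the global mean
  expect_equal(sum(dec$omega), 1, tolerance = 1e-12)
  expect_equal(sum(dec$omega * dec$mu), attr(dec, "mu_T"), tolerance = 1e-9)
})

test_that("exhaustive_search finds analytic optima and honors the tie-break", {
  hu <- channel_histogram(rep(4, 256))
  res <- exhaustive_search(hu, 1, "kapur")
  expect_equal(as.integer(res$thresholds), 128L)
  expect_equal(res$score, 2 * log(128), tolerance = 1e-9)

  # every threshold ties on the two-delta histogram: lexicographic winner is 1
  h2 <- delta_histogram(c(0, 255), c(0.5, 0.5), total = 100)
  res2 <- exhaustive_search(h2, 1, "otsu")
  expect_equal(as.integer(res2$thresholds), 1L)
  expect_equal(res2$score, 16256.25)
})

test_that("exhaustive_search agrees with full combn enumeration", {
  # fixed 4-level histogram: frozen values from the definition-level oracle
  h4 <- channel_histogram(c(0.1, 0.4, 0.4, 0.1) * 100)
  ot <- exhaustive_search(h4, 2, "otsu")
  expect_equal(as.integer(ot$thresholds), c(1L, 2L))  # ties (1,2)/(2,3); lex wins
  expect_equal(ot$score, 0.57, tolerance = 1e-12)
  ka <- exhaustive_search(h4, 2, "kapur")
  expect_equal(as.integer(ka$thresholds), c(1L, 3L))
  expect_equal(ka$score, log(2), tolerance = 1e-12)

  # random small histograms vs brute-force combn using the oracles
  set.seed(303)
  for (i in 1:5) {
    p <- runif(12); p <- p / sum(p)
    h <- channel_histogram(p * 1e4)
    for (k in 1:3) {
      mine_o <- exhaustive_search(h, k, "otsu")
      ref_o <- oracle_best(h$probabilities, k, oracle_otsu)
      expect_equal(mine_o$score, ref_o$score, tolerance = 1e-10)
      mine_k <- exhaustive_search(h, k, "kapur")
      ref_k <- oracle_best(h$probabilities, k, oracle_kapur)
      expect_equal(mine_k$score, ref_k$score, tolerance = 1e-10)
    }
  }
})

test_that("exhaustive optima are non-decreasing in k", {
  set.seed(404)
  h <- channel_histogram(rmultinom(1, 5000, runif(64))[, 1])
  for (obj in c("otsu", "kapur")) {
    scores <- vapply(1:4, function(k) exhaustive_search(h, k, obj)$score,
                     numeric(1))
    expect_true(all(diff(scores) >= -1e-12), info = obj)
  }
})

test_that("exhaustive_search refuses over-budget enumerations", {
  h <- channel_histogram(rep(1, 256))
  expect_error(exhaustive_search(h, 4, "otsu"), "budget")
})
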