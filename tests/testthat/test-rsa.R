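test_that("population initialization respects bounds, shape and seed", {
  cfg <- rsa_config(population = 25L)
  b <- search_bounds(1, 255, n = 5L)
  set.seed(1); pop1 <- init_population(cfg, b)
  set.seed(1); pop2 <- init_population(cfg, b)
  expect_identical(pop1, pop2)
  expect_equal(dim(pop1$X), c(25L, 5L))
  expect_true(all(pop1$X >= 1 & pop1$X <= 255))
  expect_true(all(pop1$V == 0))
  expect_identical(pop1$pbest, pop1$X)
})

test_that("evolutionary sense shrinks from 2 toward 0 over the run", {
  expect_equal(evolutionary_sense(100, 100, r3 = 0.7), 0)
  expect_equal(evolutionary_sense(0, 100, r3 = 1), 2)
  expect_equal(evolutionary_sense(50, 100, r3 = -0.5), -0.5)
  expect_lte(abs(evolutionary_sense(13, 100, r3 = runif(1, -1, 1))), 2)
})

test_that("reduction function and percentage difference match their forms", {
  expect_equal(reduction_function(3, 3, 1e-10), 0)
  expect_equal(reduction_function(1, 0, 1e-10), 1, tolerance = 1e-9)
  expect_equal(reduction_function(2, 5, 0.1), -3 / 2.1)

  b <- search_bounds(0, 10, n = 2L)
  expect_equal(percentage_difference(3, 3, best_j = 7, b), 0.1)
  expect_equal(percentage_difference(5, 3, best_j = 1, b, alpha = 0.1, epsilon = 0),
               0.3)
  # sign of the deviation term flips with (x - mean) when best_j > 0
  lo <- percentage_difference(2, 3, best_j = 1, b)
  hi <- percentage_difference(4, 3, best_j = 1, b)
  expect_lt(lo, 0.1); expect_gt(hi, 0.1)

  expect_equal(mean_position(c(3, 3, 3)), 3)
  expect_equal(mean_position(c(0, 10)), 5)
  set.seed(3)
  v <- runif(17)
  expect_equal(mean_position(v), sum(v) / 17)
})

test_that("phase schedule assigns the four strategies to iteration quarters", {
  expect_equal(rsa_phase(10, 100), "high_walk")
  expect_equal(rsa_phase(25, 100), "high_walk")
  expect_equal(rsa_phase(30, 100), "belly_walk")
  expect_equal(rsa_phase(50, 100), "belly_walk")
  expect_equal(rsa_phase(60, 100), "hunt_coordination")
  expect_equal(rsa_phase(75, 100), "hunt_coordination")
  expect_equal(rsa_phase(76, 100), "hunt_cooperation")
  expect_equal(rsa_phase(100, 100), "hunt_cooperation")
})

test_that("phase updates stay inside the search bounds", {
  cfg <- rsa_config(population = 10L, iterations = 20L)
  b <- search_bounds(1, 255, n = 4L)
  set.seed(8)
  pop <- init_population(cfg, b)
  best <- pop$X[1, ]
  for (t in c(2, 7, 12, 18)) {   # one iteration per phase
    es <- evolutionary_sense(t, 20, runif(1, -1, 1))
    for (i in 1:10) {
      x_new <- phase_update(pop$X[i, ], best, pop$X, t, 20, es, cfg, b)
      expect_true(all(x_new >= 1 & x_new <= 255))
      expect_length(x_new, 4)
    }
  }
})

test_that("gbest update has the PSO fixed point and stays bounded", {
  cfg <- rsa_config()
  b <- search_bounds(1, 255, n = 3L)
  x <- c(10, 100, 200)
  res <- gbest_update(x, rep(0, 3), x, x, w = 0.5, cfg, b)
  expect_equal(res$velocity, rep(0, 3))
  expect_equal(res$position, x)

  set.seed(21)
  res2 <- gbest_update(c(250, 250, 250), c(100, 100, 100),
                       c(255, 255, 255), c(255, 255, 255), w = 0.9, cfg, b)
  expect_true(all(res2$position >= 1 & res2$position <= 255))
})

test_that("decode_thresholds clamps, rounds, sorts and deduplicates", {
  expect_equal(as.integer(decode_thresholds(c(200.4, 63.7))), c(64L, 200L))
  expect_equal(as.integer(decode_thresholds(c(100.2, 99.8))), c(100L, 101L))
  expect_equal(as.integer(decode_thresholds(c(-5, 300))), c(1L, 255L))
  # duplicates at the top wrap downward
  expect_equal(as.integer(decode_thresholds(c(255, 255, 255))),
               c(253L, 254L, 255L))
  expect_error(decode_thresholds(runif(255, 1, 255)), "distinct")
  # decoded vectors always satisfy the threshold invariants
  set.seed(31)
  for (i in 1:50) {
    t <- decode_thresholds(runif(5, -20, 280))
    expect_true(all(diff(as.integer(t)) > 0))
    expect_true(all(t >= 1 & t <= 255))
  }
})

test_that("a constant objective yields a flat trace at its value", {
  h <- delta_histogram(c(60, 200), c(0.5, 0.5), total = 1000)
  fit <- rsa_optimize(h, 2, objective = function(t) 7,
                      config = rsa_config(population = 6L, iterations = 12L),
                      seed = 5)
  expect_equal(fit$fitness, 7)
  expect_true(all(fit$trace$best_fitness == 7))
  expect_s3_class(fit$thresholds, "threshold_vector")
})

test_that("optimization is deterministic under a fixed seed", {
  h <- delta_histogram(c(60, 200), c(0.5, 0.5), total = 1000)
  cfg <- rsa_config(population = 10L, iterations = 24L)
  f1 <- rsa_optimize(h, 2, "otsu", cfg, seed = 99)
  f2 <- rsa_optimize(h, 2, "otsu", cfg, seed = 99)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$thresholds, f2$thresholds)
  expect_identical(f1$gbest_position, f2$gbest_position)
  f3 <- rsa_optimize(h, 2, "otsu", cfg, seed = 100)
  expect_false(identical(f3$gbest_position, f1$gbest_position))
})

test_that("best-so-far fitness is monotone and the trace labels phases", {
  h <- delta_histogram(c(30, 120, 220), c(0.3, 0.4, 0.3), total = 2000)
  cfg <- rsa_config(population = 8L, iterations = 20L)
  for (obj in c("otsu", "kapur")) {
    fit <- rsa_optimize(h, 2, obj, cfg, seed = 17)
    expect_true(all(diff(fit$trace$best_fitness) >= 0), info = obj)
    expect_equal(unique(fit$trace$phase),
                 c("high_walk", "belly_walk", "hunt_coordination",
                   "hunt_cooperation"))
  }
})

test_that("the optimizer recovers the exhaustive optimum on a two-delta histogram", {
  h <- delta_histogram(c(60, 200), c(0.5, 0.5), total = 1000)
  target <- exhaustive_search(h, 1, "otsu")$score
  cfg <- rsa_config(population = 15L, iterations = 40L)
  hits <- sum(vapply(1:30, function(s) {
    rsa_optimize(h, 1, "otsu", cfg, seed = s)$fitness >= target * 0.999
  }, logical(1)))
  expect_gte(hits, 28)
})

test_that("tidy, glance and autoplot expose the fit", {
  h <- delta_histogram(c(60, 200), c(0.5, 0.5), total = 1000)
  fit <- rsa_optimize(h, 1, "otsu",
                      config = rsa_config(population = 6L, iterations = 8L),
                      seed = 2)
  td <- tidy(fit)
  expect_named(td, c("iteration", "phase", "best_fitness"))
  expect_equal(nrow(td), 8)
  gl <- glance(fit)
  expect_equal(gl$k, 1L)
  expect_equal(gl$seed, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
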