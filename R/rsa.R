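#' Optimizer configuration
#'
#' Defaults follow the study conditions used throughout the package: a
#' population of 25 candidates evolved for 100 iterations and repeated over 30
#' independent runs, RSA sensitivity parameters `beta = 0.1` (high-walk
#' exploration accuracy) and `alpha = 0.1` (hunting-cooperation accuracy), and
#' the global-best velocity operator's inertia decaying linearly from 0.9 to
#' 0.2 with acceleration coefficients `c1 = c2 = 2`.
#'
#' @param population Number of candidate solutions (>= 2).
#' @param iterations Iteration count `T` (>= 4: each of the four phase
#'   strategies owns one quarter of the schedule).
#' @param beta,alpha RSA sensitivity parameters.
#' @param epsilon Small stabilizer used by the reduction function and the
#'   cooperation step.
#' @param w_max,w_min Inertia weight range for the Gbest velocity update.
#' @param c1,c2 Acceleration coefficients for the Gbest velocity update.
#' @param runs Default number of repeated runs in the benchmark harness.
#' @param seed Optional integer seed recorded in the config; [rsa_optimize()]
#'   uses it when no explicit seed is given.
#' @return A list of class `rsa_config`.
#' @export
rsa_config <- function(population = 25L, iterations = 100L,
                       beta = 0.1, alpha = 0.1, epsilon = 1e-10,
                       w_max = 0.9, w_min = 0.2, c1 = 2, c2 = 2,
                       runs = 30L, seed = NULL) {
  stopifnot(population >= 2L, iterations >= 4L, epsilon > 0,
            w_max >= w_min, beta > 0)
  structure(
    list(population = as.integer(population), iterations = as.integer(iterations),
         beta = beta, alpha = alpha, epsilon = epsilon,
         w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
         runs = as.integer(runs), seed = seed),
    class = "rsa_config"
  )
}

#' Search bounds
#'
#' @param lower,upper Box bounds (`lower < upper`); thresholding uses
#'   `[1, L-1]`.
#' @param n Problem dimension (threshold count).
#' @return A list of class `search_bounds`.
#' @export
search_bounds <- function(lower = 1, upper = 255, n) {
  stopifnot(lower < upper, n >= 1)
  structure(list(lower = lower, upper = upper, n = as.integer(n)),
            class = "search_bounds")
}

#' Initialize the RSA population
#'
#' Positions are drawn coordinate-wise as `rand * (UB - LB) + LB` from the
#' current RNG stream; velocities start at zero and each candidate's personal
#' best is its initial position.
#'
#' @param cfg An [rsa_config()].
#' @param bounds A [search_bounds()].
#' @return A list with `X` (population x dimension position matrix), `V`
#'   (velocities), `pbest` (personal-best positions) and `pbest_fit`
#'   (personal-best fitnesses, initialized to `-Inf` until first evaluation).
#' @export
init_population <- function(cfg, bounds) {
  N <- cfg$population
  n <- bounds$n
  X <- matrix(runif(N * n) * (bounds$upper - bounds$lower) + bounds$lower,
              nrow = N, ncol = n)
  list(X = X, V = matrix(0, N, n), pbest = X, pbest_fit = rep(-Inf, N))
}

#' Evolutionary sense schedule
#'
#' `ES(t) = 2 * r3 * (1 - t/T)`: a stochastic coefficient whose magnitude
#' shrinks from 2 toward 0 over the run, scaling the belly-walk step.
#'
#' @param t Current iteration (1-based).
#' @param T_max Total iterations.
#' @param r3 A draw from uniform `[-1, 1]` (one per iteration).
#' @return A scalar in `[-2, 2]`.
#' @export
evolutionary_sense <- function(t, T_max, r3) {
  2 * r3 * (1 - t / T_max)
}

#' Reduction function
#'
#' `R_ij = (best_j - x_{r2,j}) / (best_j + epsilon)`: narrows the search
#' region around the incumbent best by comparing it with a randomly chosen
#' candidate's coordinate.
#'
#' @param best_j Incumbent-best coordinate.
#' @param x_r2j Coordinate of a uniformly drawn candidate.
#' @param epsilon Small positive stabilizer.
#' @return A scalar.
#' @export
reduction_function <- function(best_j, x_r2j, epsilon = 1e-10) {
  (best_j - x_r2j) / (best_j + epsilon)
}

#' Percentage difference between the best and current position
#'
#' `P_ij = alpha + (x_ij - mean(x_i)) / (best_j * (UB - LB) + epsilon)`.
#'
#' @param x_ij Current coordinate.
#' @param mean_xi Mean of the candidate's coordinates.
#' @param best_j Incumbent-best coordinate.
#' @param bounds A [search_bounds()].
#' @param alpha Sensitivity parameter (default 0.1).
#' @param epsilon Small positive stabilizer.
#' @return A scalar.
#' @export
percentage_difference <- function(x_ij, mean_xi, best_j, bounds,
                                  alpha = 0.1, epsilon = 1e-10) {
  alpha + (x_ij - mean_xi) / (best_j * (bounds$upper - bounds$lower) + epsilon)
}

#' Mean position of a candidate
#'
#' @param x_i Coordinate vector of one candidate.
#' @return Arithmetic mean of the coordinates.
#' @export
mean_position <- function(x_i) {
  sum(x_i) / length(x_i)
}

#' Active RSA phase for an iteration
#'
#' The schedule is split into quarters: high walking (`t <= T/4`), belly
#' walking (`T/4 < t <= T/2`), hunting coordination (`T/2 < t <= 3T/4`) and
#' hunting cooperation (`3T/4 < t <= T`).
#'
#' @param t Current iteration (1-based).
#' @param T_max Total iterations.
#' @return One of `"high_walk"`, `"belly_walk"`, `"hunt_coordination"`,
#'   `"hunt_cooperation"`.
#' @export
rsa_phase <- function(t, T_max) {
  if (t <= T_max / 4) "high_walk"
  else if (t <= 2 * T_max / 4) "belly_walk"
  else if (t <= 3 * T_max / 4) "hunt_coordination"
  else "hunt_cooperation"
}

#' One RSA phase move for a single candidate
#'
#' Applies the active strategy coordinate-wise and clamps the result to the
#' bounds. All `rand` symbols are fresh uniform `[0, 1]` draws per coordinate;
#' `r1` is one uniform candidate index per call, `r2` is resampled per
#' coordinate.
#'
#' @param x_i Current position (length-n vector).
#' @param best Incumbent-best position.
#' @param X Full population matrix (for the `r1`/`r2` draws).
#' @param t,T_max Iteration and iteration count.
#' @param es Evolutionary-sense value for this iteration (see
#'   [evolutionary_sense()]).
#' @param cfg An [rsa_config()].
#' @param bounds A [search_bounds()].
#' @return The proposed new position, clamped to the bounds.
#' @export
phase_update <- function(x_i, best, X, t, T_max, es, cfg, bounds) {
  n <- length(x_i)
  N <- nrow(X)
  phase <- rsa_phase(t, T_max)
  if (phase == "belly_walk") {
    r1 <- sample.int(N, 1L)
    new_x <- best * X[r1, ] * es * runif(n)
  } else {
    m_i <- mean_position(x_i)
    P <- cfg$alpha + (x_i - m_i) / (best * (bounds$upper - bounds$lower) + cfg$epsilon)
    eta <- best * P
    if (phase == "hunt_coordination") {
      new_x <- best * P * runif(n)
    } else {
      r2 <- sample.int(N, n, replace = TRUE)
      R <- (best - X[cbind(r2, seq_len(n))]) / (best + cfg$epsilon)
      if (phase == "high_walk") {
        new_x <- best * eta * cfg$beta - R * runif(n)
      } else {
        new_x <- best - eta * cfg$epsilon - R * runif(n)
      }
    }
  }
  pmin(pmax(new_x, bounds$lower), bounds$upper)
}

#' Global-best velocity update
#'
#' The PSO-style refinement: `v' = w v + c1 rand1 (Pbest - x) + c2 rand2
#' (Gbest - x)`, `x' = x + v'` clamped to the bounds. `rand1` and `rand2` are
#' fresh uniform `[0, 1]` draws per coordinate.
#'
#' @param x_i,v_i Current position and velocity.
#' @param pbest_i Personal-best position of this candidate.
#' @param gbest Population-best position.
#' @param w Inertia weight.
#' @param cfg An [rsa_config()] (for `c1`, `c2`).
#' @param bounds A [search_bounds()].
#' @return List with `position` (clamped) and `velocity`.
#' @export
gbest_update <- function(x_i, v_i, pbest_i, gbest, w, cfg, bounds) {
  n <- length(x_i)
  v_new <- w * v_i + cfg$c1 * runif(n) * (pbest_i - x_i) +
    cfg$c2 * runif(n) * (gbest - x_i)
  list(position = pmin(pmax(x_i + v_new, bounds$lower), bounds$upper),
       velocity = v_new)
}

#' Decode a continuous position into integer thresholds
#'
#' Clamps to `[1, L-1]`, rounds half-up, sorts ascending and resolves
#' duplicates by moving the later value to the next free level above (wrapping
#' downward when the top of the range is full).
#'
#' @param position Real vector of length `n < L - 1`.
#' @param L Number of gray levels.
#' @return A [threshold_vector()].
#' @export
decode_thresholds <- function(position, L = 256L) {
  n <- length(position)
  if (n >= L - 1L) {
    stop("cannot place ", n, " distinct thresholds in [1, ", L - 1L, "]",
         call. = FALSE)
  }
  v <- sort(floor(pmin(pmax(position, 1), L - 1L) + 0.5))
  v <- pmin(as.integer(v), L - 1L)
  used <- logical(L - 1L)                 # used[t] for level t
  out <- integer(n)
  for (i in seq_len(n)) {
    t <- v[i]
    if (used[t]) {
      up <- t
      while (up < L - 1L && used[up]) up <- up + 1L
      if (!used[up]) {
        t <- up
      } else {
        down <- v[i]
        while (down > 1L && used[down]) down <- down - 1L
        t <- down
      }
    }
    used[t] <- TRUE
    out[i] <- t
  }
  threshold_vector(sort(out), L = L)
}

#' Multilevel thresholding with the Gbest-augmented reptile search algorithm
#'
#' Runs the full optimizer: a seeded random population, the four RSA phase
#' strategies over the iteration quarters, the global-best velocity refinement
#' after every phase move, and elitist greedy selection (a candidate keeps the
#' best of its old position, its RSA move and its Gbest move). Fitness is the
#' chosen objective evaluated on decoded integer thresholds, so the reported
#' optimum is always a valid threshold vector.
#'
#' @param h A [channel_histogram()].
#' @param k Number of thresholds to place.
#' @param objective `"otsu"`, `"kapur"`, or a function mapping an integer
#'   threshold vector to a scalar score (maximized).
#' @param config An [rsa_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`. The same
#'   seed, inputs and config reproduce the run exactly.
#' @return An object of class `rsa_fit`: `thresholds`, `fitness`, `trace`
#'   (tibble of per-iteration best-so-far fitness and phase), `objective`,
#'   `k`, `seed`, `config`, `gbest_position`, `evaluations`.
#' @examples
#' h <- delta_histogram(c(60, 200), c(0.5, 0.5), total = 1000)
#' fit <- rsa_optimize(h, k = 1, objective = "otsu",
#'                     config = rsa_config(iterations = 40), seed = 1)
#' fit$thresholds
#' @export
rsa_optimize <- function(h, k, objective = c("otsu", "kapur"),
                         config = rsa_config(), seed = config$seed) {
  stopifnot(inherits(h, "channel_histogram"))
  L <- length(h$probabilities)
  if (k > L - 2L) stop("k must be at most L - 2", call. = FALSE)
  if (is.function(objective)) {
    fobj <- objective
    obj_name <- "custom"
  } else {
    obj_name <- match.arg(objective)
    fobj <- objective_fun(h, obj_name)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  bounds <- search_bounds(1, L - 1L, n = k)
  N <- cfg$population
  T_max <- cfg$iterations
  pop <- init_population(cfg, bounds)
  evals <- 0L
  score_of <- function(x) {
    evals <<- evals + 1L
    fobj(decode_thresholds(x, L = L))
  }
  fit <- apply(pop$X, 1L, score_of)
  pop$pbest_fit <- fit
  g_i <- which.max(fit)
  gbest <- pop$X[g_i, ]
  gbest_fit <- fit[g_i]
  trace_fit <- numeric(T_max)
  trace_phase <- character(T_max)
  for (t in seq_len(T_max)) {
    es <- evolutionary_sense(t, T_max, runif(1, -1, 1))
    w <- cfg$w_max - (cfg$w_max - cfg$w_min) * t / T_max
    for (i in seq_len(N)) {
      x_old <- pop$X[i, ]
      f_old <- fit[i]
      x_rsa <- phase_update(x_old, gbest, pop$X, t, T_max, es, cfg, bounds)
      f_rsa <- score_of(x_rsa)
      gb <- gbest_update(x_old, pop$V[i, ], pop$pbest[i, ], gbest, w, cfg, bounds)
      f_gb <- score_of(gb$position)
      pop$V[i, ] <- gb$velocity
      # greedy selection: keep the best of {old, RSA move, Gbest move}
      if (f_rsa >= f_gb && f_rsa > f_old) {
        pop$X[i, ] <- x_rsa; fit[i] <- f_rsa
      } else if (f_gb > f_old) {
        pop$X[i, ] <- gb$position; fit[i] <- f_gb
      }
      f_new <- max(f_old, f_rsa, f_gb)
      if (f_new > pop$pbest_fit[i]) {
        pop$pbest_fit[i] <- f_new
        pop$pbest[i, ] <- pop$X[i, ]
      }
      if (f_new > gbest_fit) {
        gbest_fit <- f_new
        gbest <- pop$X[i, ]
      }
    }
    trace_fit[t] <- gbest_fit
    trace_phase[t] <- rsa_phase(t, T_max)
  }
  structure(
    list(
      thresholds = decode_thresholds(gbest, L = L),
      fitness = gbest_fit,
      trace = tibble::tibble(iteration = seq_len(T_max),
                             phase = trace_phase,
                             best_fitness = trace_fit),
      objective = obj_name, k = as.integer(k), seed = seed,
      config = cfg, gbest_position = gbest, evaluations = evals
    ),
    class = "rsa_fit"
  )
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf(
    "<rsa_fit> %s objective, k = %d\n  thresholds: %s\n  fitness: %.6g (%d evaluations)\n",
    x$objective, x$k, paste(x$thresholds, collapse = ", "),
    x$fitness, x$evaluations
  ))
  invisible(x)
}

#' Per-iteration convergence trace of a fit
#'
#' @param x An `rsa_fit`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `phase`, `best_fitness`.
#' @method tidy rsa_fit
#' @export
tidy.rsa_fit <- function(x, ...) x$trace

#' One-row summary of a fit
#'
#' @param x An `rsa_fit`.
#' @param ... Unused.
#' @return A tibble with the objective, `k`, thresholds, final fitness, seed
#'   and evaluation count.
#' @method glance rsa_fit
#' @export
glance.rsa_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, k = x$k,
    thresholds = paste(x$thresholds, collapse = ","),
    fitness = x$fitness,
    iterations = x$config$iterations,
    population = x$config$population,
    evaluations = x$evaluations,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Convergence plot of a fit
#'
#' @param object An `rsa_fit`.
#' @param ... Unused.
#' @return A ggplot: best-so-far fitness against iteration, colored by the
#'   active RSA phase.
#' @method autoplot rsa_fit
#' @export
autoplot.rsa_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$phase), size = 0.8) +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness",
                  title = sprintf("RSA-Gbest convergence (%s, k = %d)",
                                  object$objective, object$k))
}
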