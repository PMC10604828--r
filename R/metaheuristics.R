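#' Aquila Optimizer parameters
#'
#' Tunable constants of the Aquila Optimizer update rules. Defaults follow
#' the algorithm's original published values.
#'
#' @param alpha,delta Exploitation adjustment parameters (default 0.1 each).
#' @param levy_beta Levy-flight stability index in (0, 2] (default 1.5).
#' @param levy_s Levy step scale (default 0.01).
#' @param spiral_U,spiral_omega Spiral-shape constants of the narrowed
#'   exploration move (defaults 0.00565 and 0.005).
#' @param r1_base Spiral radius base, an integer in \code{[1, 20]}
#'   (default 10).
#' @return A list of class \code{ao_params}.
#' @export
ao_params <- function(alpha = 0.1, delta = 0.1, levy_beta = 1.5,
                      levy_s = 0.01, spiral_U = 0.00565,
                      spiral_omega = 0.005, r1_base = 10L) {
  stopifnot(levy_beta > 0, levy_beta <= 2, r1_base >= 1, r1_base <= 20)
  structure(list(alpha = alpha, delta = delta, levy_beta = levy_beta,
                 levy_s = levy_s, spiral_U = spiral_U,
                 spiral_omega = spiral_omega, r1_base = r1_base),
            class = "ao_params")
}

#' Gorilla Troops Optimizer parameters
#'
#' @param p Migration probability (default 0.03).
#' @param W Exploitation switch threshold (default 0.8).
#' @param beta Violence coefficient of the competition move (default 3).
#' @return A list of class \code{gto_params}.
#' @export
gto_params <- function(p = 0.03, W = 0.8, beta = 3) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p, W = W, beta = beta), class = "gto_params")
}

#' Levy flight step vector
#'
#' Draws a D-dimensional heavy-tailed step via the Mantegna algorithm:
#' per component \code{s * u * sigma / |v|^(1/beta)} with \code{u, v}
#' standard normal and \code{sigma} the Mantegna constant
#' \deqn{\sigma = \left(\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right)^{1/\beta}.}
#'
#' @param D Dimension (>= 1).
#' @param beta Stability index (default 1.5).
#' @param s Scale (default 0.01).
#' @return Numeric vector of length \code{D}.
#' @export
levy_step <- function(D, beta = 1.5, s = 0.01) {
  sigma <- mantegna_sigma(beta)
  u <- stats::rnorm(D) * sigma
  v <- stats::rnorm(D)
  s * u / abs(v)^(1 / beta)
}

#' @rdname levy_step
#' @export
mantegna_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Rank a population by fitness
#'
#' Stable sort, best (highest fitness) first, so the best and worst members
#' are the first and last rows. Ties keep their original relative order.
#'
#' @param population List with \code{positions} (N x D matrix) and
#'   \code{fitness} (length-N numeric).
#' @return The population, rows reordered by non-increasing fitness.
#' @export
rank_population <- function(population) {
  stopifnot(!anyNA(population$fitness))
  ord <- order(-population$fitness)  # radix order is stable
  population$positions <- population$positions[ord, , drop = FALSE]
  population$fitness <- population$fitness[ord]
  population
}

# Greedy replacement: evaluate a candidate row and keep it only if better.
.greedy_accept <- function(population, i, candidate, evaluate) {
  candidate <- clip_to_bounds(candidate)
  f <- evaluate(candidate)
  if (f > population$fitness[i]) {
    population$positions[i, ] <- candidate
    population$fitness[i] <- f
  }
  population
}

#' One Aquila Optimizer iteration
#'
#' Updates every member of an evaluated, ranked population. While
#' \code{t <= (2/3) * t_max} candidates come from the exploration moves:
#' expanded exploration
#' \code{Xbest * (1 - t/T) + (XM - Xbest) * rand} or narrowed exploration
#' \code{Xbest * Levy(D) + XR + (y - x) * rand}, a fair coin choosing
#' between them. Afterwards the exploitation moves take over: expanded
#' exploitation \code{(Xbest - XM) * alpha - rand + ((UB - LB) * rand + LB) *
#' delta} or narrowed exploitation
#' \code{QF * Xbest - G1 * X * rand - G2 * Levy(D) + rand * G1}, again a fair
#' coin. Candidates are clipped to \code{[0,1]}, evaluated, and accepted
#' greedily (only on improvement). \code{XM} is the mean position,
#' \code{XR} a random member, \code{QF = t^((2 rand - 1)/(1 - T)^2)},
#' \code{G1 = 2 rand - 1} and \code{G2 = 2 (1 - t/T)}.
#'
#' @param population List with \code{positions}, \code{fitness} (evaluated).
#' @param t,t_max Current iteration (1-based) and iteration budget.
#' @param evaluate Function mapping a position vector to a fitness score.
#' @param params An \code{\link{ao_params}} object.
#' @param counters Optional environment; when supplied, the fields
#'   \code{exploration}/\code{exploitation} are incremented per candidate
#'   (instrumentation for phase tests).
#' @return The updated population.
#' @export
ao_update <- function(population, t, t_max, evaluate, params = ao_params(),
                      counters = NULL) {
  N <- nrow(population$positions)
  D <- ncol(population$positions)
  xbest <- population$positions[1, ]
  xm <- colMeans(population$positions)
  explore <- t <= (2 / 3) * t_max
  # spiral coordinates of the narrowed exploration move
  d1 <- seq_len(D)
  r <- params$r1_base + params$spiral_U * d1
  theta <- -params$spiral_omega * d1 + 3 * pi / 2
  x_sp <- r * sin(theta)
  y_sp <- r * cos(theta)
  for (i in seq_len(N)) {
    xi <- population$positions[i, ]
    if (explore) {
      if (!is.null(counters)) counters$exploration <- counters$exploration + 1L
      if (stats::runif(1) < 0.5) {
        cand <- xbest * (1 - t / t_max) + (xm - xbest) * stats::runif(1)
      } else {
        xr <- population$positions[sample.int(N, 1L), ]
        cand <- xbest * levy_step(D, params$levy_beta, params$levy_s) + xr +
          (y_sp - x_sp) * stats::runif(1)
      }
    } else {
      if (!is.null(counters)) counters$exploitation <- counters$exploitation + 1L
      if (stats::runif(1) < 0.5) {
        cand <- (xbest - xm) * params$alpha - stats::runif(1) +
          ((1 - 0) * stats::runif(1) + 0) * params$delta
      } else {
        qf <- t^((2 * stats::runif(1) - 1) / (1 - t_max)^2)
        g1 <- 2 * stats::runif(1) - 1
        g2 <- 2 * (1 - t / t_max)
        cand <- qf * xbest - g1 * xi * stats::runif(1) -
          g2 * levy_step(D, params$levy_beta, params$levy_s) +
          stats::runif(1) * g1
      }
    }
    population <- .greedy_accept(population, i, cand, evaluate)
  }
  population
}

#' One Gorilla Troops Optimizer iteration
#'
#' Runs the exploration sweep then the exploitation sweep over all members,
#' with greedy acceptance after each candidate. Exploration, per member:
#' with probability \code{p} migrate to an unknown location (a fresh uniform
#' draw in \code{[0,1]^D}); else with probability 1/2 move toward another
#' gorilla \code{(r2 - C) * Xr + L * H}; else the third strategy
#' \code{X - L * (L * (X - Xr) + r3 * (X - Xr))}. Exploitation: when
#' \code{C >= W} follow the silverback \code{L * M * (X - Xsilverback) + X};
#' otherwise competition for adult females
#' \code{Xsilverback - (Xsilverback * Q - X * Q) * A}. Auxiliary quantities:
#' \code{C = F (1 - t/t_max)} with \code{F = cos(2 r4) + 1}, \code{L = C l}
#' with \code{l ~ U(-1,1)}, \code{H = Z X} with \code{Z ~ U(-C, C)},
#' \code{M = (|mean position|^g)^(1/g)} with \code{g = 2^L},
#' \code{Q = 2 r5 - 1}, and \code{A = beta * E} with \code{E} a standard
#' normal vector or scalar with probability 1/2 each.
#'
#' @inheritParams ao_update
#' @param params A \code{\link{gto_params}} object.
#' @return The updated population (best member = silverback afterwards).
#' @export
gto_update <- function(population, t, t_max, evaluate, params = gto_params()) {
  N <- nrow(population$positions)
  D <- ncol(population$positions)
  Fq <- cos(2 * stats::runif(1)) + 1
  C <- Fq * (1 - t / t_max)
  # exploration sweep
  for (i in seq_len(N)) {
    xi <- population$positions[i, ]
    L <- C * stats::runif(1, -1, 1)
    if (stats::runif(1) < params$p) {
      cand <- stats::runif(D)
    } else if (stats::runif(1) >= 0.5) {
      xr <- population$positions[sample.int(N, 1L), ]
      Z <- stats::runif(D, -C, C)
      H <- Z * xi
      cand <- (stats::runif(1) - C) * xr + L * H
    } else {
      xr <- population$positions[sample.int(N, 1L), ]
      cand <- xi - L * (L * (xi - xr) + stats::runif(1) * (xi - xr))
    }
    population <- .greedy_accept(population, i, cand, evaluate)
  }
  # exploitation sweep, relative to the current silverback
  population <- rank_population(population)
  xsb <- population$positions[1, ]
  for (i in seq_len(N)) {
    xi <- population$positions[i, ]
    L <- C * stats::runif(1, -1, 1)
    if (C >= params$W) {
      g <- 2^L
      M <- (abs(colMeans(population$positions))^g)^(1 / g)
      cand <- L * M * (xi - xsb) + xi
    } else {
      Q <- 2 * stats::runif(1) - 1
      A <- params$beta * (if (stats::runif(1) < 0.5) stats::rnorm(D)
                          else stats::rnorm(1))
      cand <- xsb - (xsb * Q - xi * Q) * A
    }
    population <- .greedy_accept(population, i, cand, evaluate)
  }
  rank_population(population)
}

#' Run a metaheuristic hyperparameter search
#'
#' Initializes a random population in the unit hypercube, then for
#' \code{t_max} iterations evaluates all members through
#' \code{objective(decode_solution(x, space))}, ranks them, and applies the
#' chosen optimizer's update sweep. Greedy acceptance makes the best-so-far
#' fitness non-decreasing.
#'
#' @param objective Function taking a \code{decoded_configuration} (or, for a
#'   raw continuous space, the named list of decoded values) and returning a
#'   scalar fitness to maximize.
#' @param space A \code{search_space} (or any list of spans with \code{D}).
#' @param n_solutions Population size (default 10).
#' @param t_max Iteration budget (>= 1, default 10).
#' @param algorithm \code{"AO"} or \code{"GTO"}.
#' @param seed Integer seed; fixes the whole run.
#' @param params Optional \code{\link{ao_params}}/\code{\link{gto_params}}.
#' @param decode Decoder applied to position vectors before calling
#'   \code{objective}; defaults to \code{\link{decode_solution}}. Pass
#'   \code{identity}-like functions to optimize raw vectors (see
#'   \code{\link{benchmark_objective}}).
#' @return A list of class \code{optimizer_run} with \code{best_configuration}
#'   (decoded), \code{best_vector}, \code{best_fitness}, \code{history}
#'   (per-iteration best fitness, length \code{t_max}), \code{mean_history},
#'   \code{algorithm}, \code{seed} and \code{n_evaluations}.
#' @export
run_optimizer <- function(objective, space, n_solutions = 10, t_max = 10,
                          algorithm = c("AO", "GTO"), seed = 1,
                          params = NULL,
                          decode = function(v, s) decode_solution(v, s)) {
  algorithm <- match.arg(algorithm)
  stopifnot(t_max >= 1)
  if (is.null(params))
    params <- if (algorithm == "AO") ao_params() else gto_params()
  local_seed(seed)
  n_evals <- 0L
  evaluate <- function(v) {
    n_evals <<- n_evals + 1L
    cfg <- decode(v, space)
    f <- tryCatch(objective(cfg), error = function(e)
      stop("evaluation error for configuration [",
           paste(deparse(cfg), collapse = " "), "]: ",
           conditionMessage(e), call. = FALSE))
    if (!is.finite(f)) stop("evaluation error: non-finite fitness")
    f
  }
  positions <- matrix(stats::runif(n_solutions * space$D),
                      nrow = n_solutions, ncol = space$D)
  fitness <- apply(positions, 1, evaluate)
  pop <- rank_population(list(positions = positions, fitness = fitness))
  history <- numeric(t_max)
  mean_history <- numeric(t_max)
  for (t in seq_len(t_max)) {
    pop <- if (algorithm == "AO")
      ao_update(pop, t, t_max, evaluate, params)
    else
      gto_update(pop, t, t_max, evaluate, params)
    pop <- rank_population(pop)
    history[t] <- pop$fitness[1]
    mean_history[t] <- mean(pop$fitness)
  }
  structure(list(
    best_configuration = decode(pop$positions[1, ], space),
    best_vector = pop$positions[1, ],
    best_fitness = pop$fitness[1],
    history = history,
    mean_history = mean_history,
    algorithm = algorithm,
    seed = seed,
    n_evaluations = n_evals), class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("<optimizer_run> %s, best fitness %.4f after %d evaluations\n",
              x$algorithm, x$best_fitness, x$n_evaluations))
  invisible(x)
}

#' Equal-budget random search baseline
#'
#' Evaluates \code{n_evaluations} uniform draws in the unit hypercube and
#' returns the best; the comparison baseline for the optimizers.
#'
#' @inheritParams run_optimizer
#' @param n_evaluations Total evaluation budget.
#' @return List with \code{best_fitness}, \code{best_vector}.
#' @export
random_search <- function(objective, space, n_evaluations, seed = 1,
                          decode = function(v, s) decode_solution(v, s)) {
  local_seed(seed)
  best_f <- -Inf
  best_v <- NULL
  for (i in seq_len(n_evaluations)) {
    v <- stats::runif(space$D)
    f <- objective(decode(v, space))
    if (f > best_f) {
      best_f <- f
      best_v <- v
    }
  }
  list(best_fitness = best_f, best_vector = best_v)
}

#' Write an optimization history as CSV
#'
#' One row per iteration: iteration, best fitness, mean fitness, and the
#' best configuration serialized as a JSON string.
#'
#' @param run An \code{optimizer_run}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_history <- function(run, path) {
  df <- data.frame(
    iteration = seq_along(run$history),
    best_fitness = run$history,
    mean_fitness = run$mean_history)
  df$best_configuration <- as.character(jsonlite::toJSON(
    unclass_deep(run$best_configuration), auto_unbox = TRUE, digits = NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
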