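#' Configuration for the quantum-behaved particle swarm optimizer
#'
#' QBPSO replaces the velocity/position update of standard PSO by a
#' quantum-inspired probabilistic scheme: each particle is treated as a
#' quantum particle confined in a potential well around a local attractor and
#' its next position is sampled from the analytical distribution of that
#' well.  The only control parameter is the contraction-expansion
#' coefficient, here annealed linearly from `beta_hi` to `beta_lo` by
#' default, or held constant at `psi` (`beta_mode = "constant"`).
#'
#' @param dimension problem dimension D.
#' @param num_particles swarm size M (default 100).
#' @param max_iter maximum number of iterations (default 350, the
#'   feature-selection preset; use 1000 for continuous optimization).
#' @param bounds length-2 numeric, the closed search box per dimension
#'   (default `c(-1, 1)`, positions are clipped to it).
#' @param beta_mode `"linear"` (annealed, default) or `"constant"`.
#' @param beta_hi,beta_lo endpoints of the linear schedule
#'   `beta_lo + (beta_hi - beta_lo) * (1 - iter/max_iter)`; the defaults
#'   (1.0, 0.1) give `0.9 * (1 - iter/max_iter) + 0.1`.
#' @param psi constant contraction-expansion coefficient used when
#'   `beta_mode = "constant"` (default 0.8).
#' @param attraction inert, documented-only coefficient (default 0.85); it
#'   parameterizes nothing in the update equations and is kept purely as a
#'   configuration record.
#' @param function_tolerance nonnegative stopping tolerance (default 1e-10),
#'   active only when `known_optimum_zero` is `TRUE`.
#' @param known_optimum_zero logical; declare that the objective's optimum is
#'   0 so that the tolerance test `|best score| <= function_tolerance` is
#'   meaningful (default `FALSE`: run to `max_iter`).
#' @param seed integer RNG seed.
#' @param maximize logical; maximize instead of minimize (default `FALSE`).
#' @return an object of class `qbpso_config`.
#' @export
qbpso_config <- function(dimension,
                         num_particles = 100L,
                         max_iter = 350L,
                         bounds = c(-1, 1),
                         beta_mode = c("linear", "constant"),
                         beta_hi = 1.0,
                         beta_lo = 0.1,
                         psi = 0.8,
                         attraction = 0.85,
                         function_tolerance = 1e-10,
                         known_optimum_zero = FALSE,
                         seed = 1L,
                         maximize = FALSE) {
  beta_mode <- match.arg(beta_mode)
  stopifnot(dimension >= 1, num_particles >= 1, max_iter >= 1,
            length(bounds) == 2, bounds[1] < bounds[2],
            beta_hi >= beta_lo, beta_lo > 0, psi > 0,
            function_tolerance >= 0)
  structure(list(dimension = as.integer(dimension),
                 num_particles = as.integer(num_particles),
                 max_iter = as.integer(max_iter),
                 bounds = as.numeric(bounds),
                 beta_mode = beta_mode,
                 beta_hi = beta_hi, beta_lo = beta_lo, psi = psi,
                 attraction = attraction,
                 function_tolerance = function_tolerance,
                 known_optimum_zero = known_optimum_zero,
                 seed = as.integer(seed),
                 maximize = maximize),
            class = "qbpso_config")
}

#' Contraction-expansion coefficient at a given iteration
#'
#' Linear mode anneals `beta_lo + (beta_hi - beta_lo) * (1 - iter/max_iter)`
#' (defaults: from 1.0 down to 0.1); constant mode returns `psi` regardless
#' of the iteration.
#'
#' @param iter nonnegative iteration counter, `0 <= iter <= max_iter`.
#' @param config a [qbpso_config()].
#' @return positive scalar.
#' @export
beta_at <- function(iter, config) {
  if (iter < 0 || iter > config$max_iter)
    stop("iter must lie in [0, max_iter]")
  if (config$beta_mode == "constant") return(config$psi)
  config$beta_lo + (config$beta_hi - config$beta_lo) *
    (1 - iter / config$max_iter)
}

#' Local attractor of a particle
#'
#' The per-particle convex combination of its personal best and the global
#' best toward which the quantum particle collapses:
#' `p = xi * lbest + (1 - xi) * gbest`, elementwise, with `xi ~ U(0,1)^D`.
#'
#' @param lbest,gbest,xi numeric vectors of equal length.
#' @return numeric vector.
#' @export
local_attractor <- function(lbest, gbest, xi) {
  if (length(lbest) != length(gbest) || length(lbest) != length(xi))
    stop("lbest, gbest and xi must have equal lengths")
  xi * lbest + (1 - xi) * gbest
}

#' Mean-best position of the swarm
#'
#' Column-wise mean of the personal-best matrix.
#'
#' @param pbest M x D numeric matrix of personal bests.
#' @return length-D numeric vector.
#' @export
mean_best <- function(pbest) {
  pbest <- as.matrix(pbest)
  if (nrow(pbest) < 1) stop("empty swarm")
  colMeans(pbest)
}

#' Random draws for one particle position update
#'
#' @param d dimension.
#' @return list with `xi` (U(0,1)), `u` (U(0,1), strictly positive) and
#'   `sign` (+1/-1 with probability 0.5 each, drawn per dimension).
#' @export
update_draws <- function(d) {
  list(xi = stats::runif(d),
       u = stats::runif(d),
       sign = ifelse(stats::runif(d) < 0.5, 1, -1))
}

#' Quantum position update
#'
#' `x'_d = p_d + sign_d * beta * |mbest_d - x_d| * log(1/u_d)`, clipped to
#' the search box.
#'
#' @param x current position.
#' @param p local attractor (see [local_attractor()]).
#' @param mbest swarm mean-best position.
#' @param beta positive contraction-expansion coefficient.
#' @param draws an [update_draws()] list.
#' @param bounds length-2 box, positions are clipped into it.
#' @return updated position vector.
#' @export
update_position <- function(x, p, mbest, beta, draws, bounds = c(-1, 1)) {
  stopifnot(beta > 0)
  if (any(draws$u <= 0)) stop("all u draws must be strictly positive")
  xp <- p + draws$sign * beta * abs(mbest - x) * log(1 / draws$u)
  pmin(pmax(xp, bounds[1]), bounds[2])
}

# Worst-possible score for the optimization direction.
worst_score <- function(config) if (config$maximize) -Inf else Inf

better <- function(a, b, config) if (config$maximize) a > b else a < b

#' One QBPSO iteration
#'
#' Scores every particle, updates personal/global bests where improved,
#' refreshes the mean-best position once from the current personal bests and
#' then moves every particle through its local attractor with fresh draws.
#' Non-finite objective values are treated as worst-possible (the particle is
#' simply not recorded as improving and is re-drawn on the next iteration).
#'
#' @param state swarm state list as produced by [qbpso_init()] or a previous
#'   step.
#' @param objective deterministic function from a length-D vector to a
#'   scalar.
#' @param config a [qbpso_config()].
#' @return updated swarm state.
#' @export
qbpso_step <- function(state, objective, config) {
  M <- config$num_particles
  scores <- apply(state$positions, 1, objective)
  scores[!is.finite(scores)] <- worst_score(config)
  improved <- if (config$maximize) scores > state$pbest_scores
              else scores < state$pbest_scores
  state$pbest[improved, ] <- state$positions[improved, , drop = FALSE]
  state$pbest_scores[improved] <- scores[improved]
  g <- if (config$maximize) which.max(state$pbest_scores)
       else which.min(state$pbest_scores)
  state$gbest <- state$pbest[g, ]
  state$gbest_score <- state$pbest_scores[g]
  state$mbest <- mean_best(state$pbest)
  beta <- beta_at(state$iteration, config)
  for (j in seq_len(M)) {
    draws <- update_draws(config$dimension)
    p <- local_attractor(state$pbest[j, ], state$gbest, draws$xi)
    state$positions[j, ] <- update_position(state$positions[j, ], p,
                                            state$mbest, beta, draws,
                                            config$bounds)
  }
  state$iteration <- state$iteration + 1L
  state
}

#' Initialize a QBPSO swarm
#'
#' Positions are drawn uniformly inside the search box; personal-best scores
#' start at the worst-possible value so the first scoring pass defines them.
#'
#' @param config a [qbpso_config()].
#' @return swarm state list.
#' @export
qbpso_init <- function(config) {
  M <- config$num_particles; D <- config$dimension
  positions <- matrix(stats::runif(M * D, config$bounds[1], config$bounds[2]),
                      M, D)
  list(positions = positions,
       pbest = positions,
       pbest_scores = rep(worst_score(config), M),
       gbest = positions[1, ],
       gbest_score = worst_score(config),
       mbest = colMeans(positions),
       iteration = 0L)
}

#' Run the quantum-behaved particle swarm optimizer
#'
#' Iterates [qbpso_step()] until `max_iter` or, when the caller declares a
#' known zero optimum (`known_optimum_zero = TRUE`), until the best score
#' falls within `function_tolerance` of zero.
#'
#' @param objective deterministic function from a length-D vector to a
#'   scalar.
#' @param config a [qbpso_config()].
#' @return an object of class `qbpso_result`: list with `best_position`,
#'   `best_score`, `score_trace` (per-iteration best), `iterations_run` and
#'   `terminated_by` (`"max_iter"` or `"tolerance"`).
#' @examples
#' cfg <- qbpso_config(dimension = 2, num_particles = 30, max_iter = 200,
#'                     known_optimum_zero = TRUE, seed = 1)
#' res <- qbpso_optimize(function(x) sum(x^2), cfg)
#' res$best_score
#' @export
qbpso_optimize <- function(objective, config) {
  set.seed(config$seed)
  state <- qbpso_init(config)
  trace <- numeric(0)
  terminated <- "max_iter"
  for (t in seq_len(config$max_iter)) {
    state <- qbpso_step(state, objective, config)
    trace[t] <- state$gbest_score
    if (config$known_optimum_zero &&
        is.finite(state$gbest_score) &&
        abs(state$gbest_score) <= config$function_tolerance) {
      terminated <- "tolerance"
      break
    }
  }
  structure(list(best_position = state$gbest,
                 best_score = state$gbest_score,
                 score_trace = trace,
                 iterations_run = length(trace),
                 terminated_by = terminated),
            class = "qbpso_result")
}

#' @export
print.qbpso_result <- function(x, ...) {
  cat("QBPSO result\n")
  cat("  best score:", format(x$best_score), "\n")
  cat("  iterations:", x$iterations_run, "(", x$terminated_by, ")\n")
  invisible(x)
}

#' Standard inertia-weight particle swarm optimizer (comparison baseline)
#'
#' Textbook velocity-based PSO (inertia 0.72, cognitive/social weights 1.49)
#' used only as a baseline hook for Monte-Carlo comparisons against QBPSO.
#'
#' @inheritParams qbpso_optimize
#' @param inertia,c1,c2 textbook PSO coefficients.
#' @return a `qbpso_result`-shaped list.
#' @export
spso_optimize <- function(objective, config, inertia = 0.72,
                          c1 = 1.49, c2 = 1.49) {
  set.seed(config$seed)
  M <- config$num_particles; D <- config$dimension
  lo <- config$bounds[1]; hi <- config$bounds[2]
  x <- matrix(stats::runif(M * D, lo, hi), M, D)
  v <- matrix(stats::runif(M * D, -(hi - lo), hi - lo) * 0.1, M, D)
  pbest <- x
  pscore <- rep(worst_score(config), M)
  trace <- numeric(config$max_iter)
  for (t in seq_len(config$max_iter)) {
    s <- apply(x, 1, objective)
    s[!is.finite(s)] <- worst_score(config)
    imp <- if (config$maximize) s > pscore else s < pscore
    pbest[imp, ] <- x[imp, , drop = FALSE]
    pscore[imp] <- s[imp]
    g <- if (config$maximize) which.max(pscore) else which.min(pscore)
    r1 <- matrix(stats::runif(M * D), M, D)
    r2 <- matrix(stats::runif(M * D), M, D)
    v <- inertia * v + c1 * r1 * (pbest - x) +
      c2 * r2 * (matrix(pbest[g, ], M, D, byrow = TRUE) - x)
    x <- pmin(pmax(x + v, lo), hi)
    trace[t] <- pscore[g]
  }
  g <- if (config$maximize) which.max(pscore) else which.min(pscore)
  structure(list(best_position = pbest[g, ], best_score = pscore[g],
                 score_trace = trace, iterations_run = config$max_iter,
                 terminated_by = "max_iter"),
            class = "qbpso_result")
}

#' Read a flat key-value optimizer configuration file
#'
#' Recognized keys: `particles`, `max_iter`, `beta_hi`, `beta_lo`,
#' `beta_mode`, `bounds_lo`, `bounds_hi`, `tolerance`, `seed`.
#'
#' @param path file of `key = value` or `key: value` lines.
#' @param dimension problem dimension (not part of the file).
#' @return a [qbpso_config()].
#' @export
read_qbpso_config <- function(path, dimension) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- do.call(rbind, strsplit(lines, "[=:]", fixed = FALSE))
  vals <- stats::setNames(trimws(kv[, 2]), trimws(kv[, 1]))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  qbpso_config(dimension = dimension,
               num_particles = num("particles", 100),
               max_iter = num("max_iter", 350),
               bounds = c(num("bounds_lo", -1), num("bounds_hi", 1)),
               beta_mode = chr("beta_mode", "linear"),
               beta_hi = num("beta_hi", 1.0),
               beta_lo = num("beta_lo", 0.1),
               function_tolerance = num("tolerance", 1e-10),
               seed = num("seed", 1))
}

#' Write an optimization trace as two-column delimited text
#'
#' @param result a `qbpso_result`.
#' @param path output file (columns: iteration, best_score).
#' @export
write_trace <- function(result, path) {
  utils::write.table(
    data.frame(iteration = seq_along(result$score_trace),
               best_score = result$score_trace),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
}
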