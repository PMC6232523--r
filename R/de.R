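#' Differential Evolution control settings
#'
#' Defaults follow the configuration used for the diagnostic-model M-step:
#' `current_to_best_1` mutation with fixed \eqn{F = 0.8}, binomial crossover
#' with \eqn{CR = 0.5}, 500 candidate solutions, box bounds of \eqn{\pm 20}
#' per coordinate, and a stop rule of 1000 generations or a best objective
#' unchanged (within `stall_tol`) for `stall` consecutive generations.
#'
#' @param NP population size (>= 4).
#' @param F mutation scaling factor; with `F_policy = "uniform"` a fresh
#'   U(0, 1) draw is used for every mutation instead.
#' @param CR crossover rate in `[0, 1]`: each trial coordinate is taken from
#'   the mutant when a fresh U(0, 1) draw falls below `CR`.
#' @param strategy mutation strategy: `"rand_1"`, `"current_to_best_1"`
#'   (base vector a random member, plus scaled differences toward the best
#'   member), or `"best_1"`.
#' @param F_policy `"fixed"` or `"uniform"`.
#' @param max_iter generation cap.
#' @param stall,stall_tol stop once the population's objective values have
#'   remained identical (no candidate improved by more than `stall_tol`) for
#'   `stall` consecutive generations.
#' @return list of class `de_control`.
#' @export
de_control <- function(NP = 500, F = 0.8, CR = 0.5,
                       strategy = c("current_to_best_1", "rand_1", "best_1"),
                       F_policy = c("fixed", "uniform"),
                       max_iter = 1000, stall = 10, stall_tol = 1e-8) {
  strategy <- match.arg(strategy)
  F_policy <- match.arg(F_policy)
  if (NP < 4) stop("DE needs a population of at least 4", call. = FALSE)
  if (CR < 0 || CR > 1) stop("CR must lie in [0, 1]", call. = FALSE)
  if (stall < 1) stop("stall must be >= 1", call. = FALSE)
  structure(list(NP = as.integer(NP), F = F, CR = CR, strategy = strategy,
                 F_policy = F_policy, max_iter = as.integer(max_iter),
                 stall = as.integer(stall), stall_tol = stall_tol),
            class = "de_control")
}

#' Initialize a DE population
#'
#' Candidates are drawn uniformly inside the box.  If `center` is supplied
#' (an educated guess), the first candidate is the center itself and the rest
#' are either uniform in the box (`spread = "uniform"`) or jittered around the
#' center by 10% of the box width (`spread = "jitter"`), clipped to the box.
#'
#' @param lower,upper bound vectors (equal length, `lower < upper` allowed to
#'   be degenerate equal for fixed coordinates).
#' @param NP population size.
#' @param center optional starting guess.
#' @param spread placement of the non-center candidates.
#' @return NP x R matrix of candidates.
#' @export
de_init <- function(lower, upper, NP, center = NULL,
                    spread = c("uniform", "jitter")) {
  spread <- match.arg(spread)
  if (length(lower) != length(upper) || any(lower > upper)) {
    stop("invalid bounds", call. = FALSE)
  }
  R <- length(lower)
  pop <- matrix(stats::runif(NP * R), NP, R)
  pop <- sweep(sweep(pop, 2L, upper - lower, "*"), 2L, lower, "+")
  if (!is.null(center)) {
    if (length(center) != R) stop("center length does not match bounds", call. = FALSE)
    if (spread == "jitter" && NP > 1L) {
      width <- upper - lower
      jit <- matrix(stats::runif((NP - 1L) * R, -0.1, 0.1), NP - 1L, R)
      pop[-1L, ] <- sweep(sweep(jit, 2L, width, "*"), 2L, center, "+")
      pop[-1L, ] <- pmin(pmax(pop[-1L, , drop = FALSE],
                              rep(lower, each = NP - 1L)),
                         rep(upper, each = NP - 1L))
    }
    pop[1L, ] <- center
  }
  pop
}

# draw, for each of NP members, three distinct indices from 1..NP that also
# avoid the member's own index; vectorized rejection sampling
draw_mutation_indices <- function(NP) {
  idx <- matrix(sample.int(NP, 3L * NP, replace = TRUE), NP, 3L)
  own <- seq_len(NP)
  repeat {
    bad <- idx[, 1L] == idx[, 2L] | idx[, 1L] == idx[, 3L] |
      idx[, 2L] == idx[, 3L] | idx[, 1L] == own | idx[, 2L] == own |
      idx[, 3L] == own
    if (!any(bad)) return(idx)
    idx[bad, ] <- sample.int(NP, 3L * sum(bad), replace = TRUE)
  }
}

#' DE mutation
#'
#' Implements the three mutation formulas with base vector \eqn{\lambda_{\delta_o}}
#' (or the best member for `best_1`):
#' \describe{
#'   \item{rand_1}{\eqn{m = \lambda_{\delta_o} + F(\lambda_{\delta_1} - \lambda_{\delta_2})}}
#'   \item{current_to_best_1}{\eqn{m = \lambda_{\delta_o} + F(\lambda_{best} - \lambda_{\delta_2}) + F(\lambda_{\delta_1} - \lambda_{\delta_2})}}
#'   \item{best_1}{\eqn{m = \lambda_{best} + F(\lambda_{\delta_1} - \lambda_{\delta_2})}}
#' }
#' \eqn{\delta_o, \delta_1, \delta_2} are distinct uniform draws from the
#' population that also avoid the current member index `d`.
#'
#' @param pop NP x R population matrix.
#' @param d index of the current member.
#' @param strategy mutation strategy tag.
#' @param F mutation scaling factor.
#' @param best index of the best member (required for strategies using it).
#' @param idx optional length-3 vector of preselected \eqn{\delta} indices.
#' @return mutant vector.
#' @export
de_mutate <- function(pop, d, strategy = "rand_1", F = 0.8, best = NULL,
                      idx = NULL) {
  NP <- nrow(pop)
  if (NP < 4) stop("population too small to draw distinct indices", call. = FALSE)
  if (is.null(idx)) {
    idx <- sample(setdiff(seq_len(NP), d), 3L)
  }
  switch(strategy,
    rand_1 = pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ]),
    current_to_best_1 = pop[idx[1L], ] + F * (pop[best, ] - pop[idx[3L], ]) +
      F * (pop[idx[2L], ] - pop[idx[3L], ]),
    best_1 = pop[best, ] + F * (pop[idx[2L], ] - pop[idx[3L], ]),
    stop("unknown strategy", call. = FALSE))
}

#' Midpoint boundary repair
#'
#' Each coordinate of the mutant that violates a bound is replaced by the
#' midpoint of the violated bound and the parent's coordinate; other
#' coordinates are untouched, so the repaired vector lies inside the box
#' whenever the parent does.
#'
#' @param m mutant vector.
#' @param parent parent vector (inside the box).
#' @param lower,upper bound vectors.
#' @return repaired vector.
#' @export
de_repair <- function(m, parent, lower, upper) {
  lo <- m < lower
  hi <- m > upper
  m[lo] <- (lower[lo] + parent[lo]) / 2
  m[hi] <- (upper[hi] + parent[hi]) / 2
  m
}

#' Binomial crossover
#'
#' Coordinate r of the trial vector is the mutant's when a U(0, 1) draw
#' \eqn{z_r} is smaller than `CR`, and the parent's otherwise.
#'
#' @param parent,mutant vectors of equal length.
#' @param CR crossover rate.
#' @param z optional vector of uniform draws (for reproducing worked cases).
#' @return trial vector.
#' @export
de_crossover <- function(parent, mutant, CR, z = NULL) {
  if (length(parent) != length(mutant)) stop("vector lengths differ", call. = FALSE)
  if (is.null(z)) z <- stats::runif(length(parent))
  ifelse(z < CR, mutant, parent)
}

#' Greedy one-to-one selection
#'
#' The trial replaces the parent only when its objective is strictly better;
#' ties and non-finite trial objectives keep the parent.
#'
#' @param parent,trial candidate vectors.
#' @param g_parent,g_trial their objective values.
#' @return list with the surviving vector (`par`) and value (`value`).
#' @export
de_select <- function(parent, trial, g_parent, g_trial) {
  if (is.finite(g_trial) && g_trial > g_parent) {
    list(par = trial, value = g_trial)
  } else {
    list(par = parent, value = g_parent)
  }
}

#' Maximize an objective by Differential Evolution
#'
#' Box-constrained, derivative-free global maximization: initialize, then loop
#' mutation, midpoint boundary repair, binomial crossover, and greedy
#' one-to-one selection until the generation cap or until the best objective
#' stalls.  The best objective along the trace is non-decreasing by
#' construction, and with a fixed RNG state the run is bit-reproducible.
#'
#' @param G objective function mapping a real vector to a scalar (maximized).
#'   May return `-Inf`; non-finite trial values never displace a parent.
#' @param lower,upper box bounds (vectors, recycled to a common length).
#' @param control a [de_control()] list.
#' @param center optional starting guess placed in the initial population.
#' @param ... further arguments passed to `G`.
#' @return list with `par` (best vector), `value` (best objective), `trace`
#'   (best objective per generation), `iterations`, `reason` (`"stall"` or
#'   `"max_iter"`), and the final `population` and `values`.
#' @examples
#' quad <- function(x) -sum((x - 2)^2)
#' fit <- de_maximize(quad, -5, 5, de_control(NP = 30, max_iter = 200))
#' fit$par
#' @export
de_maximize <- function(G, lower, upper, control = de_control(),
                        center = NULL, ...) {
  R <- max(length(lower), length(upper), length(center))
  lower <- rep_len(lower, R)
  upper <- rep_len(upper, R)
  pop <- de_init(lower, upper, control$NP, center = center)
  vals <- apply(pop, 1L, G, ...)
  vals[is.na(vals)] <- -Inf
  best <- which.max(vals)
  trace <- numeric(0)
  stalled <- 0L
  reason <- "max_iter"
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    prev_best <- vals[best]
    idx <- draw_mutation_indices(control$NP)
    Fd <- if (control$F_policy == "uniform") stats::runif(control$NP)
          else rep(control$F, control$NP)
    trials <- pop
    for (d in seq_len(control$NP)) {
      m <- de_mutate(pop, d, control$strategy, Fd[d], best = best,
                     idx = idx[d, ])
      m <- de_repair(m, pop[d, ], lower, upper)
      trials[d, ] <- de_crossover(pop[d, ], m, control$CR)
    }
    g_trials <- apply(trials, 1L, G, ...)
    improve <- !is.na(g_trials) & is.finite(g_trials) & g_trials > vals
    gen_gain <- if (any(improve)) max(g_trials[improve] - vals[improve]) else 0
    pop[improve, ] <- trials[improve, , drop = FALSE]
    vals[improve] <- g_trials[improve]
    best <- which.max(vals)
    trace <- c(trace, vals[best])
    # a stall generation: the population's objective values stayed identical
    # up to the stall tolerance
    stalled <- if (gen_gain < control$stall_tol) stalled + 1L else 0L
    if (stalled >= control$stall) {
      reason <- "stall"
      break
    }
  }
  list(par = pop[best, ], value = vals[best], trace = trace,
       iterations = iter, reason = reason, population = pop, values = vals)
}
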