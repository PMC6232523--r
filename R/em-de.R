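#' Hybrid M-step objectives
#'
#' `mstep_objective_marginal()` is the marginal log-likelihood viewed as a
#' function of the packed item-parameter vector with the class probabilities
#' `v` held fixed at their current E-step values — the objective the hybrid
#' estimator maximizes in its default-configurable `"marginal"` mode.
#' `mstep_objective_expected()` is the expected complete-data log-likelihood
#' \eqn{\ell} (identical to [m_step_objective()]), which is separable across
#' items and therefore lets the DE search run in one low-dimensional space per
#' item.
#'
#' The packing order of `par` is items ascending, and within an item the
#' canonical subset order (intercept, singletons ascending, pairs, ...).
#'
#' @param par packed parameter vector.
#' @param y N x I binary response matrix.
#' @param q Q-matrix.
#' @param v fixed class-probability vector.
#' @param counts expected counts from [expected_counts()].
#' @return scalar objective value.
#' @export
mstep_objective_marginal <- function(par, y, q, v) {
  q <- as_qmatrix(q)
  skeleton <- lcdm_start_params(q)
  if (length(par) != length(unlist(skeleton))) {
    stop("parameter vector length does not match the Q-matrix layout", call. = FALSE)
  }
  params <- unpack_params(par, skeleton)
  pi <- class_item_probability_matrix(params, q)
  marginal_log_likelihood(y, pi, v)
}

#' @rdname mstep_objective_marginal
#' @export
mstep_objective_expected <- function(par, counts, q) {
  q <- as_qmatrix(q)
  skeleton <- lcdm_start_params(q)
  if (length(par) != length(unlist(skeleton))) {
    stop("parameter vector length does not match the Q-matrix layout", call. = FALSE)
  }
  params <- unpack_params(par, skeleton)
  m_step_objective(params, counts, q = q)
}

# log sigma(x) and log(1 - sigma(x)) for clipped x, cheap and stable
lsig <- function(x) -log1p(exp(-x))

# evaluate the per-item expected complete-data objective for every candidate
# of a grouped population.  P: NP x (k*p), Xt: list of p x C design
# transposes, r: C x k expected-correct counts, n: length-C class counts.
group_objective <- function(P, Xt, r, n, k, p) {
  NP <- nrow(P)
  G <- matrix(0, NP, k)
  for (j in seq_len(k)) {
    cols <- (j - 1L) * p + seq_len(p)
    LP <- clip_logit(P[, cols, drop = FALSE] %*% Xt[[j]])
    lp <- lsig(LP)
    G[, j] <- drop(lp %*% r[, j] + (lp - LP) %*% (n - r[, j]))
  }
  G
}

# one DE generation applied to every item of a group at once.  The index
# draws and crossover masks are shared across the group's items (common
# random numbers); mutation, repair, crossover, and greedy selection follow
# the same rules as de_maximize for each item separately.
group_de_generation <- function(P, G, Xt, r, n, lo, hi, de, k, p) {
  NP <- nrow(P)
  idx <- draw_mutation_indices(NP)
  Fd <- if (de$F_policy == "uniform") stats::runif(NP) else rep(de$F, NP)
  bestvec <- unlist(lapply(seq_len(k), function(j) {
    P[which.max(G[, j]), (j - 1L) * p + seq_len(p)]
  }))
  B <- matrix(bestvec, NP, k * p, byrow = TRUE)
  P1 <- P[idx[, 1L], , drop = FALSE]
  P2 <- P[idx[, 2L], , drop = FALSE]
  P3 <- P[idx[, 3L], , drop = FALSE]
  M <- switch(de$strategy,
    rand_1 = P1 + Fd * (P2 - P3),
    current_to_best_1 = P1 + Fd * (B - P3) + Fd * (P2 - P3),
    best_1 = B + Fd * (P2 - P3))
  v1 <- M < lo
  M[v1] <- (lo + P[v1]) / 2
  v2 <- M > hi
  M[v2] <- (hi + P[v2]) / 2
  Tm <- P
  cm <- matrix(stats::runif(NP * k * p), NP) < de$CR
  Tm[cm] <- M[cm]
  for (j in seq_len(k)) {
    cols <- (j - 1L) * p + seq_len(p)
    LP <- clip_logit(Tm[, cols, drop = FALSE] %*% Xt[[j]])
    lp <- lsig(LP)
    Gt <- drop(lp %*% r[, j] + (lp - LP) %*% (n - r[, j]))
    better <- Gt > G[, j]
    if (any(better)) {
      P[better, cols] <- Tm[better, cols]
      G[better, j] <- Gt[better]
    }
  }
  list(P = P, G = G)
}

# hybrid EM / differential-evolution fit; internal, surfaced through lcdm()
fit_lcdm_emde <- function(y, q, control) {
  profiles <- attribute_profiles(ncol(q))
  designs <- lcdm_designs(q, profiles)
  I <- nrow(q)
  C <- nrow(profiles)
  de <- control$de
  lo <- -abs(control$bound)
  hi <- abs(control$bound)
  start <- if (is.null(control$start)) lcdm_start_params(q) else control$start
  start <- lapply(start, function(b) pmin(pmax(b, lo), hi))
  params <- start
  v <- rep(1 / C, C)

  sizes <- vapply(params, length, integer(1))
  groups <- split(seq_len(I), sizes)
  state <- lapply(groups, function(items) {
    p <- length(params[[items[1L]]])
    k <- length(items)
    P <- matrix(stats::runif(de$NP * k * p, lo, hi), de$NP, k * p)
    P[1L, ] <- unlist(params[items])
    list(items = items, p = p, k = k, P = P,
         Xt = lapply(items, function(i) t(designs[[i]])), G = NULL)
  })

  # persistent population for the joint marginal-objective mode
  marg_pop <- NULL
  marg_vals <- NULL
  skeleton <- lcdm_start_params(q)
  if (control$objective == "marginal") {
    R <- length(unlist(skeleton))
    marg_pop <- de_init(rep(lo, R), rep(hi, R), de$NP,
                        center = unlist(params))
  }

  trace <- numeric(0)
  obj_trace <- numeric(0)
  stalled <- 0L
  reason <- "max_iter"
  H <- NULL
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    pi <- compute_pi(params, designs)
    es <- estep_internal(y, pi, v)
    H <- es$H
    ll <- es$loglik
    trace <- c(trace, ll)
    if (iter > 1L) {
      gain <- abs(ll - trace[iter - 1L])
      stalled <- if (gain < control$stall_tol) stalled + 1L else 0L
      if (stalled >= control$stall) {
        reason <- "stall"
        break
      }
    }
    v <- update_mixing(H)
    counts <- expected_counts(y, H)

    if (control$objective == "expected") {
      for (gname in names(state)) {
        st <- state[[gname]]
        rg <- counts$r[, st$items, drop = FALSE]
        if (!control$persist) {
          st$P <- matrix(stats::runif(de$NP * st$k * st$p, lo, hi),
                         de$NP, st$k * st$p)
          st$P[1L, ] <- unlist(params[st$items])
        }
        # objectives change with the counts: re-evaluate parents each cycle
        st$G <- group_objective(st$P, st$Xt, rg, counts$n, st$k, st$p)
        for (gen in seq_len(control$gens)) {
          out <- group_de_generation(st$P, st$G, st$Xt, rg, counts$n,
                                     lo, hi, de, st$k, st$p)
          st$P <- out$P
          st$G <- out$G
        }
        for (j in seq_len(st$k)) {
          cols <- (j - 1L) * st$p + seq_len(st$p)
          params[[st$items[j]]][] <- st$P[which.max(st$G[, j]), cols]
        }
        state[[gname]] <- st
      }
      obj_trace <- c(obj_trace, m_step_objective(params, counts, designs = designs))
    } else {
      obj <- function(par) {
        pim <- compute_pi(unpack_params(par, skeleton), designs)
        marginal_log_likelihood(y, pim, v)
      }
      marg_vals <- apply(marg_pop, 1L, obj)
      best <- which.max(marg_vals)
      for (gen in seq_len(control$gens)) {
        idx <- draw_mutation_indices(de$NP)
        Fd <- if (de$F_policy == "uniform") stats::runif(de$NP) else rep(de$F, de$NP)
        trials <- marg_pop
        for (d in seq_len(de$NP)) {
          m <- de_mutate(marg_pop, d, de$strategy, Fd[d], best = best,
                         idx = idx[d, ])
          m <- de_repair(m, marg_pop[d, ], rep(lo, ncol(marg_pop)),
                         rep(hi, ncol(marg_pop)))
          trials[d, ] <- de_crossover(marg_pop[d, ], m, de$CR)
        }
        g_trials <- apply(trials, 1L, obj)
        improve <- !is.na(g_trials) & is.finite(g_trials) & g_trials > marg_vals
        marg_pop[improve, ] <- trials[improve, , drop = FALSE]
        marg_vals[improve] <- g_trials[improve]
        best <- which.max(marg_vals)
      }
      params <- unpack_params(marg_pop[best, ], skeleton)
      obj_trace <- c(obj_trace, marg_vals[best])
    }
  }

  pi <- compute_pi(params, designs)
  list(params = params, v = v, pi = pi, posterior = H,
       loglik = if (length(trace)) trace[length(trace)] else NA_real_,
       trace = trace, de_trace = obj_trace, niter = iter,
       converged = reason == "stall", reason = reason, failure = NULL,
       profiles = profiles)
}
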