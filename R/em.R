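#' E-step: posterior latent-class probabilities
#'
#' Bayes rule over the latent classes: row \eqn{p} is proportional to
#' \eqn{v_c \prod_i \pi_{ci}^{y_{pi}} (1-\pi_{ci})^{1-y_{pi}}}, normalized to
#' sum to 1.
#'
#' @param y N x I binary response matrix.
#' @param pi C x I class-by-item probability matrix.
#' @param v class-probability vector.
#' @return N x C posterior matrix with unit row sums.
#' @export
e_step <- function(y, pi, v) {
  estep_internal(as_binary_matrix(y, "response matrix"), pi, v)$H
}

# e-step returning both the posterior and the marginal log-likelihood
estep_internal <- function(y, pi, v) {
  L <- class_loglik(y, clip_prob(pi))
  A <- sweep(L, 2L, log(v), "+")
  ll <- row_log_sum_exp(A)
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    stop(sprintf(
      "posterior mass is zero for person %d across all %d classes",
      bad[1L], ncol(A)), call. = FALSE)
  }
  list(H = exp(A - ll), loglik = sum(ll))
}

#' Expected latent-class counts
#'
#' \eqn{n_c = \sum_p H_{pc}} is the expected number of persons in class
#' \eqn{c}; \eqn{r_{ci} = \sum_p y_{pi} H_{pc}} the expected number of them
#' answering item \eqn{i} correctly.
#'
#' @param y N x I binary response matrix.
#' @param h N x C posterior matrix from [e_step()].
#' @return list with `n` (length C) and `r` (C x I).
#' @export
expected_counts <- function(y, h) {
  y <- as_binary_matrix(y, "response matrix")
  if (nrow(y) != nrow(h)) stop("y and h disagree on the number of persons", call. = FALSE)
  list(n = colSums(h), r = crossprod(h, y))
}

#' M-step update of the class mixing proportions
#'
#' @param h posterior matrix.
#' @return class-probability vector `v` (column means of `h`).
#' @export
update_mixing <- function(h) colMeans(h)

#' Expected complete-data log-likelihood of the item parameters
#'
#' The M-step objective
#' \eqn{\ell = \sum_i \sum_c [r_{ci} \log \pi_{ci} + (n_c - r_{ci}) \log(1-\pi_{ci})]},
#' separable across items.
#'
#' @param params per-item parameter list.
#' @param counts expected counts from [expected_counts()].
#' @param q Q-matrix (or pass precomputed `designs`).
#' @param designs optional list of item design matrices.
#' @return scalar objective value.
#' @export
m_step_objective <- function(params, counts, q = NULL, designs = NULL) {
  if (is.null(designs)) designs <- lcdm_designs(as_qmatrix(q))
  sum(vapply(seq_along(params), function(i) {
    item_mstep_loglik(params[[i]], designs[[i]], counts$r[, i], counts$n)
  }, numeric(1)))
}

# per-item piece of the M-step objective
item_mstep_loglik <- function(beta, X, r, n) {
  eta <- clip_logit(drop(X %*% beta))
  sum(r * stats::plogis(eta, log.p = TRUE) +
        (n - r) * stats::plogis(-eta, log.p = TRUE))
}

# One guarded Newton pass for a single item.  Step-halving enforces that the
# item objective never decreases; vanishing or singular curvature raises an
# lcdm_convergence_failure condition (the failure mode of derivative-based
# M-steps this package's hybrid estimator is designed to avoid).
item_newton_step <- function(beta, X, r, n, item, iteration, monotone = FALSE) {
  eta <- clip_logit(drop(X %*% beta))
  p <- stats::plogis(eta)
  w <- n * p * (1 - p)
  g <- drop(crossprod(X, r - n * p))
  Hm <- crossprod(X, X * w)
  if (any(!is.finite(g)) || any(!is.finite(Hm)) ||
      max(abs(diag(Hm))) < 1e-10 || rcond(Hm) < 1e-12) {
    stop(convergence_failure(
      sprintf("second derivative of the M-step objective degenerated for item %d at iteration %d",
              item, iteration),
      item = item, iteration = iteration))
  }
  step <- solve(Hm, g)
  ll0 <- item_mstep_loglik(beta, X, r, n)
  new <- beta + step
  for (k in 1:30) {
    if (monotone) new[-1L][param_type(names(new)[-1L]) == "main"] <-
        pmax(new[-1L][param_type(names(new)[-1L]) == "main"], 0)
    if (item_mstep_loglik(new, X, r, n) >= ll0 - 1e-12) return(new)
    step <- step / 2
    new <- beta + step
  }
  beta
}

#' One M-step item-parameter update (quasi-Newton)
#'
#' Performs one guarded Newton ascent pass per item on the expected
#' complete-data log-likelihood (the objective is separable across items).
#' The update never decreases the objective; if the curvature of an item's
#' objective degenerates, a structured `lcdm_convergence_failure` condition
#' is signalled carrying the item index, rather than crashing.
#'
#' @inheritParams m_step_objective
#' @param iteration EM iteration number, recorded in failure conditions.
#' @param monotone if `TRUE`, main effects are clamped to be non-negative.
#' @return updated per-item parameter list.
#' @export
m_step_update <- function(params, counts, q = NULL, designs = NULL,
                          iteration = NA_integer_, monotone = FALSE) {
  if (is.null(designs)) designs <- lcdm_designs(as_qmatrix(q))
  for (i in seq_along(params)) {
    params[[i]] <- item_newton_step(params[[i]], designs[[i]], counts$r[, i],
                                    counts$n, i, iteration, monotone)
  }
  params
}

# full EM fit; internal, surfaced through lcdm()
fit_lcdm_em <- function(y, q, control) {
  profiles <- attribute_profiles(ncol(q))
  designs <- lcdm_designs(q, profiles)
  params <- if (is.null(control$start)) lcdm_start_params(q) else control$start
  C <- nrow(profiles)
  v <- rep(1 / C, C)
  trace <- numeric(0)
  converged <- FALSE
  failure <- NULL
  reason <- "max_iter"
  iter <- 0L
  H <- NULL
  for (iter in seq_len(control$max_iter)) {
    pi <- compute_pi(params, designs)
    es <- estep_internal(y, pi, v)
    H <- es$H
    ll <- es$loglik
    trace <- c(trace, ll)
    if (iter > 1L && abs(ll - trace[iter - 1L]) < control$tol) {
      converged <- TRUE
      reason <- "converged"
      break
    }
    v <- update_mixing(H)
    counts <- expected_counts(y, H)
    upd <- tryCatch(
      m_step_update(params, counts, designs = designs, iteration = iter,
                    monotone = control$monotone),
      lcdm_convergence_failure = function(e) e)
    if (inherits(upd, "lcdm_convergence_failure")) {
      failure <- list(reason = "curvature_degenerate",
                      message = conditionMessage(upd),
                      item = upd$item, iteration = upd$iteration)
      reason <- "convergence_failure"
      break
    }
    params <- upd
  }
  pi <- compute_pi(params, designs)
  list(params = params, v = v, pi = pi, posterior = H,
       loglik = if (length(trace)) trace[length(trace)] else NA_real_,
       trace = trace, niter = iter, converged = converged,
       reason = reason, failure = failure, profiles = profiles)
}
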