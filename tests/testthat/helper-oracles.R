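# independent oracles and small fixtures used across tests

# direct-product marginal log-likelihood (no log-sum-exp): the naive form
# of the mixture likelihood, used as the oracle for the stable computation
naive_marginal_loglik <- function(y, pi, v) {
  sum(vapply(seq_len(nrow(y)), function(p) {
    lik <- sum(vapply(seq_along(v), function(c) {
      v[c] * prod(pi[c, ]^y[p, ] * (1 - pi[c, ])^(1 - y[p, ]))
    }, numeric(1)))
    log(lik)
  }, numeric(1)))
}

# brute-force posterior by explicit Bayes arithmetic
naive_posterior <- function(y, pi, v) {
  t(vapply(seq_len(nrow(y)), function(p) {
    w <- vapply(seq_along(v), function(c) {
      v[c] * prod(pi[c, ]^y[p, ] * (1 - pi[c, ])^(1 - y[p, ]))
    }, numeric(1))
    w / sum(w)
  }, numeric(length(v))))
}

# the 8-point regression data of the DE worked example
ols_data <- function() {
  list(x = c(22, 14, 15, 12, 10, 26, 11, 28),
       y = c(44, 29, 30, 27, 24, 51, 25, 56))
}

# its objective: G(lambda) = -sum((y - (l1 + l2 x))^2), maximized
ols_objective <- function(lambda, data = ols_data()) {
  -sum((data$y - (lambda[1] + lambda[2] * data$x))^2)
}

# independent re-packing of a flat parameter vector into the per-item list
unpack_params_for_test <- function(vec, skeleton) {
  pos <- 0
  for (i in seq_along(skeleton)) {
    k <- length(skeleton[[i]])
    skeleton[[i]][] <- vec[pos + seq_len(k)]
    pos <- pos + k
  }
  skeleton
}

# random small binary model for property tests
random_small_model <- function(N = 8, I = 4, A = 2) {
  q <- matrix(0, I, A)
  for (i in seq_len(I)) q[i, sample(A, sample(A, 1))] <- 1
  for (a in seq_len(A)) if (sum(q[, a]) == 0) q[sample(I, 1), a] <- 1
  params <- lcdm_start_params(q, intercept = stats::rnorm(1),
                              main = stats::runif(1, 0.5, 2),
                              interaction = stats::rnorm(1, 0, 0.3))
  C <- 2^A
  v <- stats::runif(C)
  v <- v / sum(v)
  pi <- class_item_probability_matrix(params, q)
  y <- matrix(rbinom(N * I, 1, 0.5), N, I)
  list(q = q, params = params, v = v, pi = pi, y = y)
}

# degenerate dataset + start values that drive the Newton M-step into
# vanishing curvature: every person answers every item correctly and the
# starting discriminations are saturated, so the posterior collapses onto
# the all-mastery class and the other classes carry no information
degenerate_em_fixture <- function(N = 60) {
  q <- matrix(c(1, 0,
                0, 1,
                1, 1), 3, 2, byrow = TRUE)
  y <- matrix(1, N, 3)
  start <- lcdm_start_params(q, intercept = -20, main = 40, interaction = 0)
  list(y = y, q = q, start = start)
}
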