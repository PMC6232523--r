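test_that("posterior probabilities follow Bayes rule", {
  set.seed(11)
  y <- matrix(rbinom(12, 1, 0.5), 4, 3)

  # single class: certainty
  H1 <- e_step(y, matrix(0.6, 1, 3), 1)
  expect_equal(unname(H1[, 1]), rep(1, 4))

  # identical classes with uniform prior: symmetry
  H2 <- e_step(y, matrix(0.6, 4, 3, byrow = TRUE), rep(0.25, 4))
  expect_equal(unname(H2), matrix(0.25, 4, 4), tolerance = 1e-12)

  # two-class two-item hand calculation
  yh <- matrix(c(1, 0), 1, 2)
  pih <- matrix(c(0.9, 0.8,
                  0.3, 0.4), 2, 2, byrow = TRUE)
  vh <- c(0.5, 0.5)
  w1 <- 0.5 * 0.9 * 0.2
  w2 <- 0.5 * 0.3 * 0.6
  Hh <- e_step(yh, pih, vh)
  expect_equal(unname(Hh[1, ]), c(w1, w2) / (w1 + w2), tolerance = 1e-12)

  # rows always sum to one
  set.seed(12)
  for (rep in 1:10) {
    m <- random_small_model()
    H <- e_step(m$y, m$pi, m$v)
    expect_equal(unname(rowSums(H)), rep(1, nrow(m$y)), tolerance = 1e-10)
    expect_equal(unname(H), unname(naive_posterior(m$y, m$pi, m$v)),
                 tolerance = 1e-9)
  }
})

test_that("expected counts reduce to tabulation and to the double loop", {
  set.seed(13)
  y <- matrix(rbinom(20, 1, 0.5), 5, 4)

  # one-hot posteriors: hard counts
  cls <- c(1, 2, 1, 2, 2)
  H <- matrix(0, 5, 2)
  H[cbind(1:5, cls)] <- 1
  ec <- expected_counts(y, H)
  expect_equal(unname(ec$n), as.numeric(table(cls)))
  expect_equal(unname(ec$r[1, ]), colSums(y[cls == 1, , drop = FALSE]))

  # uniform posteriors: n_c = N / C
  Hu <- matrix(1 / 3, 5, 3)
  expect_equal(unname(expected_counts(y, Hu)$n), rep(5 / 3, 3))

  # random instance equals the explicit double loop
  Hr <- matrix(runif(15), 5, 3)
  Hr <- Hr / rowSums(Hr)
  ec <- expected_counts(y, Hr)
  for (c in 1:3) {
    expect_equal(ec$n[c], sum(Hr[, c]))
    for (i in 1:4) {
      expect_equal(ec$r[c, i], sum(y[, i] * Hr[, c]))
    }
  }
  expect_equal(sum(ec$n), 5, tolerance = 1e-8)
  expect_true(all(ec$r <= outer(ec$n, rep(1, 4)) + 1e-12))
})

test_that("mixing update is the posterior column mean", {
  H <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE)
  expect_equal(unname(update_mixing(H)), c(2 / 3, 1 / 3))
  Hu <- matrix(0.25, 6, 4)
  expect_equal(unname(update_mixing(Hu)), rep(0.25, 4))
  set.seed(14)
  Hr <- matrix(runif(12), 4, 3)
  Hr <- Hr / rowSums(Hr)
  expect_equal(update_mixing(Hr), colMeans(Hr))
  expect_equal(sum(update_mixing(Hr)), 1, tolerance = 1e-12)
})

test_that("M-step objective matches its closed forms", {
  q <- matrix(1, 1, 1)
  params <- lcdm_start_params(q, intercept = 0, main = 0)
  # r = n/2 with chance-level probabilities: -log(2) * sum(n) * I
  counts <- list(n = c(10, 6), r = matrix(c(5, 3), 2, 1))
  expect_equal(m_step_objective(params, counts, q),
               -log(2) * 16, tolerance = 1e-10)

  # binomial closed form for arbitrary parameters
  params2 <- lcdm_start_params(q, intercept = 0.4, main = 1.1)
  counts2 <- list(n = c(20, 0), r = matrix(c(7, 0), 2, 1))
  p <- plogis(0.4)
  expect_equal(m_step_objective(params2, counts2, q),
               7 * log(p) + 13 * log(1 - p), tolerance = 1e-10)
})

test_that("Newton M-step finds the saturated Bernoulli MLE fixed point", {
  q <- matrix(1, 1, 1)
  counts <- list(n = c(50, 50), r = matrix(c(20, 40), 2, 1))
  params <- lcdm_start_params(q)
  for (k in 1:50) params <- m_step_update(params, counts, q = q)
  expect_equal(unname(params[[1]][["0"]]), qlogis(0.4), tolerance = 1e-8)
  expect_equal(unname(params[[1]][["1"]]), qlogis(0.8) - qlogis(0.4),
               tolerance = 1e-8)
  # at the maximum the update is a fixed point
  again <- m_step_update(params, counts, q = q)
  expect_equal(unlist(again), unlist(params), tolerance = 1e-8)
})

test_that("one Newton pass never decreases the M-step objective", {
  set.seed(15)
  for (rep in 1:15) {
    A <- sample(1:2, 1)
    I <- sample(2:4, 1)
    q <- sim_q_matrix(A, I)
    C <- 2^A
    n <- runif(C, 1, 30)
    rmat <- matrix(runif(C * I), C, I) * n
    counts <- list(n = n, r = rmat)
    params <- lcdm_start_params(q, intercept = rnorm(1), main = rnorm(1),
                                interaction = rnorm(1))
    before <- m_step_objective(params, counts, q)
    after <- m_step_objective(m_step_update(params, counts, q = q), counts, q)
    expect_gte(after, before - 1e-9)
  }
})

test_that("degenerate expected counts raise a structured curvature failure", {
  # an item measuring two attributes whose single-mastery classes carry no
  # posterior mass: the main effects are unidentified, the Hessian singular
  q <- matrix(c(1, 1), 1, 2)
  counts <- list(n = c(10, 0, 0, 10), r = matrix(c(2, 0, 0, 9), 4, 1))
  params <- lcdm_start_params(q)
  cond <- tryCatch(m_step_update(params, counts, q = q, iteration = 3L),
                   lcdm_convergence_failure = function(e) e)
  expect_s3_class(cond, "lcdm_convergence_failure")
  expect_equal(cond$item, 1L)
  expect_equal(cond$iteration, 3L)
})

test_that("EM recovers a one-attribute model and ascends monotonically", {
  set.seed(16)
  q <- matrix(1, 6, 1)
  truth <- lcdm_start_params(q, intercept = -1.2, main = 2.4)
  alpha <- matrix(rbinom(2000, 1, 0.5), 2000, 1)
  y <- sim_responses(truth, q, alpha)
  fit <- lcdm(y, q, method = "em")
  expect_true(fit$converged)
  expect_lt(max(abs(unlist(fit$params) - unlist(truth))), 0.25)
  expect_true(all(diff(fit$trace) > -1e-6))

  # deterministic: same data, same result
  fit2 <- lcdm(y, q, method = "em")
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("EM surfaces mid-run curvature degeneracy as a failed fit", {
  fx <- degenerate_em_fixture()
  fit <- lcdm(fx$y, fx$q, method = "em", control = list(start = fx$start))
  expect_s3_class(fit, "lcdm")
  expect_false(fit$converged)
  expect_equal(fit$reason, "convergence_failure")
  expect_equal(fit$failure$reason, "curvature_degenerate")
  expect_true(is.numeric(fit$failure$item))
})

test_that("fit object methods are coherent", {
  set.seed(17)
  q <- sim_q_matrix(2, 6)
  att <- sim_attributes(150, 2)
  y <- sim_responses(true_item_params(q, "high"), q, att$alpha)
  fit <- lcdm(y, q, method = "em")

  expect_output(print(fit), "em estimator")
  s <- summary(fit)
  expect_s3_class(s, "summary.lcdm")
  expect_equal(nrow(s$coefficients), length(unlist(fit$params)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(attr(logLik(fit), "df"), fit$npar)

  H <- predict(fit, type = "posterior")
  expect_equal(unname(rowSums(H)), rep(1, 150), tolerance = 1e-10)
  m <- predict(fit, type = "mastery")
  expect_true(all(m >= 0 & m <= 1))
  pr <- predict(fit, type = "profile")
  expect_true(all(pr %in% c(0, 1)))

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(y))
  expect_true(all(sims[[1]] %in% c(0, 1)))

  r <- residuals(fit)
  expect_equal(dim(r), c(6, 6))
  expect_true(all(is.na(diag(r))))
})
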