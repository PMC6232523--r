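test_that("balanced Q-matrix generation honors the design rules", {
  q <- sim_q_matrix(3, 30, seed = 1)
  sizes <- rowSums(q)
  expect_equal(sum(sizes == 1), 15)
  expect_equal(sum(sizes == 2), 15)
  # each attribute appears 5 times alone and in 10 pairs
  singles <- q[sizes == 1, ]
  expect_equal(unname(colSums(singles)), rep(5, 3))
  expect_equal(unname(colSums(q[sizes == 2, ])), rep(10, 3))
  expect_true(all(colSums(q) > 0))

  # 4-5 attributes: two- and three-attribute items
  q4 <- sim_q_matrix(4, 30, seed = 2)
  expect_true(all(rowSums(q4) %in% c(2, 3)))
  q5 <- sim_q_matrix(5, 31, seed = 3)
  expect_true(all(rowSums(q5) %in% c(2, 3)))
  expect_true(all(colSums(q5) > 0))

  expect_error(sim_q_matrix(3, 2), "cannot cover")
  expect_identical(sim_q_matrix(3, 30, seed = 9), sim_q_matrix(3, 30, seed = 9))
})

test_that("attribute generation matches the threshold model", {
  att <- sim_attributes(10000, 3, seed = 4)
  # unit-diagonal positive-definite correlation matrix in the stated range
  expect_equal(diag(att$sigma), rep(1, 3))
  off <- att$sigma[upper.tri(att$sigma)]
  expect_true(all(off >= 0.7 & off <= 0.9))
  expect_gt(min(eigen(att$sigma, only.values = TRUE)$values), 0)

  # thresholding at zero gives ~50% marginal mastery
  expect_true(all(abs(colMeans(att$alpha) - 0.5) < 0.03))

  # strong latent correlation shows as strong binary agreement:
  # P(same sign) = 1/2 + asin(rho)/pi > 0.75 for rho >= 0.7
  agree12 <- mean(att$alpha[, 1] == att$alpha[, 2])
  expect_gt(agree12, 0.7)

  # independence limit: profile frequencies near uniform
  att0 <- sim_attributes(20000, 2, corr_range = c(0, 0), seed = 5)
  cls <- att0$alpha %*% c(2, 1)
  freq <- tabulate(cls + 1, 4) / 20000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("true item parameters carry the quoted quality constants", {
  q <- matrix(c(1, 0, 0,
                1, 1, 0,
                1, 1, 1), 3, 3, byrow = TRUE)
  hi <- true_item_params(q, "high")
  expect_equal(unname(hi[[1]]), c(-1.5, 2))
  expect_equal(unname(hi[[2]]), c(-1.5, 2, 2, 0.5))
  # three-attribute item: intercept, three mains, three pairwise and one
  # three-way interaction, all interactions at 0.5
  expect_equal(unname(hi[[3]]), c(-1.5, 2, 2, 2, 0.5, 0.5, 0.5, 0.5))

  lo <- true_item_params(q, "low")
  expect_equal(unname(lo[[2]]), c(-0.5, 0.2, 0.2, 0.1))
  expect_equal(unname(lo[[3]]), c(-0.5, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1))
})

test_that("response simulation draws from the item response function", {
  q <- matrix(1, 2, 1)
  sure <- lcdm_start_params(q, intercept = 50, main = 0)
  alpha <- matrix(rbinom(100, 1, 0.5), 100, 1)
  expect_true(all(sim_responses(sure, q, alpha, seed = 6) == 1))

  # empirical rates match the class-conditional probabilities
  truth <- lcdm_start_params(q, intercept = -1.5, main = 2)
  alpha_big <- matrix(rep(c(0, 1), each = 5000), ncol = 1)
  y <- sim_responses(truth, q, alpha_big, seed = 7)
  p0 <- mean(y[1:5000, 1])
  p1 <- mean(y[5001:10000, 1])
  expect_lt(abs(p0 - plogis(-1.5)), 3 * sqrt(0.25 / 5000))
  expect_lt(abs(p1 - plogis(0.5)), 3 * sqrt(0.25 / 5000))

  expect_identical(sim_responses(truth, q, alpha, seed = 8),
                   sim_responses(truth, q, alpha, seed = 8))
})

test_that("recovery metrics have their closed forms", {
  tr <- c(2, -1.5, 0.5)
  expect_equal(rbias(tr, tr), 0)
  expect_equal(rmse(tr, tr), 0)
  expect_equal(rbias(1.1 * tr, tr), 10, tolerance = 1e-10)
  expect_equal(rmse(tr + 0.1, tr), rmse(tr - 0.1, tr))
  expect_equal(rmse(tr + 0.1, tr), 10, tolerance = 1e-10)
  expect_warning(rbias(c(1, 1), c(1, 0)), "zero truth")
  expect_equal(rmse(c(1.3), c(1), scale = 1), 0.3, tolerance = 1e-10)
})

test_that("a small recovery run is reproducible and internally consistent", {
  design <- lcdm_sim_design(A = 2, I = 8, N = 120, quality = "high",
                            replications = 3, seed = 77)
  r1 <- lcdm_recovery(design, estimators = "em")
  r2 <- lcdm_recovery(design, estimators = "em")
  expect_identical(r1$estimators, r2$estimators)

  s <- r1$estimators$em
  expect_lte(s$profile_accuracy, s$attribute_accuracy)
  expect_true(s$attribute_accuracy >= 0 && s$attribute_accuracy <= 1)
  expect_true(all(s$rmse >= 0, na.rm = TRUE))
  expect_equal(s$failures, 0L)
  expect_output(print(r1), "attribute accuracy")
})

test_that("high item quality separates from low quality in recovery", {
  hi <- lcdm_recovery(lcdm_sim_design(A = 2, I = 10, N = 150, quality = "high",
                                      replications = 4, seed = 5),
                      estimators = "em")
  lo <- lcdm_recovery(lcdm_sim_design(A = 2, I = 10, N = 150, quality = "low",
                                      replications = 4, seed = 5),
                      estimators = "em")
  expect_gt(hi$estimators$em$attribute_accuracy,
            lo$estimators$em$attribute_accuracy)
  # weak items leave classification near the chance floor
  expect_lt(lo$estimators$em$attribute_accuracy, 0.7)
})
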