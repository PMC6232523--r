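test_that("the regression objective reproduces the worked-example values", {
  expect_equal(ols_objective(c(2, 1)), -2400)
  expect_equal(ols_objective(c(-3, 5)), -21672)
  expect_equal(ols_objective(c(1, 2)), -24)
  expect_equal(ols_objective(c(3.5, 1)), -2022)
  expect_equal(ols_objective(c(1, 1.8)), -116.8)
})

test_that("greedy selection keeps the better of parent and trial", {
  # trial improves: replaces the parent
  s1 <- de_select(c(2, 1), c(3.5, 1), -2400, -2022)
  expect_equal(s1$par, c(3.5, 1))
  expect_equal(s1$value, -2022)
  # trial worse: parent retained
  s3 <- de_select(c(1, 2), c(1, 1.8), -24, -116.8)
  expect_equal(s3$par, c(1, 2))
  # ties keep the parent
  st <- de_select(c(0, 0), c(1, 1), -5, -5)
  expect_equal(st$par, c(0, 0))
  # non-finite trial objective keeps the parent
  sn <- de_select(c(0, 0), c(1, 1), -5, NaN)
  expect_equal(sn$par, c(0, 0))
})

test_that("mutation follows the printed strategy arithmetic", {
  pop <- matrix(c(1, 2,
                  3, 0,
                  -1, 4,
                  2, 2), 4, 2, byrow = TRUE)
  # hand arithmetic for rand_1 with delta = (1, 2, 3), F = 0.5:
  # m = pop[1] + 0.5 * (pop[2] - pop[3]) = (1,2) + 0.5*(4,-4) = (3, 0)
  expect_equal(de_mutate(pop, 4, "rand_1", F = 0.5, idx = c(1, 2, 3)),
               c(3, 0))
  # current_to_best_1: m = pop[1] + F(best - pop[3]) + F(pop[2] - pop[3])
  best <- 2
  expect_equal(de_mutate(pop, 4, "current_to_best_1", F = 0.5, best = best,
                         idx = c(1, 2, 3)),
               pop[1, ] + 0.5 * (pop[2, ] - pop[3, ]) +
                 0.5 * (pop[2, ] - pop[3, ]))
  # best_1 with F = 0: the best member itself
  expect_equal(de_mutate(pop, 4, "best_1", F = 0, best = best,
                         idx = c(1, 3, 4)), pop[2, ])
  # identical candidates: every strategy returns that candidate
  same <- matrix(1.5, 5, 3)
  for (st in c("rand_1", "current_to_best_1", "best_1")) {
    expect_equal(de_mutate(same, 1, st, F = 0.8, best = 2, idx = c(3, 4, 5)),
                 rep(1.5, 3))
  }
})

test_that("boundary repair moves violations to the parent-bound midpoint", {
  lo <- c(-20, -20)
  hi <- c(20, 20)
  # below the floor with parent at 0: midpoint -10
  expect_equal(de_repair(c(-25, 5), c(0, 5), lo, hi), c(-10, 5))
  # above the ceiling with parent at 10: midpoint 15
  expect_equal(de_repair(c(31, 0), c(10, 0), lo, hi), c(15, 0))
  # inside the box: untouched
  expect_equal(de_repair(c(3, -7), c(0, 0), lo, hi), c(3, -7))
  # repaired vectors are always inside the box when the parent is
  set.seed(20)
  for (rep in 1:50) {
    parent <- runif(4, -20, 20)
    mutant <- runif(4, -60, 60)
    rep_v <- de_repair(mutant, parent, rep(-20, 4), rep(20, 4))
    expect_true(all(rep_v >= -20 & rep_v <= 20))
  }
})

test_that("binomial crossover takes mutant coordinates where z < CR", {
  parent <- c(2, 1)
  mutant <- c(3.5, 0.8)
  # z = (0.7, 0.4) with CR = 0.5: first from parent, second from mutant
  expect_equal(de_crossover(parent, mutant, 0.5, z = c(0.7, 0.4)),
               c(2, 0.8))
  expect_equal(de_crossover(parent, mutant, 1), mutant)
  expect_equal(de_crossover(parent, mutant, 0), parent)
  expect_error(de_crossover(c(1, 2), c(1, 2, 3), 0.5), "length")
})

test_that("population initialization respects bounds, center, and seed", {
  expect_equal(de_init(c(0, 0), c(0, 0), 5), matrix(0, 5, 2))
  set.seed(21)
  p1 <- de_init(rep(-20, 3), rep(20, 3), 1000)
  expect_true(all(p1 >= -20 & p1 <= 20))
  set.seed(21)
  expect_identical(de_init(rep(-20, 3), rep(20, 3), 1000), p1)
  set.seed(22)
  pc <- de_init(rep(-5, 2), rep(5, 2), 10, center = c(1, 2))
  expect_equal(pc[1, ], c(1, 2))
  expect_error(de_control(NP = 3), "at least 4")
})

test_that("DE reaches the closed-form optimum of the regression example", {
  d <- ols_data()
  ls_fit <- lm(y ~ x, data = d)
  expect_equal(unname(round(coef(ls_fit), 2)), c(4.98, 1.78))
  g_star <- -sum(resid(ls_fit)^2)
  expect_equal(round(g_star, 2), -7.19)

  set.seed(23)
  de <- de_maximize(ols_objective, c(-20, -20), c(20, 20))
  expect_lt(abs(de$value - g_star), 1e-3)
  expect_equal(unname(round(de$par, 2)), c(4.98, 1.78))
})

test_that("DE solves a concave quadratic and a 5-D sphere", {
  set.seed(24)
  q1 <- de_maximize(function(x) -(x - 3)^2, -10, 10,
                    de_control(NP = 50, max_iter = 500))
  expect_lt(abs(q1$par - 3), 1e-3)

  set.seed(25)
  s5 <- de_maximize(function(x) -sum(x^2), rep(-5, 5), rep(5, 5))
  expect_lt(sqrt(sum(s5$par^2)), 1e-2)
})

test_that("DE trace is monotone, bounded, and reproducible", {
  obj <- function(x) -sum((x - 1)^2)
  set.seed(26)
  fit <- de_maximize(obj, rep(-2, 3), rep(2, 3),
                     de_control(NP = 20, max_iter = 60, stall = 60))
  expect_true(all(diff(fit$trace) >= 0))
  expect_true(all(fit$population >= -2 & fit$population <= 2))
  set.seed(26)
  fit2 <- de_maximize(obj, rep(-2, 3), rep(2, 3),
                      de_control(NP = 20, max_iter = 60, stall = 60))
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$trace, fit2$trace)
})
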