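# reconstruct a raw sample with exactly the given mean, sd and n
raw_with_moments <- function(m, s, n) {
  z <- scale(stats::rnorm(n))
  as.numeric(m + s * z)
}

test_that("summary t-test reproduces the printed migration-distance contrast", {
  g1 <- group_summary(11012, 72.4, 14)
  g2 <- group_summary(8404, 76.0, 13)
  res <- t_test_from_summary(g1, g2)
  expect_equal(res$statistic, 24.9, tolerance = 0.1 / 24.9)
  expect_equal(res$df, 25)
  expect_lt(res$p_value, 0.001)
  # equal means give statistic 0, p 1
  same <- t_test_from_summary(group_summary(5, 1, 10), group_summary(5, 1, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary t-test equals the classic test on reconstructed raw data", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    m1 <- runif(1, -10, 10); m2 <- runif(1, -10, 10)
    s1 <- runif(1, 0.5, 5); s2 <- runif(1, 0.5, 5)
    x1 <- raw_with_moments(m1, s1, n1); x2 <- raw_with_moments(m2, s2, n2)
    gs1 <- group_summary(mean(x1), sd(x1) / sqrt(n1), n1)
    gs2 <- group_summary(mean(x2), sd(x2) / sqrt(n2), n2)
    pooled <- t_test_from_summary(gs1, gs2, "pooled")
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(pooled$p_value, ref$p.value, tolerance = 1e-10)
    welch <- t_test_from_summary(gs1, gs2, "welch")
    refw <- t.test(x1, x2)
    expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-8)
  }
})

test_that("Yates-corrected G-test matches the brute-force oracle on random tables", {
  expect_equal(g_test_yates(matrix(10, 2, 2))$statistic, 0)
  expect_equal(g_test_yates(matrix(10, 2, 2))$p_value, 1)
  # correction keeps adjusted counts positive even with zero cells
  g0 <- g_test_yates(matrix(c(0, 10, 10, 0), 2))
  expect_true(is.finite(g0$statistic))
  expect_error(g_test_yates(matrix(c(0, 0, 5, 5), 2)), "margin")

  set.seed(15)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    res <- g_test_yates(tab)
    expect_equal(res$statistic, g_test_oracle(tab), tolerance = 1e-10)
    expect_gte(res$statistic, 0)
    # off independence, the uncorrected statistic dominates the corrected one
    un <- g_test_yates(tab, correct = FALSE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (max(abs(tab - E)) > 0.5)
      expect_gte(un$statistic + 1e-12, res$statistic)
  }
})

test_that("the printed journey tables' G statistic matches the oracle, not 18.3", {
  # encounter counts per population: 3 of 26 vs 13 of 21 crossings
  tab <- matrix(c(3, 13, 23, 8), 2)
  res <- g_test_yates(tab)
  expect_equal(res$statistic, g_test_oracle(tab), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)
})

test_that("mixed logit reduces to plain logistic when the variance hits zero", {
  set.seed(2)
  x <- rbinom(300, 1, 0.5)
  y <- rbinom(300, 1, plogis(-0.4 + 1.1 * x))
  g <- rep(1:15, each = 20)
  fit <- fit_logistic_random_intercept(y, cbind(`(Intercept)` = 1, x = x), g)
  expect_true(fit$singular)
  ref <- glm(y ~ x, family = binomial)
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("mixed logit agrees with an adaptive-quadrature reference fit", {
  skip_if_not_installed("lme4")
  set.seed(9)
  ng <- 30; m <- 15
  u <- rnorm(ng, 0, sqrt(0.5))
  x <- rbinom(ng * m, 1, 0.5); g <- rep(1:ng, each = m)
  y <- rbinom(ng * m, 1, plogis(-0.3 - 1.5 * x + u[g]))
  fit <- fit_logistic_random_intercept(y, cbind(`(Intercept)` = 1, x = x), g)
  ref <- lme4::glmer(y ~ x + (1 | g), family = binomial, nAGQ = 25)
  expect_lt(max(abs(coef(fit) - lme4::fixef(ref))), 1e-3)
  expect_equal(fit$sigma2, as.numeric(lme4::VarCorr(ref)$g), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_lt(max(abs(fit$se - sqrt(diag(as.matrix(vcov(ref)))))), 1e-3)
  # quadrature convergence: 20 vs 50 nodes changes the log-likelihood little
  f20 <- fit_logistic_random_intercept(y, cbind(1, x), g, quad_points = 20)
  f50 <- fit_logistic_random_intercept(y, cbind(1, x), g, quad_points = 50)
  expect_lt(abs(f20$logLik - f50$logLik), 1e-6)
})

test_that("a bird-identity intercept with no between-bird signal is singular", {
  # two journeys per bird, every bird with one encounter and one miss:
  # all the outcome variation is within birds, so the bird-identity
  # variance collapses to the boundary
  set.seed(16)
  nb <- 30
  id <- rep(seq_len(nb), each = 2)
  y <- rep(c(0, 1), nb)
  x <- rbinom(2 * nb, 1, 0.5)
  fit <- fit_logistic_random_intercept(y, cbind(1, x), id)
  expect_true(fit$singular)
  expect_equal(fit$sigma2, 0)
})

test_that("complete separation is a named error", {
  x <- rep(c(0, 1), each = 20)
  y <- x
  g <- rep(1:8, 5)
  expect_error(fit_logistic_random_intercept(y, cbind(`(Intercept)` = 1,
                                                      sep_x = x), g),
               "separation")
})

test_that("AICc matches its closed form and the ranking flags ties", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_equal(aicc(-10, 0, 10), 20)                    # k = 0: AICc = AIC
  expect_equal(aicc(-10, 2, 1e9), -2 * -10 + 4, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")

  set.seed(17)
  ng <- 12; m <- 6
  u <- rnorm(ng, 0, 0.7)
  pop <- rbinom(ng * m, 1, 0.5); g <- rep(1:ng, each = m)
  y <- rbinom(ng * m, 1, plogis(-0.5 - 1.2 * pop + u[g]))
  f0 <- fit_logistic_random_intercept(y, cbind(`(Intercept)` = rep(1, length(y))), g)
  f1 <- fit_logistic_random_intercept(y, cbind(`(Intercept)` = 1,
                                               pop = pop), g)
  tab <- rank_models(list(null = f0, population = f1),
                     nested_within = c(population = "null"))
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(!is.unsorted(tab$AICc))
  expect_type(tab$uninformative_extra, "logical")
})

test_that("beta recovery is unbiased over replicated random-intercept simulations", {
  set.seed(18)
  nrep <- 200; ng <- 30; m <- 10
  beta_hat <- numeric(nrep); cover <- logical(nrep)
  for (r in seq_len(nrep)) {
    u <- rnorm(ng, 0, sqrt(0.5))
    x <- rbinom(ng * m, 1, 0.5); g <- rep(1:ng, each = m)
    y <- rbinom(ng * m, 1, plogis(0.3 - 1.5 * x + u[g]))
    f <- fit_logistic_random_intercept(y, cbind(`(Intercept)` = 1, x = x), g,
                                       quad_points = 15)
    beta_hat[r] <- coef(f)[["x"]]
    cover[r] <- abs(coef(f)[["x"]] - (-1.5)) <= 1.96 * f$se[["x"]]
  }
  expect_lt(abs(mean(beta_hat) - (-1.5)), 0.1)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})
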