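coords_grid <- function(n = 50, seed = 5) {
  set.seed(seed)
  matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("x1", "x2", "x3")))
}

test_that("projection weights live on the simplex and collapse correctly", {
  co <- coords_grid()
  pr <- projection(co, beta1 = 1, beta2 = 0.4)
  expect_equal(pr$p, co[, 1], ignore_attr = TRUE)
  pr2 <- projection(co, beta1 = 0, beta2 = 1)
  expect_equal(pr2$p, co[, 2], ignore_attr = TRUE)
  for (b1 in c(0, 0.3, 0.8, 1)) {
    for (b2 in c(0, 0.5, 1)) {
      w <- projection(co, b1, b2)$weights
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
    }
  }
  expect_error(projection(co, 1.2, 0.5), "\\[0, 1\\]")
  expect_error(projection(matrix(0.5, 4, 3), 0.5, 0.5), "degenerate")
})

test_that("p_norm spans [0,1] and preserves order", {
  co <- coords_grid()
  pr <- projection(co, 0.4, 0.7)
  expect_equal(range(pr$p_norm), c(0, 1))
  expect_identical(order(pr$p), order(pr$p_norm))
})

test_that("model means evaluate the printed predictors", {
  co <- coords_grid()
  pA <- model_params("A", lambda0 = 0)
  expect_equal(predict_mean(pA, co), rep(1, nrow(co)))

  pB <- model_params("B", lambda0 = 1, lambda1 = 0.5, lambda2 = -0.25,
                     lambda3 = 2)
  expect_equal(predict_mean(pB, co),
               exp(1 + 0.5 * co[, 1] - 0.25 * co[, 2] + 2 * co[, 3]))

  # Model C at a point with p_norm = 0.1: below tau1 -> d1 = 1, d2 = 0
  co3 <- cbind(x1 = c(0, 0.1, 1), x2 = 0.5, x3 = 0.5)
  pC <- model_params("C", lambda0 = 1, lambda1 = 0.5, lambda2 = -0.5,
                     beta1 = 1, beta2 = 0, tau1 = 0.3, tau2 = 0.7)
  mu <- predict_mean(pC, co3)
  expect_equal(mu[2], exp(1.5), tolerance = 1e-12)   # ~4.4817
  expect_equal(mu[1], exp(1.5))
  expect_equal(mu[3], exp(0.5))
})

test_that("Model D sigmoids halve exactly at the borders and step at large kappa", {
  co <- cbind(x1 = c(0, 0.35, 0.5, 0.65, 1), x2 = 0, x3 = 0)
  pD <- model_params("D", lambda0 = 1, lambda1 = 0.8, lambda2 = -0.4,
                     beta1 = 1, beta2 = 0, tau1 = 0.35, tau2 = 0.65,
                     kappa = 7)
  mu <- predict_mean(pD, co)
  s2_at_tau1 <- 1 / (1 + exp(-7 * (0.65 - 0.35)))
  expect_equal(mu[2], exp(1 + 0.8 / 2 - 0.4 * s2_at_tau1), tolerance = 1e-12)

  pD$kappa <- 1e9
  step <- predict_mean(pD, co)
  expect_equal(step[1], exp(1 + 0.8 - 0.4))   # below both borders
  expect_equal(step[3], exp(1 - 0.4))         # middle: only second sigmoid
  expect_equal(step[5], exp(1))               # above both
})

test_that("steep Model D equals the reparameterized threshold model", {
  co <- coords_grid(200, seed = 8)
  pC <- model_params("C", lambda0 = 2, lambda1 = 0.9, lambda2 = -0.6,
                     beta1 = 0.4, beta2 = 0.5, tau1 = 0.32, tau2 = 0.68,
                     alpha = 10)
  pD <- model_params("D", lambda0 = 2 + (-0.6) * -1, lambda1 = 0.9,
                     lambda2 = 0.6, beta1 = 0.4, beta2 = 0.5,
                     tau1 = 0.32, tau2 = 0.68, kappa = 1e6, alpha = 10)
  pD$lambda0 <- 2 - 0.6 * 1   # lambda0_D = lambda0_C + lambda2_C
  pD$lambda2 <- 0.6           # lambda2_D = -lambda2_C
  muC <- predict_mean(pC, co)
  muD <- predict_mean(pD, co)
  expect_equal(muD, muC, tolerance = 1e-6)
})

test_that("the NB log-density passes closed-form and normalization oracles", {
  # y = 0, mu = 1, alpha = 1 is geometric: P = 1/2
  expect_equal(nb_logpmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  # normalization by brute-force summation
  expect_equal(sum(exp(nb_logpmf(0:500, 3.7, 2.5))), 1, tolerance = 1e-10)
  # agreement with the standard parameterization
  expect_equal(nb_logpmf(0:60, 5.3, 3.1),
               dnbinom(0:60, size = 3.1, mu = 5.3, log = TRUE),
               tolerance = 1e-12)
  expect_error(nb_logpmf(c(1, NA), 1, 1), "finite")
  expect_error(nb_logpmf(1, 1, 0), "positive")
})

test_that("huge dispersion reproduces the Poisson log-pmf", {
  y <- c(0, 1, 3, 17, 50, 120)
  for (mu in c(0.4, 4.2, 30)) {
    expect_equal(nb_logpmf(y, mu, 1e12), dpois(y, mu, log = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("the NB likelihood accepts non-integer intensities", {
  g <- toy_grid(3, seed = 2)
  g$y <- g$y + 0.37
  p <- model_params("A", lambda0 = log(20), alpha = 5)
  expect_true(is.finite(nb_neg_loglik(p, g)))
})

test_that("parameter spaces carry the printed bounds and counts", {
  expect_equal(param_space("A")$k, 2)
  expect_equal(param_space("B")$k, 5)
  expect_equal(param_space("C")$k, 8)
  expect_equal(param_space("D")$k, 9)

  sB <- param_space("B")
  expect_equal(unname(sB$lower[c("lambda1", "lambda2", "lambda3")]),
               rep(-2, 3))
  expect_equal(unname(sB$upper[c("lambda1", "lambda2", "lambda3")]),
               rep(2, 3))
  sC <- param_space("C")
  expect_equal(unname(sC$lower[c("tau1", "tau2")]), c(0.2, 0.4))
  expect_equal(unname(sC$upper[c("tau1", "tau2")]), c(0.6, 0.8))
  expect_equal(unname(sC$lower["lambda1"]), -15)
  expect_equal(unname(sC$upper["lambda1"]), 200)
  expect_equal(unname(sC$upper["alpha"]), 1e20)
  sD <- param_space("D")
  expect_setequal(setdiff(sD$names, sC$names), "kappa")
  # middle subdivision must span at least 20% of the projection axis
  expect_gt(sC$constrain(c(tau1 = 0.5, tau2 = 0.6)), 0)
  expect_equal(sC$constrain(c(tau1 = 0.3, tau2 = 0.7)), 0)
})

test_that("the homogeneous optimum is feasible in every larger model", {
  g <- toy_grid(4, seed = 4)
  pA <- model_params("A", lambda0 = log(mean(g$y)), alpha = 8)
  nllA <- nb_neg_loglik(pA, g)
  for (m in c("B", "C", "D")) {
    pm <- model_params(m, lambda0 = pA$lambda0, alpha = 8)
    expect_equal(nb_neg_loglik(pm, g), nllA, tolerance = 1e-10)
  }
})
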