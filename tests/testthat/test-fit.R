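test_that("BIC and BIC weights match hand computations", {
  expect_equal(bic_score(100, 5, 1000), 200 + 5 * log(1000))
  expect_equal(bic_score(100, 5, 1000), 234.5388, tolerance = 1e-4)
  expect_equal(bic_score(50, 0, 123), 100)
  expect_gt(bic_score(100, 6, 1000), bic_score(100, 5, 1000))
  expect_error(bic_score(1, 2, 0), "positive")

  expect_equal(unname(wbic_weights(rep(10, 4))), rep(0.25, 4))
  w <- wbic_weights(c(100, 102))
  expect_equal(unname(w), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(unname(w[1]), 0.7311, tolerance = 1e-4)
  expect_equal(wbic_weights(c(100, 102) + 57.3), w, tolerance = 1e-12)
  expect_error(wbic_weights(c(Inf, Inf)), "non-finite")
})

test_that("Model A intercept is recovered within 0.05 across seeds", {
  truth <- model_params("A", lambda0 = log(20), alpha = 10)
  errs <- vapply(1:20, function(r) {
    g <- simulate_intensities(truth, grid_shape = c(10, 10, 10),
                              seed = 100 + r)
    f <- stn_fit(g, "A", control = fast_ctl(seed = 500 + r, maxiter = 200))
    abs(f$params[["lambda0"]] - log(20))
  }, 0)
  expect_lt(mean(errs), 0.02)
  expect_lt(max(errs), 0.05)
})

test_that("the fitted NB model agrees with an independent GLM fit", {
  truth <- model_params("B", lambda0 = log(30), lambda1 = 1, lambda2 = -1,
                        lambda3 = 0.5, alpha = 10)
  g <- simulate_intensities(truth, grid_shape = c(10, 10, 10), seed = 77)
  f <- stn_fit(g, "B", control = fast_ctl(seed = 78, maxiter = 300))
  ref <- MASS::glm.nb(y ~ x1 + x2 + x3, data = as.data.frame(g))
  expect_equal(unname(f$params[c("lambda0", "lambda1", "lambda2", "lambda3")]),
               unname(coef(ref)), tolerance = 0.01)
  expect_equal(f$params[["alpha"]], ref$theta, tolerance = 0.02)
  expect_equal(-f$nll, as.numeric(logLik(ref)), tolerance = 0.01)
})

test_that("nested seeding keeps the likelihood monotone over model nesting", {
  for (s in 1:3) {
    truth <- default_truth(c("A", "B", "D")[s])
    g <- simulate_intensities(truth, grid_shape = c(6, 6, 6), seed = 40 + s)
    sel <- stn_select(g, control = fast_ctl(seed = 60 + s, maxiter = 120))
    nll <- setNames(sel$table$nll, sel$table$model)
    expect_lte(nll[["B"]], nll[["A"]] + 1e-9)
    expect_lte(nll[["C"]], nll[["A"]] + 1e-9)
    expect_lte(nll[["D"]], nll[["A"]] + 1e-9)
  }
})

test_that("DE with refinement beats an exhaustive coarse grid search", {
  truth <- model_params("B", lambda0 = 2, lambda1 = 1, lambda2 = -1,
                        lambda3 = 0, alpha = 10)
  g <- simulate_intensities(truth, grid_shape = c(5, 5, 5), seed = 91)
  # oracle: all lambdas over {-2,...,2}, alpha over {1,10,100}
  lam <- c(-2, -1, 0, 1, 2)
  combos <- expand.grid(l0 = lam, l1 = lam, l2 = lam, l3 = lam,
                        a = c(1, 10, 100))
  oracle <- min(apply(combos, 1, function(v) {
    nb_neg_loglik(list(lambda0 = v[1], lambda1 = v[2], lambda2 = v[3],
                       lambda3 = v[4], alpha = v[5]), g, model_id = "B")
  }))
  f <- stn_fit(g, "B", control = fast_ctl(seed = 92, maxiter = 300))
  expect_lte(f$nll, oracle + 1e-3)
})

test_that("fit objects expose the standard modelling methods", {
  truth <- model_params("B", lambda0 = log(25), lambda1 = 1, alpha = 10)
  g <- simulate_intensities(truth, grid_shape = c(5, 5, 5), seed = 14)
  f <- stn_fit(g, "B", control = fast_ctl(seed = 15, maxiter = 150))
  expect_s3_class(f, "stn_fit")
  expect_named(coef(f), c("lambda0", "lambda1", "lambda2", "lambda3", "alpha"))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), 5)
  expect_equal(as.numeric(ll), -f$nll)
  expect_equal(f$bic, bic_score(f$nll, f$k, f$n))

  mu <- predict(f)
  expect_length(mu, f$n)
  expect_equal(predict(f, type = "link"), log(mu))
  nd <- data.frame(x1 = c(0, 1), x2 = 0.5, x3 = 0.5)
  expect_length(predict(f, nd), 2)

  r <- residuals(f)
  expect_equal(residuals(f, "response") / sqrt(mu + mu^2 / f$params[["alpha"]]),
               r, tolerance = 1e-12)
  expect_true(all(is.finite(residuals(f, "deviance"))))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(f$n, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))

  expect_output(print(f), "linear gradient")
  expect_output(print(summary(f)), "Pearson residuals")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("selection tables are coherent and degenerate grids are flagged", {
  truth <- model_params("A", lambda0 = log(20), alpha = 10)
  g <- simulate_intensities(truth, grid_shape = c(5, 5, 5), seed = 18)
  sel <- stn_select(g, control = fast_ctl(seed = 19, maxiter = 120))
  expect_equal(sum(sel$table$wbic), 1, tolerance = 1e-12)
  expect_equal(sel$preferred,
               sel$table$model[which.min(sel$table$bic)])
  expect_output(print(sel), "Preferred model")

  flat <- g
  flat$y <- rep(5, nrow(g))
  fB <- stn_fit(flat, "B", control = fast_ctl(seed = 1, maxiter = 30))
  expect_false(fB$identifiable)
  fA <- stn_fit(flat, "A", control = fast_ctl(seed = 1, maxiter = 30))
  expect_true(fA$identifiable)
})

test_that("ties prefer the simpler model", {
  bics <- c(A = 10, B = 10, D = 12)
  ks <- c(A = 2, B = 5, D = 9)
  expect_equal(stngrad:::pick_preferred(bics, ks), "A")
  expect_equal(stngrad:::pick_preferred(c(B = 5, D = 5), c(B = 5, D = 9)), "B")
})

test_that("fitting refuses grids smaller than the parameter count", {
  g <- toy_grid(2, seed = 3)   # 8 sectors
  expect_error(stn_fit(g, "D", control = fast_ctl()), "more than")
})

test_that("preference tallies and aggregation follow the definitions", {
  m <- matrix("B", 3, 4)
  expect_equal(unname(tally_preferences(m)), c(0, 100, 0, 0))
  m[1, 1] <- "C"; m[2, 2] <- "D"
  pct <- tally_preferences(m)
  expect_equal(sum(pct), 100)
  expect_equal(unname(pct["B"]), 100 * 10 / 12)
  expect_error(tally_preferences(character(0)), "empty")
  expect_error(tally_preferences(matrix("Z", 2, 2)), "unknown model label")

  tab <- data.frame(specimen = rep(c("s1", "s2"), each = 2),
                    marker = rep(c("m1", "m2"), 2),
                    preferred = c("B", "B", "D", "B"),
                    wbic_A = c(0.05, 0.1, 0.05, 0.2),
                    wbic_B = c(0.9, 0.8, 0.15, 0.6),
                    wbic_C = c(0.02, 0.05, 0.1, 0.1),
                    wbic_D = c(0.03, 0.05, 0.7, 0.1))
  ag <- aggregate_preferences(tab)
  expect_equal(ag$by_specimen$winner[ag$by_specimen$specimen == "s1"], "B")
  expect_equal(ag$overall, "B")
  single <- aggregate_preferences(tab[3, ])
  expect_equal(single$overall, "D")   # single row: winner is its preference

  tie <- tab[1:2, ]
  tie$wbic_A <- c(0.5, 0.5); tie$wbic_B <- c(0.5, 0.5)
  tie$wbic_C <- 0; tie$wbic_D <- 0
  expect_equal(aggregate_preferences(tie)$overall, "A")
})
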