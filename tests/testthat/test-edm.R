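test_that("delay embedding builds lagged-coordinate points", {
  e <- delay_embed(c(1, 2, 3, 4), E = 2, tau = 1)
  expect_equal(unname(e[, 1]), c(2, 3, 4))
  expect_equal(unname(e[, 2]), c(1, 2, 3))
  expect_equal(attr(e, "time"), 2:4)
  e1 <- delay_embed(c(5, 6, 7), E = 1)
  expect_equal(as.numeric(e1), c(5, 6, 7))
  expect_error(delay_embed(1:3, E = 4), "too short")
  expect_equal(nrow(delay_embed(rnorm(20), E = 3, tau = 2)), 20 - 2 * 2)
})

test_that("sRMSE uses the population-sd untrained-model baseline", {
  obs <- c(0, 2, 4, 1, 3)
  expect_equal(srmse(rep(mean(obs), 5), obs), 1)
  expect_equal(srmse(obs, obs), 0)
  expect_equal(srmse(c(1, 1), c(0, 2)), 1)
  expect_warning(out <- srmse(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(out))
  expect_error(srmse(1:3, 1:4), "equal length")
})

test_that("simplex projection reproduces deterministic cycles exactly", {
  per2 <- rep(c(0.2, 0.9), 12)
  res <- simplex_predict(per2, E = 2)
  expect_equal(res$rmse, 0, tolerance = 1e-12)
  expect_equal(res$srmse, 0, tolerance = 1e-12)
  const <- rep(3, 15)
  suppressWarnings(rc <- simplex_predict(const, E = 2))
  expect_equal(rc$rmse, 0)
  expect_true(is.na(rc$srmse))
})

test_that("simplex projection equals the brute-force oracle", {
  set.seed(202)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    E <- sample(1:5, 1)
    x <- as.numeric(piecewise_map(n, n %/% 2, 3.8, 3.8, seed = i)) +
      rnorm(n, 0, 0.01)
    res <- simplex_predict(x, E = E)
    ora <- brute_simplex(x, E = E)
    expect_equal(res$predicted, ora$predicted, tolerance = 1e-10)
    expect_equal(res$observed, ora$observed)
    # cross-window prediction with overlap exclusion
    y <- x + 0.1
    res2 <- simplex_predict(x, y, E = E, lib_start = 1, tgt_start = 5)
    ora2 <- brute_simplex(x, y, E = E, lib_start = 1, tgt_start = 5)
    expect_equal(res2$predicted, ora2$predicted, tolerance = 1e-10)
  }
})

test_that("sRMSE of simplex forecasts is affine invariant", {
  x <- piecewise_map(60, 30, 3.7, 3.7, seed = 4)
  base <- simplex_predict(x, E = 3)$srmse
  shifted <- simplex_predict(5 - 2 * x, E = 3)$srmse
  expect_equal(base, shifted, tolerance = 1e-10)
})

test_that("leave-one-out exclusion keeps the target out of its own library", {
  # period-2 series with one outlier at t = 21; the point at t = 20 is the
  # only one whose future is the outlier. Were it allowed as its own
  # zero-distance neighbour its prediction would be pulled toward 5; with
  # proper exclusion the other 0.6-points all predict 0.4 exactly.
  x <- c(rep(c(0.4, 0.6), 10), 5, rep(c(0.4, 0.6), 10))
  res <- simplex_predict(x, E = 1)
  i <- which(res$time == 20)
  expect_equal(res$observed[i], 5)
  expect_equal(res$predicted[i], 0.4, tolerance = 1e-12)
})

test_that("optimal embedding minimizes self-prediction error", {
  per2 <- rep(c(0.2, 0.9), 15)
  sel <- optimal_embedding(per2)
  expect_equal(min(sel$srmse, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sel$E, as.integer(names(which.min(sel$srmse))))
  # singleton grid
  expect_equal(optimal_embedding(rnorm(30), E_range = 3)$E, 3)
  # white noise: equals the brute-force argmin over the same grid
  set.seed(33)
  wn <- rnorm(40)
  sel_wn <- optimal_embedding(wn, E_range = 1:4)
  brute <- sapply(1:4, function(E) {
    p <- brute_simplex(wn, E = E)
    sqrt(mean((p$predicted - p$observed)^2)) / pop_sd_oracle(p$observed)
  })
  expect_equal(sel_wn$E, which.min(brute))
  expect_equal(unname(sel_wn$srmse), brute, tolerance = 1e-10)
})

test_that("S-map at theta 0 matches an unweighted elastic-net oracle", {
  set.seed(55)
  x <- as.numeric(arima.sim(list(ar = 0.6), 40))
  E <- 3
  fit <- regularized_smap(x, E = E, theta = 0)
  emb <- delay_embed(x, E)
  t_emb <- attr(emb, "time")
  keep <- t_emb + 1 <= length(x)
  X <- emb[keep, , drop = FALSE]; y <- x[t_emb[keep] + 1]
  ora <- vapply(seq_len(nrow(X)), function(i) {
    g <- glmnet::glmnet(X[-i, ], y[-i], alpha = 0.5, lambda = fit$lambda)
    as.numeric(predict(g, X[i, , drop = FALSE], s = fit$lambda_best))
  }, numeric(1))
  expect_equal(fit$predicted, ora, tolerance = 1e-8)
})

test_that("closed-form single-predictor elastic net matches glmnet", {
  set.seed(66)
  n <- 30
  x1 <- rnorm(n); y <- 0.8 * x1 + rnorm(n, 0, 0.3)
  wts <- runif(n, 0.5, 1.5)
  # in the vanishing-penalty limit the solution is weighted least squares
  f <- biodivedm:::enet_1d(x1, y, wts, lambda = 1e-10, alpha = 0.5)
  ls_fit <- lm(y ~ x1, weights = wts)
  expect_equal(f$b, unname(coef(ls_fit)[2]), tolerance = 1e-6)
  expect_equal(f$b0, unname(coef(ls_fit)[1]), tolerance = 1e-6)
  # heavy penalty shrinks to zero slope
  f2 <- biodivedm:::enet_1d(x1, y, wts, lambda = 100, alpha = 0.5)
  expect_equal(f2$b, 0)
})

test_that("S-map forecasts a noiseless linear system nearly perfectly", {
  x <- 2 * 0.9^(1:40) + 0.05 * sin(1:40)   # deterministic damped signal
  fit <- regularized_smap(x, E = 2, theta = 0)
  expect_lt(fit$srmse, 0.1)
})

test_that("theta selection separates linear noise from chaos", {
  expect_equal(estimate_theta(rnorm(40), E = 2, theta_grid = 0)$theta, 0)
  set.seed(42)
  th_null <- replicate(5, {
    y <- as.numeric(arima.sim(list(ar = 0.5), 48, n.start = 50))
    estimate_theta(y)$theta
  })
  expect_lt(median(th_null), 0.5)
  th_chaos <- sapply(1:5, function(i) {
    estimate_theta(piecewise_map(48, 24, 3.8, 3.8, seed = i))$theta
  })
  expect_true(mean(th_chaos > 0) > 0.5)
  expect_error(estimate_theta(rnorm(30), theta_grid = c(1, 2)), "include 0")
})
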