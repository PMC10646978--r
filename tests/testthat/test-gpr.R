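# Gaussian-process surrogates: closed-form checks, posterior behaviour, CV.

test_that("2-point posterior matches hand-rolled GP algebra", {
  X <- matrix(c(0, 1), 2, 1)
  y <- c(0.3, -0.8)
  sf2 <- 1.4; ell <- 0.7; sn2 <- 0.05
  m <- fit_gpr(X, y, hyper_strategy = "fixed",
               hyper = c(sf2 = sf2, ell = ell, sn2 = sn2))
  xq <- matrix(c(0.35, 2.2), 2, 1)
  p <- predict(m, xq)
  # independent closed form on the standardized response
  mu_y <- mean(y); sd_y <- sd(y); ys <- (y - mu_y) / sd_y
  k <- function(a, b) sf2 * exp(-0.5 * (a - b)^2 / ell^2)
  K <- matrix(c(k(0, 0) + sn2, k(0, 1), k(1, 0), k(1, 1) + sn2), 2, 2) +
    diag(m$jitter, 2)
  for (i in 1:2) {
    ks <- c(k(xq[i], 0), k(xq[i], 1))
    mu_ref <- mu_y + sd_y * drop(ks %*% solve(K, ys))
    var_ref <- sd_y^2 * (sf2 + sn2 - drop(ks %*% solve(K, ks)))
    expect_equal(p$mean[i], mu_ref, tolerance = 1e-8)
    expect_equal(p$var[i], var_ref, tolerance = 1e-6)
  }
})

test_that("near-noiseless GP interpolates its training labels", {
  X <- matrix(seq(0, 1, length.out = 5), 5, 1)
  y <- drop(X)
  m <- fit_gpr(X, y, hyper_strategy = "fixed",
               hyper = c(sf2 = 1, ell = 0.5, sn2 = 1e-10))
  p <- predict(m, X)
  expect_lt(max(abs(p$mean - y)), 1e-6)
  # posterior variance at training points below variance at a far query
  far <- predict(m, matrix(50, 1, 1))
  expect_true(all(p$var <= far$var))
})

test_that("far queries revert to the prior and chunking is irrelevant", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  m <- fit_gpr(X, y, hyper_strategy = "fixed",
               hyper = c(sf2 = 2, ell = 1, sn2 = 0.1))
  p <- predict(m, matrix(c(100, 100), 1, 2))
  expect_equal(p$mean, m$mu_y, tolerance = 1e-6)
  expect_equal(p$var, m$sd_y^2 * (2 + 0.1), tolerance = 1e-6)
  Xq <- matrix(rnorm(60), 30, 2)
  p1 <- predict(m, Xq, chunk_size = 7L)
  p2 <- predict(m, Xq, chunk_size = 1000L)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$var, p2$var, tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 1, 3)), "dimension")
})

test_that("marginal-likelihood fitting learns a 1D function reproducibly", {
  set.seed(5)
  X <- matrix(runif(40, 0, 4), 40, 1)
  y <- sin(drop(X)) + rnorm(40, 0, 0.05)
  m1 <- fit_gpr(X, y, "ml", restarts = 3, seed = 11)
  m2 <- fit_gpr(X, y, "ml", restarts = 3, seed = 11)
  expect_identical(c(m1$sf2, m1$ell, m1$sn2), c(m2$sf2, m2$ell, m2$sn2))
  p <- predict(m1, matrix(seq(0.2, 3.8, 0.3)))
  expect_lt(mean(abs(p$mean - sin(seq(0.2, 3.8, 0.3)))), 0.1)
})

test_that("adding a training point never raises posterior variance", {
  set.seed(6)
  X <- matrix(runif(16), 8, 2)
  y <- rnorm(8)
  h <- c(sf2 = 1, ell = 0.8, sn2 = 1e-8)
  m_small <- fit_gpr(X[1:7, ], y[1:7], "fixed", hyper = h)
  m_big <- fit_gpr(X, y, "fixed", hyper = h)
  Xq <- matrix(runif(40), 20, 2)
  # compare on the standardized scale to isolate the conditioning effect
  v_small <- predict(m_small, Xq)$var / m_small$sd_y^2
  v_big <- predict(m_big, Xq)$var / m_big$sd_y^2
  expect_true(all(v_big <= v_small + 1e-10))
})

test_that("suppression symmetry: fitting on -y negates means only", {
  set.seed(7)
  X <- matrix(runif(30), 15, 2)
  y <- rnorm(15)
  h <- c(sf2 = 1, ell = 0.8, sn2 = 0.05)
  mp <- fit_gpr(X, y, "fixed", hyper = h)
  mn <- fit_gpr(X, -y, "fixed", hyper = h)
  Xq <- matrix(runif(20), 10, 2)
  pp <- predict(mp, Xq); pn <- predict(mn, Xq)
  expect_equal(pp$mean, -pn$mean, tolerance = 1e-10)
  expect_equal(pp$var, pn$var, tolerance = 1e-10)
})

test_that("cv_mae behaves like the analytic MAE on pure noise and shrinks on
           learnable structure", {
  set.seed(8)
  # pure-noise labels: predicting ~the mean gives MAE ~ sigma * sqrt(2/pi)
  X <- matrix(runif(400), 200, 2)
  y <- rnorm(200, 0, 1)
  cv <- cv_mae(X, y, folds = 5, seed = 1, hyper_strategy = "median")
  expect_equal(cv$mae, sqrt(2 / pi), tolerance = 0.15)
  # learnable linear surface: near-zero error
  y2 <- 2 * X[, 1] - X[, 2]
  cv2 <- cv_mae(X, y2, folds = 5, seed = 1, hyper_strategy = "ml", restarts = 2)
  expect_lt(cv2$mae, 0.05)
  # leave-one-out fallback warns
  expect_warning(cv_mae(X[1:3, ], y[1:3], folds = 5, seed = 1,
                        hyper_strategy = "median"), "leave-one-out")
})
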