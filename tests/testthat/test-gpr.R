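# Gaussian process regression: kernel algebra, closed-form likelihoods,
# conditioning against a dense joint-Gaussian oracle, and fit behavior.

test_that("exponential kernel matches its definition and is PSD", {
  expect_equal(exponential_kernel(c(1, 2), c(1, 2), sigma_f2 = 3.5), 3.5)
  x <- c(0, 0); xp <- c(2, 0)
  expect_equal(exponential_kernel(x, xp, sigma_f2 = 1, ell = 2), exp(-1))
  expect_error(exponential_kernel(x, xp, ell = -1), "positive")
  set.seed(10)
  X <- matrix(rnorm(50 * 3), 50, 3)
  K <- exponential_kernel(X, X, sigma_f2 = 2, ell = 1.3)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("log marginal likelihood matches closed forms at n = 1", {
  # y = beta and unit total variance: standard normal density at zero
  expect_equal(gpr_log_marginal_likelihood(matrix(0), y = 2, sigma_f2 = 0.6,
                                           ell = 1, sigma2 = 0.4, beta = 2),
               -0.5 * log(2 * pi))
  y <- 1.7; beta <- 0.4; sf2 <- 0.8; s2 <- 0.3
  expect_equal(gpr_log_marginal_likelihood(matrix(1), y, sf2, 1, s2, beta),
               -0.5 * (y - beta)^2 / (sf2 + s2) - 0.5 * log(sf2 + s2) -
                 0.5 * log(2 * pi))
})

test_that("log marginal likelihood matches a dense multivariate-normal oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 6
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    sf2 <- runif(1, 0.5, 2); ell <- runif(1, 0.5, 2)
    s2 <- runif(1, 0.05, 0.5); beta <- rnorm(1)
    # oracle: explicit inverse and determinant of the full covariance
    K <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      K[i, j] <- sf2 * exp(-sqrt(sum((X[i, ] - X[j, ])^2)) / ell)
    }
    Ky <- K + s2 * diag(n)
    r <- y - beta
    oracle <- -0.5 * drop(t(r) %*% solve(Ky) %*% r) -
      0.5 * log(det(Ky)) - 0.5 * n * log(2 * pi)
    expect_equal(gpr_log_marginal_likelihood(X, y, sf2, ell, s2, beta),
                 oracle, tolerance = 1e-8)
  }
})

test_that("predictions match brute-force joint-Gaussian conditioning", {
  set.seed(123)
  for (rep in 1:5) {
    n <- 5; m <- 4; d <- 3
    X <- matrix(rnorm(n * d), n, d); Xs <- matrix(rnorm(m * d), m, d)
    y <- rnorm(n)
    sf2 <- runif(1, 0.5, 2); ell <- runif(1, 0.5, 2); s2 <- runif(1, 0.1, 0.5)
    model <- gpr_exact(X, y, sf2, ell, s2, beta = 0)
    pred <- gpr_predict(model, Xs, full_cov = TRUE)
    # oracle: partition the joint covariance and condition explicitly
    kfun <- function(a, b) sf2 * exp(-sqrt(sum((a - b)^2)) / ell)
    Knn <- outer(1:n, 1:n, Vectorize(function(i, j) kfun(X[i, ], X[j, ])))
    Kns <- outer(1:n, 1:m, Vectorize(function(i, j) kfun(X[i, ], Xs[j, ])))
    Kss <- outer(1:m, 1:m, Vectorize(function(i, j) kfun(Xs[i, ], Xs[j, ])))
    A <- solve(Knn + s2 * diag(n))
    mean_o <- drop(t(Kns) %*% A %*% y)
    cov_o <- Kss - t(Kns) %*% A %*% Kns
    expect_equal(pred$mean, mean_o, tolerance = 1e-8)
    expect_equal(pred$cov, cov_o, tolerance = 1e-8)
  }
})

test_that("noise-free GP interpolates its training points", {
  set.seed(31)
  X <- matrix(rnorm(8 * 2), 8, 2)
  y <- rnorm(8)
  model <- gpr_exact(X, y, sigma_f2 = 1.5, ell = 1, sigma2 = 0)
  pred <- gpr_predict(model, X)
  expect_equal(pred$mean, y, tolerance = 1e-6)
  expect_lt(max(pred$var), 1e-6)
})

test_that("far from the data the prediction reverts to the basis with prior variance", {
  set.seed(32)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- rnorm(10, mean = 3)
  model <- gpr_exact(X, y, sigma_f2 = 2, ell = 0.7, sigma2 = 0.1)
  far <- matrix(1e4, 1, 2)
  pred <- gpr_predict(model, far)
  expect_equal(pred$mean, model$beta, tolerance = 1e-6)
  expect_equal(pred$var, 2, tolerance = 1e-6)
})

test_that("latent predictive variance never exceeds the signal variance", {
  set.seed(55)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40)
  model <- gpr_exact(X, y, sigma_f2 = 1.2, ell = 1, sigma2 = 0.05)
  pred <- gpr_predict(model, matrix(rnorm(60 * 3), 60, 3))
  expect_lte(max(pred$var), 1.2 + 1e-8)
})

test_that("adding a training point never increases latent variance", {
  set.seed(56)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    X <- matrix(rnorm((n + 1) * 2), n + 1, 2)
    y <- rnorm(n + 1)
    Xtest <- matrix(rnorm(5 * 2), 5, 2)
    m_small <- gpr_exact(X[1:n, ], y[1:n], 1, 1, 0.1, beta = 0)
    m_big <- gpr_exact(X, y, 1, 1, 0.1, beta = 0)
    v_small <- gpr_predict(m_small, Xtest)$var
    v_big <- gpr_predict(m_big, Xtest)$var
    expect_true(all(v_big <= v_small + 1e-8))
  }
})

test_that("fitting pure noise attributes most variance to the noise term", {
  set.seed(60)
  frac <- replicate(5, {
    X <- matrix(rnorm(60 * 2), 60, 2)
    y <- rnorm(60, sd = 2)
    fit <- gpr_fit(X, y, restarts = 3, seed = 1)
    fit$sigma2 / var(y)
  })
  expect_gte(mean(frac), 0.8)
})

test_that("hyperparameters of a known GP draw are recovered to broad tolerance", {
  sf2_0 <- 1; ell_0 <- 1.5; s2_0 <- 0.1
  set.seed(61)
  dlog <- replicate(10, {
    n <- 200
    X <- matrix(rnorm(n * 2), n, 2)
    K <- exponential_kernel(X, X, sf2_0, ell_0) + s2_0 * diag(n)
    y <- drop(rnorm(n) %*% chol(K))
    fit <- gpr_fit(X, y, restarts = 3, seed = 2)
    abs(log(c(fit$sigma_f2, fit$ell, fit$sigma2)) -
          log(c(sf2_0, ell_0, s2_0)))
  })
  expect_lt(max(apply(dlog, 1, median)), 1)
})

test_that("fitting is deterministic given the seed", {
  set.seed(70)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- rnorm(50)
  f1 <- gpr_fit(X, y, restarts = 3, seed = 9)
  f2 <- gpr_fit(X, y, restarts = 3, seed = 9)
  expect_identical(f1[c("sigma_f2", "ell", "sigma2", "beta", "lml")],
                   f2[c("sigma_f2", "ell", "sigma2", "beta", "lml")])
})

test_that("95 % observation intervals are calibrated on the model's own draws", {
  set.seed(80)
  sf2 <- 1; ell <- 1; s2 <- 0.2
  n_tr <- 100; n_te <- 500
  X <- matrix(runif((n_tr + n_te) * 2, -2, 2), n_tr + n_te, 2)
  K <- exponential_kernel(X, X, sf2, ell)
  f <- drop(rnorm(n_tr + n_te) %*% chol(K + 1e-8 * diag(n_tr + n_te)))
  y <- f + rnorm(n_tr + n_te, sd = sqrt(s2))
  model <- gpr_exact(X[1:n_tr, ], y[1:n_tr], sf2, ell, s2, beta = 0)
  pred <- gpr_predict(model, X[(n_tr + 1):(n_tr + n_te), ])
  y_te <- y[(n_tr + 1):(n_tr + n_te)]
  coverage <- mean(y_te >= pred$lower & y_te <= pred$upper)
  expect_gt(coverage, 0.92)   # binomial band around 0.95 at n = 500
  expect_lt(coverage, 0.985)
})

test_that("the kernel matrix agrees with an independent Laplace-kernel implementation", {
  skip_if_not_installed("kernlab")
  set.seed(90)
  X <- matrix(rnorm(20 * 3), 20, 3)
  ell <- 1.7
  K_ours <- exponential_kernel(X, X, sigma_f2 = 1, ell = ell)
  K_ref <- kernlab::kernelMatrix(kernlab::laplacedot(sigma = 1 / ell), X)
  expect_equal(K_ours, unclass(K_ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})
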