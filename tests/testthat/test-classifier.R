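test_that("pooled covariance is the unweighted mean of class covariances", {
  set.seed(2)
  # deliberately unbalanced classes: unweighted mean != pooled estimate
  X <- rbind(matrix(rnorm(20 * 2), 20, 2),
             matrix(rnorm(8 * 2, sd = 3), 8, 2),
             matrix(rnorm(12 * 2), 12, 2) %*% matrix(c(1, .5, .5, 1), 2))
  y <- rep(c("a", "b", "c"), c(20, 8, 12))
  m <- fit_classifier(X, y, lambda = 0)
  S_oracle <- (cov(X[1:20, ]) + cov(X[21:28, ]) + cov(X[29:40, ])) / 3
  expect_equal(m$covariance, S_oracle, tolerance = 1e-12)
  expect_equal(m$means[, 1], colMeans(X[1:20, ]))
  # weights and offsets follow the discriminant formulas
  expect_equal(m$weights, solve(S_oracle, m$means))
  expect_equal(m$offsets[2],
               as.numeric(-0.5 * t(m$means[, 2]) %*%
                            solve(S_oracle, m$means[, 2])))
})

test_that("shrinkage endpoints behave as specified", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(1:3, each = 10)
  m1 <- fit_classifier(X, y, lambda = 1)
  expect_equal(m1$covariance, m1$nu * diag(4), tolerance = 1e-14)
  m0 <- fit_classifier(X, y, lambda = 0.3)
  expect_true(all(eigen(m0$covariance)$values > 0))
  expect_error(fit_classifier(X, y, lambda = 1.2), "lambda")
  expect_error(fit_classifier(X[1:11, ], rep(1:3, c(9, 1, 1))), "fewer than 2")
})

test_that("posterior matches the direct Gaussian-density Bayes oracle", {
  set.seed(7)
  for (rep in 1:25) {
    p <- sample(2:5, 1)
    K <- sample(2:4, 1)
    n <- 10 * K
    X <- matrix(rnorm(n * p), n, p) +
      matrix(rnorm(K * p, sd = 2), K, p)[rep(1:K, each = 10), ]
    y <- rep(1:K, each = 10)
    m <- fit_classifier(X, y, lambda = runif(1, 0, 0.3))
    x0 <- rnorm(p)
    dens <- sapply(1:K, function(k) {
      d <- x0 - m$means[, k]
      exp(-0.5 * as.numeric(t(d) %*% solve(m$covariance, d)))
    })
    expect_equal(as.vector(posterior(m, x0)), dens / sum(dens),
                 tolerance = 1e-10)
  }
})

test_that("posterior degenerate and stability cases", {
  set.seed(8)
  # identical class distributions -> uniform posterior
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(1:3, 20)
  m <- fit_classifier(X, y)
  m$means[] <- m$means[, 1]  # force exactly equal means
  m$weights <- solve(m$covariance, m$means)
  m$offsets <- -0.5 * colSums(m$means * m$weights)
  expect_equal(as.vector(posterior(m, rnorm(3))), rep(1 / 3, 3))
  # x at a well-separated class mean -> near-certain posterior
  mu <- matrix(c(0, 0, 10, 0, 0, 10), 2)
  Xs <- mu[, rep(1:3, each = 10)] + 0.05 * matrix(rnorm(60), 2)
  ms <- fit_classifier(t(Xs), rep(1:3, each = 10), lambda = 0.01)
  expect_gt(posterior(ms, mu[, 1])[1, 1], 0.99)
  # rows sum to one, even for extreme inputs (log-sum-exp stabilization)
  big <- posterior(ms, matrix(c(1e6, -1e6), 1))
  expect_equal(sum(big), 1)
  expect_false(anyNA(big))
  expect_error(posterior(ms, rnorm(5)), "features")
})

test_that("decoding is invariant to shared affine rescaling when lambda=0", {
  set.seed(10)
  X <- matrix(rnorm(90 * 4), 90, 4) + rep(1:3, each = 30)
  y <- rep(1:3, each = 30)
  A <- matrix(rnorm(16), 4); A <- A + t(A) + 4 * diag(4)  # invertible
  m0 <- fit_classifier(X, y, lambda = 0)
  m1 <- fit_classifier(X %*% A, y, lambda = 0)
  x0 <- rnorm(4)
  expect_equal(posterior(m0, x0), posterior(m1, x0 %*% A),
               tolerance = 1e-8)
})

test_that("tidy/glance expose the model in broom style", {
  set.seed(1)
  m <- fit_classifier(matrix(rnorm(30 * 2), 30, 2), rep(1:3, 10))
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_named(td, c("class", "feature", "mean", "weight"))
  gl <- glance(m)
  expect_equal(gl$n_classes, 3)
  expect_equal(gl$lambda, 0.05)
})
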