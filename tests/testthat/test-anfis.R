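test_that("design matrix matches hand computation and the naive oracle", {
  # single-rule zero-order: a column of ones
  one0 <- sugeno_fis(matrix(0.5, 1, 2), matrix(0.3, 1, 2),
                     matrix(0, 1, 1), "zero")
  X <- matrix(runif(10), 5, 2)
  expect_equal(design_matrix(one0, X), matrix(1, 5, 1))
  # single-rule first-order: each row is (x, 1)
  one1 <- sugeno_fis(matrix(0.5, 1, 2), matrix(0.3, 1, 2), NULL, "first")
  expect_equal(design_matrix(one1, X), cbind(X, 1), ignore_attr = TRUE)
  # random instances vs the loop oracle
  set.seed(1)
  for (trial in 1:20) {
    n <- sample(1:4, 1); L <- sample(1:4, 1); K <- sample(2:8, 1)
    order <- sample(c("zero", "first"), 1)
    fis <- random_fis(n, L, order)
    X <- matrix(runif(K * n), K, n)
    expect_equal(design_matrix(fis, X), naive_design_matrix(fis, X),
                 tolerance = 1e-12)
  }
})

test_that("least-squares consequents reach the optimum", {
  # single-rule zero-order: fitted constant is the target mean
  set.seed(2)
  one <- sugeno_fis(matrix(0.5, 1, 2), matrix(0.3, 1, 2), NULL, "zero")
  X <- matrix(runif(40), 20, 2)
  y <- rnorm(20)
  fit <- lse_consequents(one, X, y)
  expect_equal(fit$coeffs[1, 1], mean(y), tolerance = 1e-12)
  # noise-free recovery of known consequents (overdetermined, full rank)
  truth <- random_fis(2, 2, "first")
  Xr <- matrix(runif(120), 60, 2)
  yr <- fis_eval(truth, Xr)
  blank <- truth; blank$coeffs[] <- 0
  rec <- lse_consequents(blank, Xr, yr)
  expect_equal(rec$coeffs, truth$coeffs, tolerance = 1e-8)
  # all-zero targets give all-zero consequents
  z <- lse_consequents(blank, Xr, rep(0, 60))
  expect_equal(max(abs(z$coeffs)), 0, tolerance = 1e-12)
  # residual orthogonal to the design columns
  yfit <- fis_eval(rec, Xr)
  Phi <- design_matrix(rec, Xr)
  expect_lt(max(abs(t(Phi) %*% (yfit - yr))), 1e-8)
})

test_that("rank deficiency falls back to minimum norm with a warning", {
  set.seed(3)
  fis <- random_fis(3, 4, "first")   # 16 parameters
  X <- matrix(runif(15), 5, 3)       # only 5 samples
  y <- rnorm(5)
  expect_warning(fit <- lse_consequents(fis, X, y), "minimum-norm")
  # still interpolates the data
  expect_equal(fis_eval(fit, X), y, tolerance = 1e-8)
})

test_that("LSE is the global optimum over consequents", {
  set.seed(4)
  fis <- random_fis(2, 3, "zero")
  X <- matrix(runif(60), 30, 2)
  y <- rnorm(30)
  fit <- lse_consequents(fis, X, y)
  sse0 <- sum((fis_eval(fit, X) - y)^2)
  for (trial in 1:25) {
    pert <- fit
    pert$coeffs <- pert$coeffs + matrix(rnorm(3, sd = 0.05), 3, 1)
    expect_gte(sum((fis_eval(pert, X) - y)^2), sse0 - 1e-12)
  }
})

test_that("analytic premise gradients match central finite differences", {
  set.seed(5)
  h <- 1e-6
  for (trial in 1:50) {
    n <- sample(1:3, 1); L <- sample(1:4, 1); K <- 12
    order <- sample(c("zero", "first"), 1)
    fis <- random_fis(n, L, order)
    X <- matrix(runif(K * n), K, n)
    y <- rnorm(K)
    g <- premise_gradients(fis, X, y)
    sse <- function(f) sum((fis_eval(f, X) - y)^2)
    for (check in 1:3) {
      i <- sample(L, 1); j <- sample(n, 1)
      par <- sample(c("centers", "sigmas"), 1)
      fp <- fis; fm <- fis
      fp[[par]][i, j] <- fp[[par]][i, j] + h
      fm[[par]][i, j] <- fm[[par]][i, j] - h
      fd <- (sse(fp) - sse(fm)) / (2 * h)
      expect_equal(g[[par]][i, j], fd,
                   tolerance = max(1e-5, 1e-5 * abs(fd)))
    }
  }
})

test_that("gradients vanish at a perfect fit and for a single rule", {
  set.seed(6)
  fis <- random_fis(2, 3, "first")
  X <- matrix(runif(40), 20, 2)
  y <- fis_eval(fis, X)            # zero residual by construction
  g <- premise_gradients(fis, X, y)
  expect_lt(max(abs(g$centers)), 1e-10)
  expect_lt(max(abs(g$sigmas)), 1e-10)
  # one rule: normalization makes the output premise-independent
  one <- random_fis(2, 1, "first")
  g1 <- premise_gradients(one, X, rnorm(20))
  expect_lt(max(abs(g1$centers)), 1e-10)
  expect_lt(max(abs(g1$sigmas)), 1e-10)
})

test_that("hybrid training converges immediately on self-generated data", {
  set.seed(7)
  truth <- random_fis(2, 2, "first")
  X <- matrix(runif(100), 50, 2)
  y <- fis_eval(truth, X)
  init <- truth; init$coeffs[] <- 0
  rep <- hybrid_fit(init, X, y, train_config(epochs = 10))
  expect_lt(rep$errors[1], 1e-8)
  expect_true(rep$converged)
  expect_lte(length(rep$errors), 10)
})

test_that("one epoch equals an LSE solve plus one gradient step", {
  set.seed(8)
  fis <- random_fis(2, 3, "zero")
  X <- matrix(runif(60), 30, 2)
  y <- rnorm(30)
  cfg <- train_config(epochs = 1, learning_rate = 0.05)
  rep <- hybrid_fit(fis, X, y, cfg)
  manual <- lse_consequents(fis, X, y)
  g <- premise_gradients(manual, X, y)
  expect_equal(rep$fis$coeffs, manual$coeffs, tolerance = 1e-12)
  expect_equal(rep$fis$centers,
               manual$centers - 0.05 * g$centers / nrow(X),
               tolerance = 1e-12)
  expect_length(rep$errors, 1)
})

test_that("training improves the fit on a two-cluster regression", {
  set.seed(9)
  x <- c(rnorm(60, 0.25, 0.05), rnorm(60, 0.75, 0.05))
  y <- ifelse(x < 0.5, 0.2, 0.8) + rnorm(120, sd = 0.02)
  cr <- subclust(matrix(x, ncol = 1), cluster_config(ra = 0.5))
  fis0 <- build_initial_fis(cr, "zero")
  init_rmse <- sqrt(mean((fis_eval(fis0, matrix(x)) - y)^2))
  rep <- hybrid_fit(fis0, matrix(x), y, train_config(epochs = 30,
                                                     learning_rate = 0.1))
  expect_lt(tail(rep$errors, 1), init_rmse)
  expect_true(all(is.finite(rep$errors)))
})

test_that("training is deterministic under a fixed config", {
  set.seed(10)
  fis <- random_fis(2, 3, "zero")
  X <- matrix(runif(60), 30, 2)
  y <- rnorm(30)
  cfg <- train_config(epochs = 5, learning_rate = 0.05, seed = 99)
  r1 <- hybrid_fit(fis, X, y, cfg)
  r2 <- hybrid_fit(fis, X, y, cfg)
  expect_identical(r1$errors, r2$errors)
  expect_identical(r1$fis, r2$fis)
})

test_that("sigma clamping keeps widths positive", {
  set.seed(11)
  fis <- sugeno_fis(matrix(c(0.2, 0.8), 2, 1),
                    matrix(1e-3, 2, 1), NULL, "zero")
  X <- matrix(runif(50), ncol = 1)
  y <- rnorm(50)
  rep <- hybrid_fit(fis, X, y, train_config(epochs = 20, learning_rate = 1,
                                            min_sigma = 1e-3))
  expect_true(all(rep$fis$sigmas >= 1e-3 - 1e-15))
})
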