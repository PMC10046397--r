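test_that("xmax_range is the largest column range", {
  expect_equal(xmax_range(cbind(c(0, 1), c(0, 3))), 3)
  expect_equal(xmax_range(matrix(5, 3, 4)), 0)
  expect_equal(xmax_range(matrix(c(1, 2, 9), 1, 3)), 0)  # single row
  expect_error(xmax_range(matrix(numeric(0), 0, 2)), "empty")
})

test_that("the initial signal SD is the pooled sample SD of the entries", {
  expect_equal(signal_std_init(c(1, 2, 3)), 1)  # mu = 2, sum = 2, /(N-1) = 1
  expect_equal(signal_std_init(matrix(7, 4, 5)), 0)
  x <- matrix(c(0.3, -1.2, 4.5, 2.2, 0.9, -3.1), 2, 3)
  expect_equal(signal_std_init(5 * x), 5 * signal_std_init(x))
  expect_equal(signal_std_init(x), sd(as.numeric(x)))
  expect_error(signal_std_init(3.2), "at least 2")
})

test_that("the exponential kernel matches its closed form", {
  prm <- kernel_params(2.5, 1.7, 0.1)
  x <- rep(1, 10)
  expect_equal(exp_kernel(x, x, prm), 1.7^2)
  y <- x; y[1] <- 1 + 2.5  # distance exactly one kernel scale
  expect_equal(exp_kernel(x, y, prm), 1.7^2 * exp(-1))
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(exp_kernel(a, b, prm),
               1.7^2 * exp(-sqrt(sum((a - b)^2)) / 2.5))
  expect_equal(exp_kernel(a, b, prm), exp_kernel(b, a, prm))
  expect_error(exp_kernel(a, b[1:5], prm), "dimension mismatch")
  expect_error(kernel_params(-1, 1), "strictly positive")
})

test_that("fixed-kernel fits hold the shipped hyperparameters exactly", {
  set.seed(21)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- 120 + 10 * X[, 1] + rnorm(40)
  fit <- gpr_fit(X, y, init = pretrained_kernel_config(), fix_kernel = TRUE)
  expect_identical(fit$params$kernel_scale, 11.9)
  expect_identical(fit$params$signal_std, 9.6)
  expect_identical(fit$searched, "noise_std")  # no kernel search performed
  full <- gpr_fit(X, y)
  expect_setequal(full$searched,
                  c("kernel_scale", "signal_std", "noise_std"))
})

test_that("a two-point fit reproduces the explicit 2x2 solution", {
  X <- rbind(c(0, 0), c(1, 1))
  y <- c(100, 140)
  prm <- kernel_params(1.5, 8, 0.5)
  fit <- gpr_fit(X, y, init = prm, fix_kernel = TRUE, standardize = FALSE)
  p <- fit$params
  K <- outer(1:2, 1:2, Vectorize(function(i, j) exp_kernel(X[i, ], X[j, ], p)))
  diag(K) <- diag(K) + p$noise_std^2 + 1e-8 * p$signal_std^2
  for (i in 1:2) {
    ks <- c(exp_kernel(X[1, ], X[i, ], p), exp_kernel(X[2, ], X[i, ], p))
    mu <- mean(y) + sum(ks * solve(K, y - mean(y)))
    expect_equal(predict(fit, X[i, ])$mean, mu, tolerance = 1e-10)
  }
})

test_that("posterior mean and sd match a dense-inverse oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(3:10, 1)
    X <- matrix(rnorm(n * 10), n, 10)
    y <- 110 + 5 * rnorm(n)
    fit <- gpr_fit(X, y, init = kernel_params(3, 5, 1), fix_kernel = TRUE)
    for (k in 1:3) {
      xs <- rnorm(10)
      got <- predict(fit, xs)
      want <- gp_oracle(fit, xs)
      expect_equal(got$mean, want[["mean"]], tolerance = 1e-8)
      expect_equal(got$sd, want[["sd"]], tolerance = 1e-8)
    }
  }
})

test_that("predictions interpolate training data and revert to the prior", {
  set.seed(5)
  X <- matrix(rnorm(8 * 10), 8, 10)
  y <- 120 + 8 * rnorm(8)
  fit <- gpr_fit(X, y, init = kernel_params(11.9, 9.6, 1e-4),
                 fix_kernel = TRUE)
  # near-noiseless interpolation at a training point
  if (fit$params$noise_std < 0.1) {
    expect_equal(predict(fit, X[3, ])$mean, y[3], tolerance = 0.05)
  }
  # far from all training data: prior mean and full prior spread
  far <- rep(1e4, 10)
  pf <- predict(fit, far)
  expect_equal(pf$mean, mean(y), tolerance = 1e-6)
  expect_equal(pf$sd,
               sqrt(fit$params$signal_std^2 + fit$params$noise_std^2),
               tolerance = 1e-6)
  expect_true(all(predict(fit, X)$sd > 0))
})

test_that("kernel matrices are symmetric positive definite after jitter", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:30, 1)
    X <- matrix(rnorm(n * 10), n, 10)
    prm <- kernel_params(runif(1, 0.5, 20), runif(1, 1, 15), runif(1, 0.01, 2))
    K <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) exp_kernel(X[i, ], X[j, ], prm)))
    expect_equal(K, t(K))
    diag(K) <- diag(K) + prm$noise_std^2 + 1e-8 * prm$signal_std^2
    expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("fine-tuning keeps the pretrained kernel and equals a fresh fit", {
  set.seed(8)
  Xp <- matrix(rnorm(30 * 10), 30, 10)
  yp <- 115 + 6 * rnorm(30)
  pre <- gpr_fit(Xp, yp, init = pretrained_kernel_config(), fix_kernel = TRUE)

  # empty new data: the pretrained model is returned unchanged
  same <- gpr_finetune(pre, matrix(numeric(0), 0, 10), numeric(0))
  expect_identical(same, pre)

  Xn <- matrix(rnorm(20 * 10), 20, 10)
  yn <- 125 + 5 * rnorm(20)
  ft <- gpr_finetune(pre, Xn, yn)
  expect_identical(ft$params$kernel_scale, 11.9)
  expect_identical(ft$params$signal_std, 9.6)
  # pretrained model untouched
  expect_identical(pre$n_train, 30L)

  fresh <- gpr_fit(Xn, yn, init = pre$params, fix_kernel = TRUE)
  xs <- matrix(rnorm(5 * 10), 5, 10)
  expect_equal(predict(ft, xs), predict(fresh, xs), tolerance = 1e-12)
})

test_that("synthetic-cohort recovery meets the ISO criterion-1 envelope", {
  tr <- cohort_features(50, 100)  # 200 windows
  te <- cohort_features(25, 900)  # 100 windows
  expect_gte(nrow(tr$X), 195)
  init <- pretrained_kernel_config()
  ms <- gpr_fit(tr$X, tr$sbp, init = init, fix_kernel = TRUE)
  md <- gpr_fit(tr$X, tr$dbp, init = init, fix_kernel = TRUE)
  es <- predict(ms, te$X)$mean - te$sbp
  ed <- predict(md, te$X)$mean - te$dbp
  expect_lte(sqrt(mean(es^2)), 5)
  expect_lte(sqrt(mean(ed^2)), 5)
  expect_true(iso_criterion1(mean(es), sd(es)))
  expect_true(iso_criterion1(mean(ed), sd(ed)))
})

test_that("models survive a JSON round trip", {
  set.seed(12)
  X <- matrix(rnorm(15 * 10), 15, 10)
  y <- 118 + 7 * rnorm(15)
  fit <- gpr_fit(X, y, init = pretrained_kernel_config(), fix_kernel = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_gpr_model(fit, path)
  back <- read_gpr_model(path)
  xs <- matrix(rnorm(3 * 10), 3, 10)
  expect_equal(predict(back, xs), predict(fit, xs), tolerance = 1e-10)
})
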