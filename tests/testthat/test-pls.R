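test_that("noiseless linear targets are recovered exactly", {
  set.seed(21)
  X <- matrix(rnorm(200 * 6), 200, 6)
  beta <- c(2, -1, 0.5, 0, 3, -0.25)
  y <- drop(X %*% beta) + 4
  m <- fit_pls(X, y, n_components = 6)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  expect_equal(m$coefficients, beta, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a single informative feature carries the K=1 weight", {
  set.seed(22)
  X <- scale(matrix(rnorm(100 * 8), 100, 8), scale = FALSE)
  # remove in-sample correlation of the uninformative columns with column 5
  X[, -5] <- X[, -5] -
    X[, 5] %*% (crossprod(X[, 5], X[, -5]) / sum(X[, 5]^2))
  y <- 3 * X[, 5]
  m <- fit_pls(X, y, n_components = 1)
  b <- abs(m$coefficients) / max(abs(m$coefficients))
  expect_lt(max(b[-5]), 1e-6)
  expect_equal(b[5], 1)
})

test_that("degenerate inputs are rejected or rank-truncated", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_pls(X, rep(1, 20), 2), "zero variance")
  expect_error(fit_pls(X, rnorm(20), 0), "n_components")
  expect_error(fit_pls(X[1:3, ], rnorm(3), 3), "n_components")
  # rank-1 feature matrix cannot support 3 components
  Xr <- outer(rnorm(20), c(1, 2, 3))
  expect_warning(m <- fit_pls(Xr, Xr[, 1] + rnorm(20, sd = 1e-3), 3),
                 "reduced")
  expect_lt(m$n_components, 3)
})

test_that("prediction matches an independent component-wise oracle", {
  set.seed(23)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(80, sd = 0.3)
  m <- fit_pls(X, y, n_components = 4)
  Xnew <- matrix(rnorm(15 * 10), 15, 10)
  # oracle: accumulate scores component by component via deflation
  E <- sweep(Xnew, 2, m$x_mean)
  yhat <- rep(m$y_mean, 15)
  for (k in seq_len(m$n_components)) {
    t_k <- drop(E %*% m$weights[, k])
    yhat <- yhat + m$y_loadings[k] * t_k
    E <- E - outer(t_k, m$loadings[, k])
  }
  expect_equal(predict(m, Xnew), yhat, tolerance = 1e-10)

  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(predict(m, Xnew[, 1:3]), "columns")
  expect_error(predict(m, Xnew, ncomp = 9), "ncomp")
})

test_that("PLS reaches the OLS solution at full rank", {
  set.seed(24)
  X <- matrix(rnorm(120 * 7), 120, 7)
  y <- drop(X %*% rnorm(7)) + rnorm(120, sd = 0.5)
  m <- fit_pls(X, y, n_components = 7)
  # independent oracle: normal equations on centered data
  Xc <- scale(X, scale = FALSE)
  bols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  yols <- mean(y) + drop(Xc %*% bols)
  expect_equal(predict(m, X), yols, tolerance = 1e-6)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(25)
  X <- matrix(rnorm(150 * 12), 150, 12)
  y <- drop(X %*% rnorm(12)) + rnorm(150)
  m <- fit_pls(X, y, n_components = 6)
  g <- crossprod(m$scores)
  offdiag <- g[upper.tri(g)]
  expect_lt(max(abs(offdiag)) / max(diag(g)), 1e-8)
})

test_that("coefficients are scale-equivariant", {
  set.seed(26)
  X <- matrix(rnorm(90 * 5), 90, 5)
  y <- drop(X %*% c(1, 2, 0, -1, 0.5)) + rnorm(90, sd = 0.2)
  m <- fit_pls(X, y, 3)
  m_cy <- fit_pls(X, 7 * y, 3)
  expect_equal(m_cy$coefficients, 7 * m$coefficients, tolerance = 1e-8)
  # column rescaling is undone exactly once the fit reaches the OLS limit
  mf <- fit_pls(X, y, 5)
  X2 <- X
  X2[, 2] <- 5 * X2[, 2]
  m_cx <- fit_pls(X2, y, 5)
  expect_equal(m_cx$coefficients[2], mf$coefficients[2] / 5,
               tolerance = 1e-6)
})

test_that("component contributions are R-squared ratios", {
  set.seed(27)
  # orthogonal design, one informative direction: the first component is
  # exactly that direction and explains everything
  X <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6))) * 3
  y <- drop(X %*% c(3, 0, 0, 0, 0, 0))
  m1 <- fit_pls(X, y, 1)
  expect_equal(component_contribution(m1, X, y), 1.0, tolerance = 1e-10)

  yn <- y + rnorm(100, sd = 0.01)
  m2 <- fit_pls(X, yn, 2)
  cc <- component_contribution(m2, X, yn)
  expect_gt(cc[1], 0.99)
  expect_equal(cc[2], 1.0, tolerance = 1e-12)
  expect_true(all(diff(cc) >= -1e-10))
  expect_error(component_contribution(m2, X, rnorm(100) + 100), "R-squared")
})

test_that("ensemble averaging aligns signs before averaging", {
  v <- c(1, -2, 3, 0.5)
  expect_equal(ensemble_average_vectors(list(v, v, v))$average, v)
  avg <- ensemble_average_vectors(list(v, -v))$average
  expect_equal(abs(avg), abs(v))
  expect_gt(sum(avg * v)^2, 0)   # not the zero vector
  expect_error(ensemble_average_vectors(list()), "at least one")
  expect_error(ensemble_average_vectors(list(v, v[1:2])), "length")

  # averaging noisy copies beats the median individual vector
  set.seed(28)
  w <- rnorm(50)
  copies <- lapply(1:10, function(i) {
    s <- sample(c(-1, 1), 1)
    s * (w + rnorm(50, sd = 0.5))
  })
  out <- ensemble_average_vectors(copies)
  cos_i <- vapply(copies, function(v) abs(cosine(v, w)), numeric(1))
  expect_gt(abs(cosine(out$average, w)), median(cos_i))
  expect_equal(dim(out$similarity), c(10, 10))
  expect_equal(diag(out$similarity), rep(1, 10), tolerance = 1e-12)
})

test_that("scaled-down ensembles yield accurate coefficient recovery", {
  ens <- generate_force_ensemble(small_spec(seed = 1))
  X <- do.call(rbind, lapply(ens$replicas, `[[`, "X"))
  y <- unlist(lapply(ens$replicas, `[[`, "y"))
  m <- fit_pls(X, y, 1)
  expect_gt(cosine(m$coefficients, ens$true_coefficients), 0.95)
  # mean-centering must absorb the nonzero resting baselines
  expect_gt(min(m$x_mean), 0)
})

test_that("extra components dilute but do not destroy hotspot recovery", {
  # frozen behaviour on the calibrated ensemble, seed 1: the coefficient
  # cosine with the ground truth decreases as pure-noise components enter
  # (values cross-checked against an independent NIPALS implementation)
  ens <- generate_force_ensemble(synthetic_ensemble_spec(seed = 1))
  X <- do.call(rbind, lapply(ens$replicas, `[[`, "X"))
  y <- unlist(lapply(ens$replicas, `[[`, "y"))
  m <- fit_pls(X, y, 5)
  cosk <- vapply(1:5, function(k)
    cosine(m$coef_path[, k], ens$true_coefficients), numeric(1))
  expect_equal(cosk[1], 0.9878255, tolerance = 1e-6)
  expect_equal(cosk[5], 0.9301092, tolerance = 1e-6)
  expect_true(all(diff(cosk) < 0))
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(29)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(60, sd = 0.1)
  m <- fit_pls(X, y, 4)
  f <- tempfile(fileext = ".json")
  write_pls_model(m, f)
  back <- read_pls_model(f)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-10)
  expect_equal(predict(back, X, ncomp = 2), predict(m, X, ncomp = 2),
               tolerance = 1e-10)
})
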