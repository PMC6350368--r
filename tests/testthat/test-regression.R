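test_that("log-likelihood matches the naive direct formula", {
  expect_equal(logistic_loglik(c(0, 0, 0), cbind(1, runif(10), runif(10)),
                               rbinom(10, 1, 0.5)),
               -10 * log(2))
  set.seed(41)
  for (rep in 1:10) {
    n <- 25
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rbinom(n, 1, 0.5)
    w <- rnorm(3)
    eta <- as.vector(X %*% w)
    naive <- sum(y * eta - log(1 + exp(eta)))  # no softplus guard
    expect_equal(logistic_loglik(w, X, y), naive, tolerance = 1e-10)
  }
  # large-weight limit on a single positive sample approaches 0 from below
  ll <- logistic_loglik(c(30, 0, 0), cbind(1, 0, 0), 1)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-10)
})

test_that("Newton fit recovers the closed-form saturated 2x2 solution", {
  # 20 samples with x=1 (15 positive), 20 with x=0 (5 positive):
  # intercept = log(5/15) = ln(1/3), slope = log(15/5) - log(5/15) = 2 ln 3
  X <- cbind(1, rep(c(1, 0), each = 20))
  y <- c(rep(1, 15), rep(0, 5), rep(1, 5), rep(0, 15))
  fit <- fit_logistic(X, y = y, ridge = 0)
  expect_true(fit$converged)
  expect_equal(unname(fit$w[1]), log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(fit$w[2]), 2 * log(3), tolerance = 1e-6)
  # log-likelihood trace is non-decreasing across accepted steps
  expect_true(all(diff(fit$loglik_trace) >= -1e-12))
})

test_that("fit agrees with glm(binomial) as an independent oracle", {
  set.seed(51)
  n <- 400
  phi1 <- runif(n, 0, 0.8)
  phi0 <- runif(n, 0, 0.8)
  y <- rbinom(n, 1, plogis(-0.5 + 2 * phi1 - 1.5 * phi0))
  feats <- tibble::tibble(mirna = sprintf("m%d", 1:n),
                          phi1 = phi1, phi0 = phi0, label = y)
  fit <- fit_logistic(feats, ridge = 0)
  ref <- glm(y ~ phi1 + phi0, family = binomial())
  expect_equal(unname(fit$w), unname(coef(ref)), tolerance = 1e-6)
  # score equations hold at the optimum
  X <- cbind(1, phi1, phi0)
  resid <- y - predict(fit, X)
  expect_lt(max(abs(crossprod(X, resid))), fit$tol)
})

test_that("symmetric zero-feature data gives a zero intercept and P = 0.5", {
  n <- 40
  feats <- tibble::tibble(mirna = sprintf("m%d", 1:n),
                          phi1 = 0, phi0 = 0,
                          label = rep(c(0L, 1L), n / 2))
  fit <- fit_logistic(feats, ridge = 0)
  expect_equal(unname(fit$w[1]), 0, tolerance = 1e-8)
  expect_equal(predict(fit, feats), rep(0.5, n), tolerance = 1e-8)
})

test_that("prediction follows the closed logistic form and sums to one", {
  fit <- structure(list(w = c(intercept = 0, phi1 = 1, phi0 = 0),
                        tol = 1e-8),
                   class = "mda_logit")
  # w.x = ln 3 -> P = 0.75
  expect_equal(predict(fit, cbind(1, log(3), 0)), 0.75)
  expect_equal(predict(fit, cbind(1, 0, 5)), 0.5)
  p <- predict(fit, cbind(1, rnorm(10), rnorm(10)))
  expect_true(all(p > 0 & p < 1))
})

test_that("duplicated rows leave the unpenalized optimum unchanged", {
  set.seed(61)
  n <- 60
  X <- cbind(1, runif(n), runif(n))
  y <- rbinom(n, 1, plogis(X %*% c(-0.3, 1, -1)))
  f1 <- fit_logistic(X, y = y, ridge = 0)
  f2 <- fit_logistic(rbind(X, X, X), y = c(y, y, y), ridge = 0)
  expect_equal(f1$w, f2$w, tolerance = 1e-7)
})

test_that("separable data terminates finitely with a tiny ridge", {
  X <- cbind(1, c(0, 0, 0, 1, 1, 1))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(X, y = y, ridge = 1e-6)
  expect_true(all(is.finite(fit$w)))
  expect_true(fit$grad_norm < 1e-6 || !fit$converged)
})

test_that("one-class label vectors are rejected", {
  expect_error(fit_logistic(cbind(1, runif(5)), y = rep(1, 5)),
               "cannot be trained")
  expect_error(fit_logistic(cbind(1, runif(5)), y = rep(0, 5)),
               "cannot be trained")
})

test_that("tidy/glance/JSON export expose the fit", {
  set.seed(71)
  X <- cbind(1, runif(30), runif(30))
  fit <- fit_logistic(X, y = rbinom(30, 1, 0.5))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "x1", "x2"))
  gl <- glance(fit)
  expect_true(gl$converged)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$weights$intercept, unname(fit$w[1]), tolerance = 1e-12)
})
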