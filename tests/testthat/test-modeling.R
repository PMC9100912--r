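make_table <- function(n, n_pct) {
  sample_table(sprintf("T%03d", seq_len(n)), row = rep(5, n), col = seq_len(n),
               radius_px = 2, n_pct = n_pct)
}

test_that("the rank-ordered split reproduces the 69/23 partition", {
  set.seed(1)
  tb <- make_table(92, runif(92, 2.1, 3.1))
  sp <- split_samples(tb)
  expect_length(sp$modeling_ids, 69)
  expect_length(sp$validation_ids, 23)
  expect_length(intersect(sp$modeling_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$modeling_ids, sp$validation_ids), tb$tree_id)

  sp4 <- split_samples(make_table(4, c(2.2, 2.4, 2.6, 2.8)))
  expect_length(sp4$modeling_ids, 3)
  expect_length(sp4$validation_ids, 1)
  expect_error(split_samples(make_table(3, c(2.2, 2.4, 2.6))), "4 samples")
})

test_that("validation nitrogen is nested inside the modeling range", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:60, 1)
    tb <- make_table(n, runif(n, 2.0, 3.2))
    sp <- split_samples(tb)
    vm <- tb$n_pct[match(sp$modeling_ids, tb$tree_id)]
    vv <- tb$n_pct[match(sp$validation_ids, tb$tree_id)]
    expect_gte(min(vv), min(vm))
    expect_lte(max(vv), max(vm))
    expect_length(c(vm, vv), n)
  }
})

test_that("every curve family recovers its own generating coefficients", {
  cases <- list(
    list(family = "linear", cf = c(a = 449, b = 2.646),
         x = seq(-0.01, 0.01, length.out = 40),
         f = function(x) 449 * x + 2.646),
    list(family = "cubic_poly", cf = c(a3 = -625.3, a2 = 498.6, a1 = -132.4, a0 = 14.4),
         x = seq(0.1, 0.4, length.out = 40),
         f = function(x) -625.3 * x^3 + 498.6 * x^2 - 132.4 * x + 14.4),
    list(family = "exponential", cf = c(a = 2.4096, b = -0.113),
         x = seq(0, 8, length.out = 40),
         f = function(x) 2.4096 * exp(-0.113 * x)),
    list(family = "logarithmic", cf = c(a = -0.204, b = 1.6965),
         x = seq(0.5, 3, length.out = 40),
         f = function(x) -0.204 * log(x) + 1.6965),
    list(family = "rational", cf = c(a = 0.253, b = -1.933, c = 1.028),
         x = seq(0.1, 0.9, length.out = 40),
         f = function(x) 0.253 / (x^2 - 1.933 * x + 1.028))
  )
  for (cs in cases) {
    fit <- fit_curve(cs$x, cs$f(cs$x), family = cs$family)
    rel <- abs(fit$coefficients - cs$cf) / abs(cs$cf)
    tol <- if (cs$family %in% c("exponential", "rational")) 1e-4 else 1e-6
    expect_true(all(rel < tol),
                label = sprintf("%s max rel err %.2e", cs$family, max(rel)))
    expect_equal(predict(fit, cs$x), cs$f(cs$x), tolerance = 1e-3)
  }
})

test_that("the logarithmic fit evaluates to its intercept at x = 1", {
  x <- seq(0.5, 3, length.out = 30)
  fit <- fit_curve(x, -0.204 * log(x) + 1.6965, family = "logarithmic")
  expect_equal(predict(fit, 1), 1.6965, tolerance = 1e-9)
  expect_error(fit_curve(c(-1, x), c(2, -0.204 * log(x) + 1.6965),
                         family = "logarithmic"), "x > 0")
})

test_that("a rational fit with a pole inside the data range is rejected", {
  x <- seq(0.1, 0.9, length.out = 30)
  y <- 0.1 / (x^2 - x + 0.24)  # roots 0.4 and 0.6, inside the range
  expect_error(fit_curve(x, y + rnorm(30, sd = 1e-3), family = "rational"),
               "pole|converge")
})

test_that("PLSR reduces to OLS in one dimension and to MLR at full rank", {
  set.seed(9)
  n <- 30
  x <- rnorm(n)
  y <- 2.6 + 0.3 * x + rnorm(n, sd = 0.05)
  pls1 <- fit_plsr(matrix(x, ncol = 1), y, n_components = 1)
  ols <- lm(y ~ x)
  expect_equal(predict(pls1, matrix(x, ncol = 1)),
               unname(fitted(ols)), tolerance = 1e-10)

  X <- matrix(rnorm(n * 4), n, 4)
  y2 <- 2.6 + X %*% c(0.3, -0.2, 0.1, 0.05) + rnorm(n, sd = 0.05)
  plsF <- fit_plsr(X, as.numeric(y2), n_components = 4)
  # normal-equations oracle
  Xb <- cbind(1, X)
  beta <- solve(crossprod(Xb), crossprod(Xb, y2))
  expect_equal(predict(plsF, X), as.numeric(Xb %*% beta), tolerance = 1e-8)
})

test_that("a noise column orthogonal to the response does not move PLSR", {
  set.seed(10)
  n <- 40
  x <- rnorm(n)
  y <- 2.6 + 0.3 * x + rnorm(n, sd = 0.05)
  raw_noise <- rnorm(n)
  # orthogonalize against both the intercept and centred y
  noise <- residuals(lm(raw_noise ~ y))
  p1 <- predict(fit_plsr(cbind(a = x), y, 1), cbind(a = x))
  p2 <- predict(fit_plsr(cbind(a = x, z = noise), y, 1), cbind(a = x, z = noise))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("PLSR predictions are invariant to feature order", {
  set.seed(11)
  X <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2.6 + X %*% c(0.2, -0.1, 0.3) + rnorm(25, sd = 0.02)
  m1 <- fit_plsr(X, as.numeric(y), 2)
  m2 <- fit_plsr(X[, c(3, 1, 2)], as.numeric(y), 2)
  expect_equal(predict(m1, X), predict(m2, X[, c(3, 1, 2)]), tolerance = 1e-12)
  expect_error(fit_plsr(cbind(X, d = rep(1, 25)), as.numeric(y), 2), "zero-variance")
  expect_error(fit_plsr(X, as.numeric(y), 10), "n_components")
})

test_that("mixOmics agrees with the NIPALS implementation", {
  set.seed(12)
  X <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2.6 + X %*% c(0.3, -0.2, 0.1, 0, 0.05) + rnorm(30, sd = 0.05)
  ours <- fit_plsr(X, as.numeric(y), n_components = 3)
  ref <- mixOmics::pls(X, as.numeric(y), ncomp = 3, mode = "regression",
                       scale = TRUE)
  ref_pred <- predict(ref, X)$predict[, 1, 3]
  expect_equal(predict(ours, X), unname(ref_pred), tolerance = 1e-6)
})

test_that("the LM network learns an exact linear map", {
  set.seed(20)
  x <- seq(-1, 1, length.out = 50)
  y <- 2 * x + 1
  net <- fit_bpnn(cbind(x = x), y, seed = 3)
  expect_lte(net$final_train_mse, 1e-4)
  expect_lt(net$iterations, 1000)
  x_new <- seq(-0.95, 0.95, length.out = 31)
  yhat <- predict(net, cbind(x = x_new))
  em <- eval_metrics(2 * x_new + 1, yhat, r2_method = "one_minus_sse")
  expect_gte(em$r_squared, 0.999)
})

test_that("network training is reproducible and its loss non-increasing", {
  set.seed(21)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- as.numeric(2.6 + X %*% c(0.3, -0.2)) + rnorm(40, sd = 0.02)
  n1 <- fit_bpnn(X, y, seed = 7)
  n2 <- fit_bpnn(X, y, seed = 7)
  expect_identical(n1$weights, n2$weights)
  expect_true(all(diff(n1$training_log$train_mse) <= 1e-12))
  n3 <- fit_bpnn(X, y, seed = 8)
  expect_false(identical(n1$weights, n3$weights))
})

test_that("degenerate network inputs are handled explicitly", {
  X <- matrix(rnorm(20), 20, 1)
  net <- fit_bpnn(X, rep(2.622, 20), seed = 1)
  expect_equal(predict(net, X), rep(2.622, 20), tolerance = 1e-6)
  expect_error(fit_bpnn(cbind(X, k = rep(1, 20)), rnorm(20, 2.6), seed = 1),
               "degenerate")
  expect_error(fit_bpnn(X[1:5, , drop = FALSE], rnorm(5, 2.6), seed = 1),
               "10 samples")
})
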