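# Model fitting: rank-ordered equidistant sample split, five univariate
# curve families, NIPALS partial least squares regression, and a single-
# hidden-layer network trained by Levenberg-Marquardt.

#' Rank-ordered equidistant sample split
#'
#' Sorts samples by nitrogen concentration (ties broken by `tree_id`) and
#' assigns every `pattern`-th rank to the validation set; the remainder is
#' the modeling set. The default `pattern = 4` sends ranks 4, 8, 12, ... to
#' validation, which at n = 92 gives the 69/23 modeling/validation partition;
#' `pattern = 3` gives a strict 2:1 split. The extremes anchor the modeling
#' set, as is standard for rank-based calibration splits: rank 1 never falls
#' on the validation cycle, and when the top rank does, it swaps with its
#' neighbour so the validation nitrogen range is always nested inside the
#' modeling range (the reference data show the same nesting).
#'
#' @param table a [sample_table()] with at least 4 rows.
#' @param pattern cycle length; every `pattern`-th rank is validation.
#' @return a `cnc_split`: list with `modeling_ids`, `validation_ids`.
#' @export
split_samples <- function(table, pattern = 4) {
  stopifnot(inherits(table, "sample_table"))
  n <- nrow(table)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  if (pattern < 2) stop("pattern must be >= 2", call. = FALSE)
  ord <- order(table$n_pct, table$tree_id)
  ranks <- seq_len(n)
  is_val <- ranks %% pattern == 0
  if (is_val[n]) {  # keep the maximum in the modeling set
    is_val[n] <- FALSE
    is_val[n - 1] <- TRUE
  }
  val <- ord[is_val]
  mod <- ord[!is_val]
  structure(list(modeling_ids = table$tree_id[mod],
                 validation_ids = table$tree_id[val]),
            class = "cnc_split")
}

# ---- univariate curve families ---------------------------------------------

.curve_families <- c("linear", "cubic_poly", "exponential", "logarithmic", "rational")

#' Fit a univariate curve model
#'
#' Five families of y-on-x regressions:
#' \itemize{
#'   \item `linear`: y = a x + b (closed form)
#'   \item `cubic_poly`: y = a3 x^3 + a2 x^2 + a1 x + a0 (closed form)
#'   \item `logarithmic`: y = a ln(x) + b (closed form; requires x > 0)
#'   \item `exponential`: y = a exp(b x) (nonlinear LS, log-linear start)
#'   \item `rational`: y = a / (x^2 + b x + c) (nonlinear LS, inverse-y
#'     quadratic start; the fitted denominator must have no real root inside
#'     the observed x range, so predictions have no pole)
#' }
#'
#' @param x predictor (a spectral feature).
#' @param y response, % N.
#' @param family one of the five family names.
#' @return a `cnc_curve_fit` with coefficients, modeling R2 (regression sum
#'   of squares over total) and RMSE.
#' @export
fit_curve <- function(x, y, family = .curve_families) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n_coef <- switch(family, linear = 2, cubic_poly = 4, exponential = 2,
                   logarithmic = 2, rational = 3)
  if (length(x) < n_coef + 1) stop("too few samples for family ", family, call. = FALSE)

  coefs <- switch(family,
    linear = {
      fit <- stats::lm(y ~ x)
      c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
    },
    cubic_poly = {
      fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
      cf <- unname(stats::coef(fit))
      c(a3 = cf[4], a2 = cf[3], a1 = cf[2], a0 = cf[1])
    },
    logarithmic = {
      if (any(x <= 0)) stop("logarithmic family requires x > 0", call. = FALSE)
      fit <- stats::lm(y ~ log(x))
      c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
    },
    exponential = {
      if (any(y <= 0)) stop("exponential family requires y > 0 for the log-linear start",
                            call. = FALSE)
      lin <- stats::lm(log(y) ~ x)
      start <- list(a = exp(unname(stats::coef(lin)[1])), b = unname(stats::coef(lin)[2]))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) stop("exponential fit did not converge: ",
                                 conditionMessage(e), call. = FALSE))
      cf <- stats::coef(fit); c(a = unname(cf["a"]), b = unname(cf["b"]))
    },
    rational = {
      if (any(abs(y) < 1e-12)) stop("rational family requires nonzero y", call. = FALSE)
      lin <- stats::lm(I(1 / y) ~ x + I(x^2))
      k <- unname(stats::coef(lin))      # 1/y = c/a + (b/a) x + (1/a) x^2
      if (abs(k[3]) < 1e-12) stop("singular start for rational family", call. = FALSE)
      a0 <- 1 / k[3]
      start <- list(a = a0, b = k[2] * a0, cc = k[1] * a0)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a / (x^2 + b * x + cc), start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) stop("rational fit did not converge: ",
                                 conditionMessage(e), call. = FALSE))
      cf <- stats::coef(fit)
      disc <- cf[["b"]]^2 - 4 * cf[["cc"]]
      if (disc >= 0) {
        roots <- (-cf[["b"]] + c(-1, 1) * sqrt(disc)) / 2
        if (any(roots >= min(x) & roots <= max(x))) {
          stop("rational fit has a pole inside the observed x range", call. = FALSE)
        }
      }
      c(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]])
    })
  if (any(!is.finite(coefs))) stop("non-finite coefficients in ", family, " fit", call. = FALSE)

  model <- structure(list(family = family, coefficients = coefs),
                     class = "cnc_curve_fit")
  yhat <- predict(model, x)
  em <- eval_metrics(y, yhat)
  model$r_squared <- em$r_squared
  model$rmse <- em$rmse
  model
}

#' Predict from a univariate curve fit
#' @param object a `cnc_curve_fit`.
#' @param newdata numeric vector (or 1-column matrix) of feature values.
#' @param ... unused.
#' @return predicted % N.
#' @export
predict.cnc_curve_fit <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata[, 1] else as.numeric(newdata)
  cf <- object$coefficients
  switch(object$family,
         linear = cf[["a"]] * x + cf[["b"]],
         cubic_poly = cf[["a3"]] * x^3 + cf[["a2"]] * x^2 + cf[["a1"]] * x + cf[["a0"]],
         logarithmic = cf[["a"]] * log(x) + cf[["b"]],
         exponential = cf[["a"]] * exp(cf[["b"]] * x),
         rational = cf[["a"]] / (x^2 + cf[["b"]] * x + cf[["c"]]))
}

# ---- partial least squares regression --------------------------------------

#' Fit PLSR by NIPALS
#'
#' Deterministic NIPALS extraction on centred, unit-variance-scaled
#' predictors and a centred response; prediction is the rebuilt linear map.
#' With one component on a single feature this reduces to ordinary least
#' squares; with as many components as the predictor rank it equals multiple
#' linear regression.
#'
#' @param X numeric matrix `[samples x features]` with positive column
#'   variances.
#' @param y response, % N.
#' @param n_components number of latent components,
#'   `<= min(samples - 1, features)`.
#' @return a `cnc_plsr` model.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("n_components must lie in [1, min(samples - 1, features)]", call. = FALSE)
  }
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd < 1e-12)) {
    stop("zero-variance feature column(s): ",
         paste(colnames(X)[x_sd < 1e-12], collapse = ", "), call. = FALSE)
  }
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Xr <- Xc; yr <- yc
  for (h in seq_len(n_components)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("residual X carries no covariance with y at component ", h,
                         call. = FALSE)
    w <- w / nw
    t_scores <- Xr %*% w
    tt <- sum(t_scores^2)
    p_load <- crossprod(Xr, t_scores) / tt
    q <- sum(yr * t_scores) / tt
    Xr <- Xr - tcrossprod(t_scores, p_load)
    yr <- yr - t_scores * q
    W[, h] <- w; P[, h] <- p_load; Q[h] <- q
  }
  # regression vector on the scaled predictors
  B <- W %*% solve(crossprod(P, W), Q)
  structure(list(n_components = n_components, x_weights = W, x_loadings = P,
                 y_loadings = Q, coef_scaled = as.numeric(B),
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 feature_names = colnames(X)),
            class = "cnc_plsr")
}

#' Predict from a PLSR model
#' @param object a `cnc_plsr`.
#' @param newdata matrix `[samples x features]` in the training column order.
#' @param ... unused.
#' @return predicted % N.
#' @export
predict.cnc_plsr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, "/")
  as.numeric(Xs %*% object$coef_scaled) + object$y_mean
}

# ---- Levenberg-Marquardt network -------------------------------------------

# forward pass; w is the flat parameter vector
.bpnn_unpack <- function(w, p, hidden) {
  n1 <- (p + 1) * hidden
  list(W1 = matrix(w[seq_len(n1)], p + 1, hidden),
       w2 = w[(n1 + 1):(n1 + hidden + 1)])
}

.bpnn_forward <- function(Xb, w, p, hidden) {
  pars <- .bpnn_unpack(w, p, hidden)
  Z <- tanh(Xb %*% pars$W1)
  list(yhat = as.numeric(cbind(Z, 1) %*% pars$w2), Z = Z)
}

# Jacobian of predictions wrt the flat parameter vector (analytic)
.bpnn_jacobian <- function(Xb, w, p, hidden) {
  pars <- .bpnn_unpack(w, p, hidden)
  Z <- tanh(Xb %*% pars$W1)
  n <- nrow(Xb)
  dZ <- (1 - Z^2) * matrix(pars$w2[seq_len(hidden)], n, hidden, byrow = TRUE)
  J1 <- matrix(0, n, (p + 1) * hidden)
  for (k in seq_len(hidden)) {
    J1[, ((k - 1) * (p + 1) + 1):(k * (p + 1))] <- Xb * dZ[, k]
  }
  cbind(J1, Z, 1)
}

#' Fit a single-hidden-layer network by Levenberg-Marquardt
#'
#' Architecture `[features, hidden, 1]` with tanh hidden units and a linear
#' output. Inputs and the target are min-max scaled to `[-1, 1]` (matching
#' the tanh range); training minimizes full-batch squared error with
#' Levenberg-Marquardt updates on the analytic Jacobian, damping multiplied
#' by 10 on a rejected step and divided by 10 on an accepted one. A random
#' internal validation fraction is held out and the weights with the best
#' validation error are retained. The seed fully determines initial weights,
#' the validation split, and hence the fitted model.
#'
#' @param X numeric matrix `[samples x features]`; no constant columns.
#' @param y response, % N.
#' @param hidden hidden units (default 4).
#' @param max_iter maximum accepted iterations (default 1000).
#' @param damping_init initial LM damping (default 0.001).
#' @param target_mse stop when training MSE on the scaled target falls below
#'   this (default 1e-4).
#' @param val_fraction internal validation fraction for best-weight
#'   retention (default 0.15).
#' @param seed integer seed.
#' @return a `cnc_bpnn` model with a training log.
#' @export
fit_bpnn <- function(X, y, hidden = 4, max_iter = 1000, damping_init = 0.001,
                     target_mse = 1e-4, val_fraction = 0.15, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < 10) stop("need at least 10 samples to train the network", call. = FALSE)
  x_min <- apply(X, 2, min); x_max <- apply(X, 2, max)
  if (any(x_max - x_min < 1e-12)) {
    stop("degenerate scaling: constant feature column(s)", call. = FALSE)
  }
  y_min <- min(y); y_max <- max(y)
  scale01 <- function(v, lo, hi) 2 * (v - lo) / (hi - lo) - 1
  Xs <- sweep(sweep(X, 2, x_min), 2, x_max - x_min, "/") * 2 - 1
  if ((y_max - y_min) < 1e-12) {
    # degenerate target: the network would just learn the constant
    return(structure(list(layer_sizes = c(p, hidden, 1), weights = NULL,
                          constant = mean(y), x_min = x_min, x_max = x_max,
                          y_min = y_min, y_max = y_max,
                          feature_names = colnames(X), training_log = NULL,
                          iterations = 0L, final_train_mse = 0,
                          seed = as.integer(seed)),
                     class = "cnc_bpnn"))
  }
  ys <- scale01(y, y_min, y_max)

  model <- with_seed(seed, {
    n_val <- max(0L, floor(n * val_fraction))
    val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xb_tr <- cbind(Xs[tr_idx, , drop = FALSE], 1)
    y_tr <- ys[tr_idx]
    Xb_val <- cbind(Xs[val_idx, , drop = FALSE], 1)
    y_val <- ys[val_idx]
    has_val <- length(val_idx) > 0

    nw <- (p + 1) * hidden + hidden + 1
    w <- stats::runif(nw, -0.5, 0.5)
    mu <- damping_init
    sse <- sum((.bpnn_forward(Xb_tr, w, p, hidden)$yhat - y_tr)^2)
    best_w <- w
    best_val <- if (has_val) sum((.bpnn_forward(Xb_val, w, p, hidden)$yhat - y_val)^2) else sse
    log_rows <- list()
    iter <- 0L
    while (iter < max_iter) {
      if (sse / length(y_tr) <= target_mse) break
      r <- .bpnn_forward(Xb_tr, w, p, hidden)$yhat - y_tr
      J <- .bpnn_jacobian(Xb_tr, w, p, hidden)
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      accepted <- FALSE
      while (!accepted && mu < 1e10) {
        delta <- tryCatch(solve(JtJ + mu * diag(nw), -g), error = function(e) NULL)
        if (!is.null(delta)) {
          w_new <- w + as.numeric(delta)
          sse_new <- sum((.bpnn_forward(Xb_tr, w_new, p, hidden)$yhat - y_tr)^2)
          if (is.finite(sse_new) && sse_new < sse) {
            w <- w_new; sse <- sse_new
            mu <- mu / 10
            accepted <- TRUE
          } else {
            mu <- mu * 10
          }
        } else {
          mu <- mu * 10
        }
      }
      if (!accepted) break  # damping exhausted: converged
      iter <- iter + 1L
      val_sse <- if (has_val) sum((.bpnn_forward(Xb_val, w, p, hidden)$yhat - y_val)^2) else sse
      if (val_sse <= best_val) { best_val <- val_sse; best_w <- w }
      log_rows[[iter]] <- c(iter = iter, train_mse = sse / length(y_tr),
                            val_mse = val_sse / max(1, length(y_val)), mu = mu)
    }
    if (!is.finite(sse)) stop("non-finite training loss", call. = FALSE)
    list(weights = best_w, log = do.call(rbind, log_rows), iter = iter,
         final_train_mse = sse / length(y_tr), val_idx = val_idx)
  })

  structure(list(
    layer_sizes = c(p, hidden, 1),
    weights = model$weights,
    constant = NULL,
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    feature_names = colnames(X),
    training_log = as.data.frame(model$log),
    iterations = model$iter,
    final_train_mse = model$final_train_mse,
    seed = as.integer(seed)
  ), class = "cnc_bpnn")
}

#' Predict from a fitted network
#' @param object a `cnc_bpnn`.
#' @param newdata matrix `[samples x features]` in the training column order.
#' @param ... unused.
#' @return predicted % N (original scale).
#' @export
predict.cnc_bpnn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(X)))
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  p <- object$layer_sizes[1]; hidden <- object$layer_sizes[2]
  Xs <- sweep(sweep(X, 2, object$x_min), 2, object$x_max - object$x_min, "/") * 2 - 1
  ys <- .bpnn_forward(cbind(Xs, 1), object$weights, p, hidden)$yhat
  (ys + 1) / 2 * (object$y_max - object$y_min) + object$y_min
}
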