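# Model accuracy metrics: R2, RMSE, SD, the ratio of performance to
# deviation (RPD) with its interpretation bands, coefficient of variation,
# and 1:1 scatter summaries.

#' Accuracy metrics for predicted vs measured nitrogen
#'
#' Computes, in this order and with these conventions:
#' \itemize{
#'   \item R2 = sum((yhat_i - ybar)^2) / sum((y_i - ybar)^2) with ybar the
#'     measured mean — the regression-sum-of-squares form
#'     (`r2_method = "ssr"`, default). This form can exceed 1 for biased
#'     predictors; the conventional 1 - SSE/SST variant is available as
#'     `r2_method = "one_minus_sse"`.
#'   \item RMSE = sqrt(mean((y - yhat)^2)) (population 1/N form).
#'   \item SD = sample standard deviation of the measured values (1/(N-1)).
#'   \item RPD = SD / RMSE, with interpretation: below 1.4 the model cannot
#'     be used for prediction ("poor"), above 2.0 it has superior predictive
#'     power ("superior"), otherwise "moderate". Both cuts are strict.
#' }
#' A perfect prediction (RMSE = 0) leaves RPD undefined (`NA`) and sets the
#' `perfect` flag.
#'
#' @param y_measured,y_predicted equal-length vectors (n >= 2); the measured
#'   values must not be constant.
#' @param r2_method `"ssr"` or `"one_minus_sse"`.
#' @return an `eval_metrics` list: `r_squared`, `rmse`, `sd`, `rpd`,
#'   `rpd_category`, `perfect`, `n`.
#' @export
eval_metrics <- function(y_measured, y_predicted, r2_method = c("ssr", "one_minus_sse")) {
  r2_method <- match.arg(r2_method)
  y <- as.numeric(y_measured); yhat <- as.numeric(y_predicted)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  n <- length(y)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("measured values are constant; SD = 0", call. = FALSE)
  r2 <- switch(r2_method,
               ssr = sum((yhat - mean(y))^2) / sst,
               one_minus_sse = 1 - sum((y - yhat)^2) / sst)
  rmse <- sqrt(mean((y - yhat)^2))
  sdv <- sqrt(sst / (n - 1))
  perfect <- rmse == 0
  rpd <- if (perfect) NA_real_ else sdv / rmse
  category <- if (perfect) NA_character_ else rpd_category(rpd)
  structure(list(r_squared = r2, rmse = rmse, sd = sdv, rpd = rpd,
                 rpd_category = category, perfect = perfect, n = n),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n = %d: R2 = %.3f, RMSE = %.4f, SD = %.4f, RPD = %s (%s)\n",
              x$n, x$r_squared, x$rmse, x$sd,
              if (is.na(x$rpd)) "undefined" else sprintf("%.3f", x$rpd),
              if (x$perfect) "perfect" else x$rpd_category))
  invisible(x)
}

#' Interpret an RPD value
#'
#' Strict bands: below 1.4 the model cannot be used for prediction
#' ("poor"), above 2.0 it has superior predictive power ("superior");
#' everything in between — including the boundary values themselves — is
#' "moderate".
#'
#' @param rpd ratio of performance to deviation.
#' @return `"poor"`, `"moderate"` or `"superior"`.
#' @export
rpd_category <- function(rpd) {
  stopifnot(is.finite(rpd), rpd >= 0)
  if (rpd < 1.4) "poor" else if (rpd > 2.0) "superior" else "moderate"
}

#' Coefficient of variation in percent
#'
#' `100 * SD / mean` with the sample (1/(N-1)) standard deviation. A
#' constant sample has CV 0%.
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(v)
  if (abs(m) < 1e-15) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(v) / m
}

#' Slope, intercept and R2 of the 1:1 scatter trend line
#'
#' Ordinary least squares of predicted on measured; a perfect model has
#' slope 1, intercept 0, R2 1.
#'
#' @param y_measured,y_predicted equal-length vectors, n >= 3.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
one_to_one_summary <- function(y_measured, y_predicted) {
  y <- as.numeric(y_measured); yhat <- as.numeric(y_predicted)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(y) == 0) stop("measured values are constant", call. = FALSE)
  fit <- stats::lm(yhat ~ y)
  cf <- unname(stats::coef(fit))
  r2 <- if (stats::sd(yhat) == 0) 0 else stats::cor(y, yhat)^2
  list(slope = cf[2], intercept = cf[1], r_squared = r2)
}
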