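## Shared nonlinear-regression machinery: equal-fractional-error weighted
## least squares on log-scale parameters, fit_result container, pooling.

#' Fit result container
#'
#' Point estimates, standard errors and diagnostics from one nonlinear
#' regression.
#'
#' @param estimates data.frame with columns `parameter`, `value`, `se`.
#' @param covariance covariance matrix of the estimates (natural scale).
#' @param weighting character description of the weighting scheme.
#' @param residuals weighted residual vector at the optimum.
#' @param converged logical convergence flag.
#' @param n_points number of data points used.
#' @param message solver message.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(estimates, covariance = NULL,
                       weighting = "none", residuals = numeric(),
                       converged = TRUE, n_points = NA_integer_,
                       message = "") {
  stopifnot(is.data.frame(estimates),
            all(c("parameter", "value", "se") %in% names(estimates)))
  if (converged && any(estimates$se < 0, na.rm = TRUE))
    stop("standard errors must be nonnegative", call. = FALSE)
  structure(list(estimates = estimates, covariance = covariance,
                 weighting = weighting, residuals = residuals,
                 converged = converged, n_points = n_points,
                 message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear fit (", x$weighting, " weighting, n = ", x$n_points,
      ")\n", sep = "")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-8s %.6g  (SE %.3g)\n",
                est$parameter[i], est$value[i], est$se[i]))
  cat(if (x$converged) "  converged" else
    paste0("  NOT converged: ", x$message), "\n")
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) {
  stats::setNames(object$estimates$value, object$estimates$parameter)
}

## Generic equal-fractional-error fit engine.
##
## model_fn(theta) -> predicted vector on the natural scale; theta is the
## natural-scale named parameter vector.  Parameters are optimised on the
## log scale (positivity without hard bounds).  Residuals are
## (obs - pred)/max(pred, floor): fractional errors, with the weight
## re-evaluated at every iterate (continuous IRLS).
.floor_v <- 1e-12

.fractional_fit <- function(obs, model_fn, start, weighting = "fractional",
                            max_iter = 500L) {
  if (all(obs == 0))
    stop("degenerate data: all observations are zero", call. = FALSE)
  pnames <- names(start)
  resid_fn <- function(lpar) {
    pred <- model_fn(stats::setNames(exp(lpar), pnames))
    if (weighting == "fractional")
      (obs - pred) / pmax(pred, .floor_v)
    else obs - pred
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter,
                                    ftol = 1e-12, ptol = 1e-12)
  ans <- minpack.lm::nls.lm(par = log(start), fn = resid_fn, control = ctl)
  ## nls.lm info codes 1:4 indicate convergence in f, p, both, or gradient
  converged <- ans$info %in% 1:4
  if (!converged)
    stop("nonlinear regression did not converge (", ans$message,
         "); last iterate: ",
         paste(pnames, signif(exp(ans$par), 6), sep = "=", collapse = ", "),
         call. = FALSE)
  lhat <- ans$par
  theta <- stats::setNames(exp(lhat), pnames)

  ## covariance from a numeric Jacobian of the residual vector wrt log-params
  r0 <- resid_fn(lhat)
  n <- length(r0); p <- length(lhat)
  J <- matrix(0, n, p)
  h <- 1e-6
  for (j in seq_len(p)) {
    lp <- lhat; lm <- lhat
    lp[j] <- lp[j] + h; lm[j] <- lm[j] - h
    J[, j] <- (resid_fn(lp) - resid_fn(lm)) / (2 * h)
  }
  dof <- max(n - p, 1L)
  sigma2 <- sum(r0^2) / dof
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, p, p))
  ## delta method: theta = exp(ltheta)
  D <- diag(theta, p)
  cov_nat <- D %*% cov_log %*% D
  se <- sqrt(pmax(diag(cov_nat), 0))
  dimnames(cov_nat) <- list(pnames, pnames)

  fit_result(
    estimates = data.frame(parameter = pnames, value = unname(theta),
                           se = unname(se)),
    covariance = cov_nat,
    weighting = weighting,
    residuals = r0,
    converged = TRUE,
    n_points = n,
    message = ans$message)
}

#' Pool parameter estimates across independent experiments
#'
#' Inverse-variance weighted mean per parameter:
#' \eqn{\hat\theta = \sum w_i \theta_i / \sum w_i}, \eqn{w_i = 1/SE_i^2},
#' with pooled standard error \eqn{(\sum w_i)^{-1/2}} -- the standard
#' fixed-effect combination of estimates from replicate experiments.
#'
#' @param fits list of converged [fit_result()] objects estimating the
#'   same parameters.
#' @return A [fit_result()] with pooled estimates.  A single fit is
#'   returned unchanged (with a note in `message`).
#' @examples
#' f1 <- fit_result(data.frame(parameter = "Km", value = 0.9, se = 0.1))
#' f2 <- fit_result(data.frame(parameter = "Km", value = 1.7, se = 0.4))
#' pool_experiments(list(f1, f2))  # 0.947 +/- 0.0970
#' @export
pool_experiments <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1))))
    stop("all fits must have converged before pooling", call. = FALSE)
  if (length(fits) == 1L) {
    f <- fits[[1L]]
    f$message <- paste0(f$message, " [single experiment: not pooled]")
    return(f)
  }
  pnames <- fits[[1L]]$estimates$parameter
  for (f in fits)
    if (!identical(f$estimates$parameter, pnames))
      stop("fits estimate different parameters", call. = FALSE)
  vals <- sapply(fits, function(f) f$estimates$value)  # p x k
  ses  <- sapply(fits, function(f) f$estimates$se)
  vals <- matrix(vals, nrow = length(pnames))
  ses  <- matrix(ses, nrow = length(pnames))
  w <- 1 / ses^2
  pooled <- rowSums(w * vals) / rowSums(w)
  pooled_se <- 1 / sqrt(rowSums(w))
  fit_result(
    estimates = data.frame(parameter = pnames, value = pooled,
                           se = pooled_se),
    weighting = "inverse-variance pooling",
    converged = TRUE,
    n_points = sum(vapply(fits, function(f) f$n_points, integer(1))),
    message = sprintf("pooled over %d experiments", length(fits)))
}

#' Write a fit result to JSON
#'
#' @param fit a [fit_result()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(
    estimates = fit$estimates,
    weighting = fit$weighting,
    converged = fit$converged,
    n_points = fit$n_points,
    residual_rss = sum(fit$residuals^2),
    message = fit$message,
    package_version = as.character(utils::packageVersion("b55kin")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
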