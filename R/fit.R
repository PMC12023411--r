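#' Weighted nonlinear least-squares fit engine
#'
#' All model fits in the package go through this engine, which wraps
#' Levenberg-Marquardt trust-region least squares
#' ([minpack.lm::nls.lm()]) and returns a uniform `"coldlac_fit"` object:
#' estimates, standard errors, residuals, reduced chi-squared and a
#' convergence flag. Non-convergence and singular Jacobians are flagged, not
#' raised; a singular Jacobian yields infinite uncertainties.
#'
#' @param model Either a registered model identifier (see
#'   [coldlac_models()]) or a function `f(params, x)` returning predicted
#'   values, where `params` is a full named vector.
#' @param data A [titration_series()] or a data frame with columns `x`, `y`
#'   and optionally `sigma`.
#' @param init Named vector of starting values. Must lie within bounds.
#' @param lower,upper Optional named vectors of box constraints (parameters
#'   not named are unbounded).
#' @param fixed Optional named vector of parameters held fixed during the
#'   fit (excluded from the parameter count).
#' @param weights Optional per-point standard deviations overriding
#'   `data$sigma`. If absent everywhere, unit weights are used.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `"coldlac_fit"` with elements `coefficients`,
#'   `se`, `fitted`, `residuals` (sigma-weighted), `redchi2`, `converged`,
#'   `singular`, `nobs`, `npar`, `model`, `data`, `fixed`.
#' @export
#' @examples
#' d <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
#' f <- fit_curve("line", d, init = c(intercept = 0, slope = 1))
#' coef(f)
fit_curve <- function(model, data, init, lower = NULL, upper = NULL,
                      fixed = NULL, weights = NULL, control = list()) {
  fn <- if (is.character(model)) coldlac_model(model) else model
  data <- as.data.frame(data)
  stopifnot(nrow(data) > 0, all(c("x", "y") %in% names(data)))
  x <- data$x
  y <- data$y
  sigma <- weights
  if (is.null(sigma)) sigma <- data$sigma
  if (is.null(sigma) || all(is.na(sigma))) sigma <- rep(1, length(y))
  stopifnot(all(sigma > 0))

  free <- names(init)
  if (!is.null(fixed) && length(intersect(free, names(fixed))))
    stop("parameters cannot be both free and fixed")
  full <- function(p) c(p, fixed)[union(free, names(fixed))]

  lo <- rep(-Inf, length(free)); names(lo) <- free
  hi <- rep(Inf, length(free));  names(hi) <- free
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(init < lo - 1e-12) || any(init > hi + 1e-12))
    stop("initial values must lie within bounds")

  resid_fn <- function(p) {
    names(p) <- free
    r <- (y - fn(full(p), x)) / sigma
    r[!is.finite(r)] <- 1e10
    r
  }
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 500), control))
  out <- minpack.lm::nls.lm(par = init, lower = lo, upper = hi,
                            fn = resid_fn, control = ctrl)
  est <- out$par
  names(est) <- free
  res <- resid_fn(est)
  nobs <- length(y)
  npar <- length(free)
  dof <- nobs - npar
  redchi2 <- if (dof > 0) sum(res^2) / dof else NA_real_

  hes <- out$hessian  # t(J) %*% J of the weighted residuals
  se <- rep(Inf, npar)
  singular <- TRUE
  cv <- tryCatch(solve(hes), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
    scale2 <- if (is.finite(redchi2) && redchi2 > 0) redchi2 else 1
    se <- sqrt(diag(cv) * scale2)
    singular <- FALSE
  }
  names(se) <- free

  structure(list(
    coefficients = est,
    se = se,
    fitted = fn(full(est), x),
    residuals = res,
    redchi2 = redchi2,
    converged = out$info %in% 1:4,
    singular = singular,
    message = out$message,
    nobs = nobs,
    npar = npar,
    model = fn,
    fixed = fixed,
    data = data.frame(x = x, y = y, sigma = sigma)
  ), class = "coldlac_fit")
}

# ---- model registry ---------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Registered model identifiers
#'
#' The fit engine accepts either a bare function or one of these registered
#' identifiers. Each maps to a function `f(params, x)`.
#'
#' @return Character vector of registered model ids.
#' @export
coldlac_models <- function() sort(ls(.model_registry))

coldlac_model <- function(id) {
  if (!exists(id, envir = .model_registry, inherits = FALSE))
    stop("unknown model id: ", id,
         " (see coldlac_models() for registered ids)")
  get(id, envir = .model_registry, inherits = FALSE)
}

register_model <- function(id, fn) assign(id, fn, envir = .model_registry)

register_model("line", function(p, x) p[["intercept"]] + p[["slope"]] * x)

# ---- methods ----------------------------------------------------------------

#' @export
print.coldlac_fit <- function(x, ...) {
  cat("coldlac fit (", x$npar, " parameters, ", x$nobs, " points)\n", sep = "")
  print(format_estimates(x))
  cat("reduced chi-squared:", format(x$redchi2, digits = 4),
      if (!x$converged) " [NOT CONVERGED]" else "",
      if (x$singular) " [singular Jacobian]" else "", "\n")
  invisible(x)
}

#' @export
summary.coldlac_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  out <- list(coefficients = tab, redchi2 = object$redchi2,
              converged = object$converged, nobs = object$nobs,
              npar = object$npar, fixed = object$fixed)
  class(out) <- "summary.coldlac_fit"
  out
}

#' @export
print.summary.coldlac_fit <- function(x, ...) {
  printCoefmat(x$coefficients)
  cat("reduced chi-squared:", format(x$redchi2, digits = 4),
      "on", x$nobs - x$npar, "degrees of freedom\n")
  if (!is.null(x$fixed)) {
    cat("fixed:", paste(names(x$fixed), signif(unlist(x$fixed), 4),
                        sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.coldlac_fit <- function(object, ...) object$coefficients

#' @export
vcov.coldlac_fit <- function(object, ...) {
  v <- diag(object$se^2)
  dimnames(v) <- list(names(object$se), names(object$se))
  v
}

#' @export
residuals.coldlac_fit <- function(object, ...) object$residuals

#' @export
predict.coldlac_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  p <- c(object$coefficients, object$fixed)
  object$model(p, x)
}

#' @export
plot.coldlac_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = "x", ylab = "y", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Format estimates in estimate +/- standard error style
#'
#' Mirrors the field's reporting convention (e.g. "0.23 +/- 0.20").
#'
#' @param fit A `"coldlac_fit"` object.
#' @param digits Significant digits for the uncertainty.
#' @return Named character vector.
#' @export
format_estimates <- function(fit, digits = 2) {
  est <- fit$coefficients
  se <- fit$se
  out <- vapply(seq_along(est), function(i) {
    if (!is.finite(se[i])) return(sprintf("%g (se undetermined)", est[i]))
    sprintf("%s ± %s", signif(est[i], 6), signif(se[i], digits))
  }, character(1))
  names(out) <- names(est)
  out
}
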