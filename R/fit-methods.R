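# Shared S3 infrastructure for fit objects returned by fit_trast(),
# global_fit_fcs() and fit_flow(). Each is a list with elements
#   coefficients, se, residuals, fitted, data, converged, message,
#   model (short description), predict_fun (function(coef, newdata)).

new_tk_fit <- function(subclass, coefficients, se, residuals, fitted, data,
                       converged, message = "", model = "", extra = list()) {
  structure(c(list(coefficients = coefficients, se = se,
                   residuals = residuals, fitted = fitted, data = data,
                   converged = converged, message = message, model = model),
              extra),
            class = c(subclass, "tk_fit"))
}

# Pull estimates and standard errors out of a minpack.lm::nls.lm result.
# Returns list(coef, se, converged, message).
nlslm_pars <- function(res, par_names) {
  est <- stats::coef(res)
  names(est) <- par_names
  se <- rep(NA_real_, length(est))
  names(se) <- par_names
  sm <- tryCatch(summary(res), error = function(e) NULL)
  if (!is.null(sm) && is.matrix(sm$coefficients))
    se <- stats::setNames(sm$coefficients[, "Std. Error"], par_names)
  converged <- res$info %in% 1:4
  list(coef = est, se = se, converged = converged,
       message = res$message %||% "")
}

#' @export
coef.tk_fit <- function(object, ...) object$coefficients

#' @export
residuals.tk_fit <- function(object, ...) object$residuals

#' @export
fitted.tk_fit <- function(object, ...) object$fitted

#' @export
print.tk_fit <- function(x, ...) {
  cat(sprintf("%s\n", x$model))
  if (!x$converged)
    cat("  ** fit did not converge:", x$message, "**\n")
  est <- x$coefficients
  se <- x$se
  for (nm in names(est)) {
    if (is.finite(se[nm]))
      cat(sprintf("  %-12s %.6g  (se %.3g)\n", nm, est[nm], se[nm]))
    else
      cat(sprintf("  %-12s %.6g\n", nm, est[nm]))
  }
  cat(sprintf("  residual sum of squares: %.4g on %d points\n",
              sum(x$residuals^2), length(x$residuals)))
  invisible(x)
}

#' @export
summary.tk_fit <- function(object, ...) {
  out <- list(model = object$model, converged = object$converged,
              message = object$message,
              coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              rss = sum(object$residuals^2),
              n = length(object$residuals))
  class(out) <- "summary.tk_fit"
  out
}

#' @export
print.summary.tk_fit <- function(x, ...) {
  cat(sprintf("%s\n", x$model))
  cat(sprintf("Converged: %s\n", x$converged))
  print(x$coefficients)
  cat(sprintf("RSS %.4g on %d residuals\n", x$rss, x$n))
  invisible(x)
}
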