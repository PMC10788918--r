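# Stationary TRAST: pulse-train fluorescence integration, normalization,
# monoexponential and brightness-weighted mixture models, curve fitting.
#
# A TRAST experiment applies trains of rectangular excitation pulses of
# width w (N repetitions, constant total illumination time t_ill = N*w,
# low duty cycle eta) and records the time-averaged fluorescence
# <F_exc(w)>. Dark-state buildup during longer pulses depresses the
# average; normalizing each point by the value at a short reference width
# w0 cancels concentration, detection and quantum-yield factors and leaves
# a dimensionless TRAST curve that encodes the dark-state kinetics.

#' Rectangular pulse-train description
#'
#' @param w Pulse width (s).
#' @param n_pulses Number of pulse repetitions; if `NULL`, derived from
#'   `t_ill` as `round(t_ill / w)` (at least 1).
#' @param duty_cycle Excitation duty cycle eta in (0, 1].
#' @param t_ill Total illumination time `n_pulses * w` (s).
#' @param w0 Normalization reference pulse width (s).
#' @return An object of class `"pulse_train"`.
#' @export
pulse_train <- function(w, n_pulses = NULL, duty_cycle = 0.01,
                        t_ill = NULL, w0 = 1e-7) {
  stopifnot(w > 0, w0 > 0)
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty_cycle must be in (0, 1]")
  if (is.null(n_pulses)) {
    if (is.null(t_ill)) t_ill <- 1e-3
    n_pulses <- max(1L, as.integer(round(t_ill / w)))
  }
  structure(list(w = w, n_pulses = as.integer(n_pulses),
                 duty_cycle = duty_cycle, t_ill = n_pulses * w, w0 = w0),
            class = "pulse_train")
}

#' Monoexponential TRAST relaxation parameters
#'
#' Parameters of the monoexponential decay of the emissive-state
#' population during one pulse: `S(t) = 1 - A (1 - exp(-t / tau))`.
#'
#' @param A Relaxation amplitude in [0, 1].
#' @param tau Relaxation time (s), > 0.
#' @return An object of class `"monoexp"`.
#' @export
monoexp_params <- function(A, tau) {
  stopifnot(is.numeric(A), is.numeric(tau))
  if (A < 0 || A > 1) stop("A must be in [0, 1]")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(A = A, tau = tau), class = "monoexp")
}

# Reduce any supported object to monoexponential in-pulse kinetics
# (amplitude + relaxation time) at the given excitation.
as_monoexp <- function(object, exc = NULL) {
  if (inherits(object, "monoexp")) return(object)
  if (inherits(object, "fluorophore_model")) {
    if (is.null(exc)) stop("an excitation() is required with a fluorophore model")
    r <- dark_rates(object, exc)
    tot <- sum(r)
    if (tot == 0) return(monoexp_params(0, 1))
    monoexp_params(unname(r["k_on"]) / tot, 1 / tot)
  } else stop("expected a monoexp_params() or fluorophore model")
}

#' Fluorescence response to a rectangular excitation pulse
#'
#' Relative fluorescence F(t) during a rectangular pulse starting at t = 0,
#' proportional to the emissive-state probability and normalized so that
#' F(0+) = 1. Decays toward `1 - A` where `A` is the steady-state dark
#' fraction.
#'
#' @param object A fluorophore model or [monoexp_params()].
#' @param exc An [excitation()] (required for fluorophore models).
#' @param t_grid Sorted times (s), >= 0.
#' @return Numeric vector F(t).
#' @export
pulse_response <- function(object, exc = NULL, t_grid) {
  if (inherits(object, "fluorophore_model")) {
    evolve_population(object, exc, t_grid)[, "bright"]
  } else {
    p <- as_monoexp(object, exc)
    1 - p$A * (1 - exp(-t_grid / p$tau))
  }
}

#' Time-averaged fluorescence of one excitation pulse
#'
#' Pulse-window average `(1/w) * integral_0^w F(t) dt` of the fluorescence
#' response. For monoexponential kinetics the closed form is
#' \deqn{\langle F(w)\rangle = 1 - A + \frac{A\tau}{w}(1 - e^{-w/\tau}).}
#'
#' @param object A fluorophore model or [monoexp_params()].
#' @param w Pulse width(s) (s), > 0.
#' @param exc An [excitation()] (required for fluorophore models).
#' @param method `"closed"` (monoexponential closed form) or `"integrate"`
#'   (numerical quadrature of [pulse_response()]).
#' @param start_bright Bright-state occupancy at pulse onset (default 1);
#'   used by the per-pulse train summation.
#' @return Mean fluorescence, dimensionless, in (1 - A, 1].
#' @examples
#' mean_pulse_fluorescence(monoexp_params(0.45, 12.4e-6), w = 12.4e-6) # 0.834
#' @export
mean_pulse_fluorescence <- function(object, w, exc = NULL,
                                    method = c("closed", "integrate"),
                                    start_bright = 1) {
  method <- match.arg(method)
  if (any(w <= 0)) stop("pulse width w must be > 0")
  p <- as_monoexp(object, exc)
  s_inf <- 1 - p$A
  if (method == "closed") {
    # S(t) = s_inf + (start_bright - s_inf) e^(-t/tau), averaged over [0, w]
    x <- w / p$tau
    s_inf + (start_bright - s_inf) * (-expm1(-x)) / x
  } else {
    vapply(w, function(wi) {
      stats::integrate(function(t)
        s_inf + (start_bright - s_inf) * exp(-t / p$tau),
        0, wi, rel.tol = 1e-12, abs.tol = 0)$value / wi
    }, numeric(1))
  }
}

#' Construct a TRAST curve object
#'
#' @param widths Strictly increasing pulse widths (s).
#' @param values Normalized mean fluorescence values.
#' @param sd Optional per-point standard deviations.
#' @param w0 Normalization reference width (s).
#' @return A data frame of class `"trast_curve"` with columns
#'   `width_s`, `value` (and `sd` if given), and attribute `w0`.
#' @export
new_trast_curve <- function(widths, values, sd = NULL, w0 = min(widths)) {
  stopifnot(length(widths) == length(values))
  if (is.unsorted(widths, strictly = TRUE))
    stop("widths must be strictly increasing")
  df <- data.frame(width_s = widths, value = values)
  if (!is.null(sd)) df$sd <- sd
  structure(df, w0 = w0, class = c("trast_curve", "data.frame"))
}

#' @export
print.trast_curve <- function(x, ...) {
  cat(sprintf("TRAST curve: %d widths from %.3g to %.3g s (w0 = %.3g s)\n",
              nrow(x), min(x$width_s), max(x$width_s), attr(x, "w0")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.trast_curve <- function(x, ...) {
  graphics::plot(x$width_s, x$value, log = "x", xlab = "pulse width w (s)",
                 ylab = expression(paste("<", F[exc], "(w)>")[norm]),
                 type = "b", ...)
  invisible(x)
}

#' Default TRAST pulse-width grid
#'
#' 30 log-spaced pulse widths from 100 ns to 1 ms.
#'
#' @param n Number of widths.
#' @param from,to Range (s).
#' @return Numeric vector of widths.
#' @export
trast_widths <- function(n = 30, from = 1e-7, to = 1e-3) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate a stationary TRAST curve
#'
#' Computes the normalized TRAST curve for a fluorophore model (at a given
#' excitation) or directly from monoexponential relaxation parameters. Each
#' point is the pulse-window average of the fluorescence response,
#' normalized by the value at the reference width `w0`. At low duty cycle
#' the fluorophores recover fully between pulses and the single-pulse
#' expression suffices; with `per_pulse = TRUE` the full per-train
#' summation is used instead, chaining pulses through the incomplete
#' inter-pulse recovery (recommended for duty cycles above ~0.05 or very
#' slow thermal recovery).
#'
#' @param object A fluorophore model or [monoexp_params()].
#' @param exc An [excitation()] (for fluorophore models).
#' @param widths Pulse widths (s); default [trast_widths()].
#' @param w0 Reference width; must be one of `widths` (default the
#'   smallest).
#' @param duty_cycle Excitation duty cycle eta.
#' @param t_ill Total illumination time per train (s).
#' @param per_pulse Use the full per-train summation with inter-pulse
#'   recovery (isomerization models only).
#' @param w0_tol Warn if the model predicts more than this dark-state
#'   buildup at `w0` (default 1e-3).
#' @return A `"trast_curve"` object with value 1 at `w0`.
#' @examples
#' trast_curve(fluorophore("Cy5_free"), excitation(1e3, 638))
#' @export
trast_curve <- function(object, exc = NULL, widths = trast_widths(),
                        w0 = min(widths), duty_cycle = 0.01, t_ill = 1e-3,
                        per_pulse = FALSE, w0_tol = 1e-3) {
  if (!any(widths == w0)) stop("w0 must be one of the simulated widths")
  if (w0 > min(widths)) stop("w0 must be the smallest width in the series")
  mpf <- function(w) {
    if (per_pulse) {
      vapply(w, function(wi)
        train_mean_fluorescence(object, exc, wi, duty_cycle, t_ill),
        numeric(1))
    } else {
      mean_pulse_fluorescence(object, w, exc)
    }
  }
  v0 <- mpf(w0)
  if (1 - v0 > w0_tol)
    warning(sprintf(
      "model predicts %.2g%% dark-state buildup at w0; choose a shorter w0",
      100 * (1 - v0)))
  vals <- mpf(widths) / v0
  vals[widths == w0] <- 1
  new_trast_curve(widths, vals, w0 = w0)
}

# Mean fluorescence over a full pulse train, chaining incomplete
# inter-pulse recovery between consecutive pulses.
train_mean_fluorescence <- function(object, exc, w, duty_cycle, t_ill) {
  p <- as_monoexp(object, exc)
  k_th <- if (inherits(object, "iso_model")) object$k_biso_th else
    if (inherits(object, "triplet_model")) object$k_T else Inf
  n <- max(1L, as.integer(round(t_ill / w)))
  rec <- interpulse_recovery_seq(p, k_th, w, duty_cycle, n)
  means <- mean_pulse_fluorescence(p, w, start_bright = rec$bright_start)
  mean(means)
}

# Core recursion shared by interpulse_recovery() and the train summation.
interpulse_recovery_seq <- function(p, k_th, w, duty_cycle, n_pulses) {
  s_inf <- 1 - p$A
  decay <- exp(-w / p$tau)
  t_gap <- if (duty_cycle >= 1) 0 else w * (1 - duty_cycle) / duty_cycle
  g <- exp(-k_th * t_gap)                    # dark fraction surviving the gap
  bright <- numeric(n_pulses)
  b <- 1
  for (i in seq_len(n_pulses)) {
    bright[i] <- b
    b_end <- s_inf + (b - s_inf) * decay     # bright at end of pulse
    b <- 1 - (1 - b_end) * g                 # thermal recovery over gap
  }
  # geometric fixed point of the same recursion
  d_limit <- if (g * decay >= 1) 1 - s_inf else
    g * (1 - s_inf) * (1 - decay) / (1 - g * decay)
  list(bright_start = bright, limit = 1 - d_limit)
}

#' Start-of-pulse bright fraction across a pulse train
#'
#' Tracks how much of the population has recovered to the bright state at
#' the onset of each pulse in a train. During a pulse the bright fraction
#' relaxes with the in-pulse kinetics; during the inter-pulse gap of
#' duration `w (1 - eta) / eta` only the thermal dark-to-bright channel
#' acts, so slow thermal recovery plus a low duty cycle leads to a
#' geometric carry-over of dark-state population between pulses.
#'
#' @param model An [iso_model()] or [triplet_model()].
#' @param exc An [excitation()] object.
#' @param train A [pulse_train()] with `duty_cycle < 1` (at `duty_cycle = 1`
#'   there is no gap and no recovery happens).
#' @return Data frame with columns `pulse` and `bright_start`; the
#'   geometric limit of the recursion is attached as attribute `"limit"`.
#' @export
interpulse_recovery <- function(model, exc, train) {
  stopifnot(inherits(train, "pulse_train"))
  p <- as_monoexp(model, exc)
  k_th <- if (inherits(model, "iso_model")) model$k_biso_th else model$k_T
  rec <- interpulse_recovery_seq(p, k_th, train$w, train$duty_cycle,
                                 train$n_pulses)
  structure(data.frame(pulse = seq_len(train$n_pulses),
                       bright_start = rec$bright_start),
            limit = rec$limit)
}

#' Two-component mixture TRAST curve
#'
#' Brightness-weighted TRAST curve of a mixture of a relaxing
#' (isomerizing, Cy5-like) species with monoexponential parameters and a
#' flat (non-relaxing, CF640R-like at low irradiance) species. At pulse
#' onset the detected intensity is proportional to
#' `(1 - R) Q + R (1 - A (1 - exp(-t/tau)))` with `Q` the brightness ratio
#' of the flat to the relaxing species; integration over the pulse and w0
#' normalization yield the mixture TRAST curve, whose plateau depression is
#' `R A / (R + (1 - R) Q)`.
#'
#' @param params_cy5 [monoexp_params()] of the relaxing species.
#' @param R_cy5 Fraction of the relaxing species, in [0, 1].
#' @param Q_ratio Brightness ratio (flat / relaxing), > 0.
#' @param widths Pulse widths (s).
#' @param w0 Reference width.
#' @return A `"trast_curve"` object.
#' @export
mixture_trast_curve <- function(params_cy5, R_cy5, Q_ratio,
                                widths = trast_widths(), w0 = min(widths)) {
  if (R_cy5 < 0 || R_cy5 > 1) stop("R_cy5 must be in [0, 1]")
  if (Q_ratio <= 0) stop("Q_ratio must be > 0")
  vals <- mixture_trast_values(params_cy5$A, params_cy5$tau, R_cy5, Q_ratio,
                               widths, w0)
  new_trast_curve(widths, vals, w0 = w0)
}

# w0-normalized mixture values; vectorized over widths.
mixture_trast_values <- function(A, tau, R, Q, widths, w0) {
  one <- function(w) {
    x <- w / tau
    cy5 <- 1 - A + A * (-expm1(-x)) / x
    ((1 - R) * Q + R * cy5) / ((1 - R) * Q + R)
  }
  one(widths) / one(w0)
}

#' Fit a monoexponential model to a TRAST curve
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of the relaxation
#' amplitude and time to a normalized TRAST curve, using the closed-form
#' pulse-window average re-normalized at the curve's `w0`. Residuals are
#' weighted by `1/sd^2` when the curve carries per-point standard
#' deviations, unweighted otherwise.
#'
#' @param curve A `"trast_curve"` object.
#' @param start Optional named start values `c(A=, tau=)`; a data-driven
#'   start is derived from the curve otherwise.
#' @param lower,upper Bounds on `c(A, tau)`.
#' @return A `"trast_fit"` object (see [coef.tk_fit()], `print`,
#'   `summary`, [predict.trast_fit()]). Non-convergence is flagged in the
#'   `converged` element and on printing, not silently ignored.
#' @examples
#' cv <- trast_curve(monoexp_params(0.45, 12.4e-6))
#' coef(fit_trast(cv))
#' @export
fit_trast <- function(curve, start = NULL,
                      lower = c(A = 0, tau = 1e-9),
                      upper = c(A = 1, tau = 1)) {
  stopifnot(inherits(curve, "trast_curve"))
  if (nrow(curve) < 4) stop("need at least 2 more points than free parameters")
  w0 <- attr(curve, "w0")
  wts <- if (!is.null(curve$sd)) 1 / pmax(curve$sd, 1e-12) else
    rep(1, nrow(curve))
  if (is.null(start)) {
    A0 <- min(0.95, max(0.05, 1 - min(curve$value)))
    # width at which the curve has fallen halfway to its plateau
    half <- 1 - A0 / 2
    tau0 <- curve$width_s[which.min(abs(curve$value - half))]
    start <- c(A = A0, tau = max(tau0, 1e-8))
  }
  model_vals <- function(par, w) {
    p <- monoexp_params(min(max(par[1], 0), 1), max(par[2], 1e-12))
    mean_pulse_fluorescence(p, w) / mean_pulse_fluorescence(p, w0)
  }
  res <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(par) wts * (curve$value - model_vals(par, curve$width_s)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pp <- nlslm_pars(res, c("A", "tau"))
  fitted <- model_vals(pp$coef, curve$width_s)
  new_tk_fit("trast_fit", pp$coef, pp$se,
             residuals = curve$value - fitted, fitted = fitted,
             data = curve, converged = pp$converged, message = pp$message,
             model = "Monoexponential TRAST fit (A, tau)",
             extra = list(w0 = w0))
}

#' Predict from a TRAST fit
#'
#' @param object A `"trast_fit"`.
#' @param widths Pulse widths (s); defaults to the fitted curve's widths.
#' @param ... Unused.
#' @return Normalized model values at `widths`.
#' @export
predict.trast_fit <- function(object, widths = NULL, ...) {
  if (is.null(widths)) widths <- object$data$width_s
  p <- monoexp_params(object$coefficients["A"], object$coefficients["tau"])
  mean_pulse_fluorescence(p, widths) /
    mean_pulse_fluorescence(p, object$w0)
}

#' @export
plot.trast_fit <- function(x, ...) {
  plot(x$data, ...)
  graphics::lines(x$data$width_s, x$fitted, col = 2)
  invisible(x)
}

#' Global mixture fit of a TRAST curve series
#'
#' Fits a series of mixture TRAST curves sharing the relaxing species'
#' monoexponential parameters, with one global brightness ratio `Q` and one
#' fraction `R` per curve. `R` can be pinned within a tolerance band around
#' externally supplied values (e.g. fractions determined by an independent
#' FCS measurement), mirroring the protocol in which the fractions may vary
#' only a few percent around their nominal values.
#'
#' @param curves List of `"trast_curve"` objects.
#' @param params_cy5 [monoexp_params()] of the relaxing species (fixed).
#' @param R_nominal Numeric vector of nominal fractions, one per curve, or
#'   `NULL` to fit each `R` freely in [0, 1].
#' @param R_tol Half-width of the allowed band around `R_nominal`
#'   (default 0.03).
#' @param Q_start Start value for the brightness ratio.
#' @return A `"trast_fit"` object whose coefficients are `Q` and
#'   `R_1 ... R_n`.
#' @export
fit_trast_mixture <- function(curves, params_cy5, R_nominal = NULL,
                              R_tol = 0.03, Q_start = 2) {
  stopifnot(length(curves) >= 1, inherits(params_cy5, "monoexp"))
  n <- length(curves)
  if (is.null(R_nominal)) {
    lowerR <- rep(0, n); upperR <- rep(1, n); R0 <- rep(0.5, n)
  } else {
    stopifnot(length(R_nominal) == n)
    lowerR <- pmax(0, R_nominal - R_tol)
    upperR <- pmin(1, R_nominal + R_tol)
    R0 <- pmin(upperR, pmax(lowerR, R_nominal))
  }
  par0 <- c(Q = Q_start, R0)
  resid_fun <- function(par) {
    Q <- par[1]; R <- par[-1]
    unlist(lapply(seq_len(n), function(i) {
      cv <- curves[[i]]
      m <- mixture_trast_values(params_cy5$A, params_cy5$tau, R[i], Q,
                                cv$width_s, attr(cv, "w0"))
      cv$value - m
    }))
  }
  res <- minpack.lm::nls.lm(
    par = par0, lower = c(1e-3, lowerR), upper = c(1e3, upperR),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  nms <- c("Q", paste0("R_", seq_len(n)))
  pp <- nlslm_pars(res, nms)
  fitted_all <- unlist(lapply(seq_len(n), function(i) {
    cv <- curves[[i]]
    mixture_trast_values(params_cy5$A, params_cy5$tau,
                         pp$coef[i + 1], pp$coef[1],
                         cv$width_s, attr(cv, "w0"))
  }))
  obs <- unlist(lapply(curves, function(cv) cv$value))
  new_tk_fit("trast_fit", pp$coef, pp$se,
             residuals = obs - fitted_all, fitted = fitted_all,
             data = curves, converged = pp$converged, message = pp$message,
             model = sprintf("Global mixture TRAST fit (%d curves)", n),
             extra = list(params_cy5 = params_cy5))
}
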