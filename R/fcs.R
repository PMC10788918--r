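# FCS autocorrelation models with dark-state relaxation, brightness^2
# weighted mixtures, global fitting across irradiances, and burst
# pre-filtering of binned intensity traces.

#' Quasi-logarithmic (multi-tau style) lag grid
#'
#' @param from,to Lag range (s).
#' @param points_per_octave Lags per factor-of-two (default 16).
#' @return Strictly increasing lag times (s).
#' @export
fcs_lag_grid <- function(from = 1e-7, to = 1, points_per_octave = 16) {
  n_oct <- log2(to / from)
  k <- seq(0, n_oct, by = 1 / points_per_octave)
  unique(from * 2^k)
}

#' FCS model parameters
#'
#' Single-species parameters of the dark-state FCS model: mean number of
#' molecules in the detection volume, 3-D diffusion time, dark-state
#' amplitude (steady-state dark fraction) and relaxation time, and the
#' axial/lateral structure ratio of the Gaussian detection volume.
#'
#' @param n_mol Mean molecules in focus, > 0.
#' @param tau_d Diffusion time (s), > 0.
#' @param a_dark Dark-state amplitude in [0, 1).
#' @param tau_dark Dark relaxation time (s), > 0.
#' @param structure Axial/lateral ratio (default 5).
#' @return An object of class `"fcs_params"`.
#' @export
fcs_params <- function(n_mol, tau_d, a_dark = 0, tau_dark = 1e-6,
                       structure = 5) {
  if (n_mol <= 0) stop("n_mol must be > 0")
  if (tau_d <= 0 || tau_dark <= 0) stop("tau_d and tau_dark must be > 0")
  if (a_dark < 0 || a_dark >= 1)
    stop("a_dark must be in [0, 1); a_dark = 1 is singular")
  structure(list(n_mol = n_mol, tau_d = tau_d, a_dark = a_dark,
                 tau_dark = tau_dark, structure = structure),
            class = "fcs_params")
}

# 3-D Gaussian-volume diffusion factor (2-D drops the axial term).
fcs_diffusion_factor <- function(lags, tau_d, structure, geometry = "3d") {
  g <- 1 / (1 + lags / tau_d)
  if (geometry == "3d") g <- g / sqrt(1 + lags / (structure^2 * tau_d))
  g
}

#' Construct an FCS curve object
#'
#' @param lags Strictly increasing positive lag times (s).
#' @param g Correlation values G(tau).
#' @param sd Optional per-point standard deviations.
#' @return A data frame of class `"fcs_curve"` with columns `lag_s`, `g`
#'   (and `sd`).
#' @export
new_fcs_curve <- function(lags, g, sd = NULL) {
  stopifnot(length(lags) == length(g))
  if (any(lags <= 0)) stop("lags must be > 0")
  if (is.unsorted(lags, strictly = TRUE))
    stop("lags must be strictly increasing")
  df <- data.frame(lag_s = lags, g = g)
  if (!is.null(sd)) df$sd <- sd
  structure(df, class = c("fcs_curve", "data.frame"))
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("FCS curve: %d lags from %.3g to %.3g s, G(min lag) = %.4g\n",
              nrow(x), min(x$lag_s), max(x$lag_s), x$g[1]))
  invisible(x)
}

#' @export
plot.fcs_curve <- function(x, ...) {
  graphics::plot(x$lag_s, x$g, log = "x", type = "l",
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression(G(tau)), ...)
  invisible(x)
}

#' Dark-state FCS model curve
#'
#' Autocorrelation of freely diffusing fluorophores undergoing reversible
#' transitions into one dark state:
#' \deqn{G(\tau) = \frac{1}{N_m} G_{diff}(\tau)
#'   \left(1 + \frac{A}{1-A} e^{-\tau/\tau_{dark}}\right),}
#' with a 3-D Gaussian-volume diffusion factor
#' \eqn{G_{diff} = (1+\tau/\tau_D)^{-1} (1+\tau/(s^2\tau_D))^{-1/2}}.
#'
#' @param params An [fcs_params()] object.
#' @param lags Lag times (s); default [fcs_lag_grid()].
#' @param geometry `"3d"` (default) or `"2d"` (no axial term).
#' @return An `"fcs_curve"` object.
#' @export
fcs_model <- function(params, lags = fcs_lag_grid(), geometry = c("3d", "2d")) {
  stopifnot(inherits(params, "fcs_params"))
  geometry <- match.arg(geometry)
  gd <- fcs_diffusion_factor(lags, params$tau_d, params$structure, geometry)
  dark <- 1 + params$a_dark / (1 - params$a_dark) * exp(-lags / params$tau_dark)
  new_fcs_curve(lags, gd * dark / params$n_mol)
}

#' Dark-state amplitude and relaxation time from a photophysical model
#'
#' Maps a fluorophore model at a given excitation onto the two dark-state
#' terms of the FCS model: amplitude `A = k_on / (k_on + k_off)` and
#' relaxation time `tau_dark = 1 / (k_on + k_off)`, where the on/off rates
#' are the effective isomerization/back-isomerization rates (isomerization
#' scheme) or the effective intersystem crossing rate and triplet decay
#' rate (triplet scheme). For an isomerization model with negligible
#' thermal back-isomerization, both rates scale with irradiance and the
#' amplitude is nearly irradiance-independent in the non-saturated regime.
#'
#' @param model An [iso_model()] or [triplet_model()].
#' @param exc An [excitation()] object.
#' @return Named vector `c(a_dark=, tau_dark=)`.
#' @export
dark_terms_from_model <- function(model, exc) {
  r <- dark_rates(model, exc)
  tot <- sum(r)
  if (tot == 0) return(c(a_dark = 0, tau_dark = Inf))
  c(a_dark = unname(r["k_on"]) / tot, tau_dark = 1 / tot)
}

#' Multi-species FCS mixture curve
#'
#' Correlation curve of a mixture in which each species contributes with a
#' weight proportional to its number fraction times its molecular
#' brightness squared, \eqn{R_i Q_i^2}; weights are normalized so a
#' single-species input reproduces [fcs_model()] exactly.
#'
#' @param components List of components, each a list with elements `R`
#'   (number fraction; fractions must sum to 1), `Q` (molecular
#'   brightness, > 0) and `params` (an [fcs_params()]).
#' @param lags Lag times (s).
#' @param geometry Passed to [fcs_model()].
#' @return An `"fcs_curve"` object.
#' @export
multispecies_fcs <- function(components, lags = fcs_lag_grid(),
                             geometry = "3d") {
  R <- vapply(components, function(cc) cc$R, numeric(1))
  Q <- vapply(components, function(cc) cc$Q, numeric(1))
  if (abs(sum(R) - 1) > 1e-8) stop("component fractions must sum to 1")
  if (any(Q <= 0)) stop("brightness values must be > 0")
  wts <- R * Q^2
  if (sum(wts) == 0) stop("all mixture weights are zero")
  wts <- wts / sum(wts)
  g <- rep(0, length(lags))
  for (i in seq_along(components))
    g <- g + wts[i] * fcs_model(components[[i]]$params, lags, geometry)$g
  new_fcs_curve(lags, g)
}

# Model FCS curve from shared photophysical parameters at one excitation.
# scheme "isomerization": shared = c(k_iso, sigma_biso); "triplet":
# shared = c(k_isc, k_T). Computed directly (no model-object validation) so
# the optimizer can roam freely within its bounds.
fcs_curve_from_photophysics <- function(scheme, shared, sigma, k10, exc,
                                        n_mol, tau_d, lags, structure = 5,
                                        k_biso_th = 0) {
  flux <- photon_flux(exc)
  k_exc <- sigma * flux
  if (scheme == "isomerization") {
    k_on <- k_exc / (k_exc + k10) * shared[1]
    k_off <- shared[2] * flux + k_biso_th
  } else {
    k_on <- k_exc / (k_exc + k10) * shared[1]
    k_off <- shared[2]
  }
  tot <- k_on + k_off
  a <- min(k_on / tot, 1 - 1e-12)
  fcs_model(fcs_params(n_mol, tau_d, a, 1 / tot, structure), lags)
}

#' Global fit of FCS curves across excitation irradiances
#'
#' Fits a set of FCS curves recorded (or simulated) at different
#' irradiances to the dark-state FCS model, with the photophysical
#' parameters shared across all curves and the diffusion time and mean
#' molecule number free per curve. For the isomerization scheme the shared
#' parameters are the isomerization rate `k_iso` and the lumped
#' back-isomerization cross section `sigma_biso`; for the triplet scheme,
#' the intersystem crossing rate `k_isc` and triplet decay rate `k_T`.
#' Levenberg-Marquardt least squares with unweighted residuals.
#'
#' @param curves List of `"fcs_curve"` objects.
#' @param excitations List of [excitation()] objects, one per curve.
#' @param scheme `"isomerization"` or `"triplet"`.
#' @param sigma Fixed excitation cross section (cm^2): `sigma_N` for the
#'   isomerization scheme, `sigma_S` for the triplet scheme.
#' @param k10 Fixed excited-state decay rate (1/s).
#' @param k_biso_th Fixed thermal back-isomerization rate (1/s); the
#'   photo-driven regime of the FCS measurements justifies 0.
#' @param start Optional named start values for the shared parameters
#'   (`k_iso`/`sigma_biso` or `k_isc`/`k_T`).
#' @param structure Detection-volume structure ratio (fixed).
#' @return An `"fcs_fit"` object; shared photophysical parameters first,
#'   then per-curve `n_mol_i`, `tau_d_i`.
#' @export
global_fit_fcs <- function(curves, excitations,
                           scheme = c("isomerization", "triplet"),
                           sigma, k10 = 1e9, k_biso_th = 0, start = NULL,
                           structure = 5) {
  scheme <- match.arg(scheme)
  stopifnot(length(curves) == length(excitations), length(curves) >= 1)
  n <- length(curves)
  shared_names <- if (scheme == "isomerization")
    c("k_iso", "sigma_biso") else c("k_isc", "k_T")
  if (is.null(start)) {
    start <- if (scheme == "isomerization")
      c(k_iso = 1e7, sigma_biso = 0.1e-16) else c(k_isc = 1e6, k_T = 1e6)
  }
  # data-driven per-curve starts: amplitude from G at the shortest lag,
  # diffusion time from the half-decay of the diffusion tail
  nm0 <- vapply(curves, function(cv) 1 / max(cv$g[1], 1e-12), numeric(1))
  td0 <- vapply(curves, function(cv) {
    half <- cv$g[1] / 2
    cv$lag_s[which.min(abs(cv$g - half))]
  }, numeric(1))
  td0 <- pmax(td0, 1e-6)
  # work on log10 scale for positivity and conditioning
  par0 <- c(log10(start[shared_names]), log10(nm0), log10(td0))
  shared_lo <- if (scheme == "isomerization")
    c(3, -20) else c(2, 2)
  shared_hi <- if (scheme == "isomerization")
    c(log10(k10) - 0.05, log10(sigma)) else c(log10(k10) - 0.05, 9)
  lower <- c(shared_lo, rep(-3, n), rep(-7, n))
  upper <- c(shared_hi, rep(6, n), rep(0, n))
  resid_fun <- function(lpar) {
    shared <- 10^lpar[1:2]
    nm <- 10^lpar[2 + seq_len(n)]
    td <- 10^lpar[2 + n + seq_len(n)]
    unlist(lapply(seq_len(n), function(i) {
      m <- fcs_curve_from_photophysics(scheme, shared, sigma, k10,
                                       excitations[[i]], nm[i], td[i],
                                       curves[[i]]$lag_s, structure,
                                       k_biso_th)
      curves[[i]]$g - m$g
    }))
  }
  res <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12))
  nms <- c(shared_names, paste0("n_mol_", seq_len(n)),
           paste0("tau_d_", seq_len(n)))
  pp <- nlslm_pars(res, nms)
  est <- 10^pp$coef
  names(est) <- nms
  se <- log(10) * est * pp$se                 # delta method from log10 scale
  fitted_all <- unlist(lapply(seq_len(n), function(i) {
    fcs_curve_from_photophysics(scheme, est[1:2], sigma, k10,
                                excitations[[i]], est[2 + i], est[2 + n + i],
                                curves[[i]]$lag_s, structure, k_biso_th)$g
  }))
  obs <- unlist(lapply(curves, function(cv) cv$g))
  new_tk_fit("fcs_fit", est, se,
             residuals = obs - fitted_all, fitted = fitted_all,
             data = curves, converged = pp$converged, message = pp$message,
             model = sprintf("Global dark-state FCS fit (%s scheme, %d curves)",
                             scheme, n),
             extra = list(scheme = scheme, sigma = sigma, k10 = k10,
                          k_biso_th = k_biso_th, structure = structure,
                          excitations = excitations))
}

#' Predict from a global FCS fit
#'
#' @param object An `"fcs_fit"`.
#' @param which Curve index.
#' @param lags Lags (s); defaults to that curve's lags.
#' @param ... Unused.
#' @return Model G values.
#' @export
predict.fcs_fit <- function(object, which = 1, lags = NULL, ...) {
  if (is.null(lags)) lags <- object$data[[which]]$lag_s
  est <- object$coefficients
  n <- length(object$data)
  fcs_curve_from_photophysics(object$scheme, est[1:2], object$sigma,
                              object$k10, object$excitations[[which]],
                              est[2 + which], est[2 + n + which], lags,
                              object$structure, object$k_biso_th)$g
}

#' Fit fractions in a multi-species FCS mixture
#'
#' With the component photophysics and brightnesses frozen, fits the number
#' fraction of the first component (plus per-curve diffusion time and
#' molecule number) to a mixture FCS curve.
#'
#' @param curve An `"fcs_curve"` of the mixture.
#' @param comp1,comp2 Component templates: lists with `Q` and `params`
#'   ([fcs_params()]; `a_dark`/`tau_dark`/`structure` are kept fixed,
#'   `n_mol` and `tau_d` are refitted).
#' @param R_start Start fraction of component 1.
#' @return An `"fcs_fit"` with coefficients `R`, `n_mol`, `tau_d`.
#' @export
fit_fcs_fraction <- function(curve, comp1, comp2, R_start = 0.5) {
  stopifnot(inherits(curve, "fcs_curve"))
  model_g <- function(R, nm, td) {
    p1 <- comp1$params; p2 <- comp2$params
    p1$n_mol <- nm; p1$tau_d <- td
    p2$n_mol <- nm; p2$tau_d <- td
    multispecies_fcs(list(list(R = R, Q = comp1$Q, params = p1),
                          list(R = 1 - R, Q = comp2$Q, params = p2)),
                     curve$lag_s)$g
  }
  par0 <- c(R = R_start, n_mol = 1 / max(curve$g[1], 1e-12),
            tau_d = comp1$params$tau_d)
  res <- minpack.lm::nls.lm(
    par = par0, lower = c(0, 1e-6, 1e-9), upper = c(1, 1e9, 10),
    fn = function(par) curve$g - model_g(par[1], par[2], par[3]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pp <- nlslm_pars(res, c("R", "n_mol", "tau_d"))
  fitted <- model_g(pp$coef[1], pp$coef[2], pp$coef[3])
  new_tk_fit("fcs_fit", pp$coef, pp$se,
             residuals = curve$g - fitted, fitted = fitted, data = curve,
             converged = pp$converged, message = pp$message,
             model = "FCS mixture-fraction fit")
}

#' Burst filtering of a binned intensity trace
#'
#' Excises anomalously bright bins (aggregates, bursts) from a binned
#' intensity time trace before correlation. The threshold is
#' `mean + k_sigma * SD`, with mean and SD computed robustly on the bins
#' at or below the 90% quantile so the bursts themselves do not inflate
#' the threshold.
#'
#' @param trace Numeric vector of binned intensities (>= 100 bins).
#' @param k_sigma Threshold multiplier (default 5).
#' @return List with `trace` (bursty bins removed), `mask` (logical,
#'   `TRUE` for removed bins) and `threshold`.
#' @export
burst_filter <- function(trace, k_sigma = 5) {
  stopifnot(is.numeric(trace))
  if (length(trace) < 100) stop("trace must have at least 100 bins")
  if (all(trace == 0)) {
    warning("all-zero trace; nothing to filter")
    return(list(trace = trace, mask = rep(FALSE, length(trace)),
                threshold = Inf))
  }
  base <- trace[trace <= stats::quantile(trace, 0.9)]
  m <- mean(base); s <- stats::sd(base)
  if (!is.finite(s) || s == 0)
    return(list(trace = trace, mask = rep(FALSE, length(trace)),
                threshold = Inf))
  thr <- m + k_sigma * s
  mask <- trace > thr
  list(trace = trace[!mask], mask = mask, threshold = thr)
}
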