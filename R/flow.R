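# Microfluidic flow-TRAST: two-curtain excitation field, recursive
# dark-state propagation of flowing fluorophores, profile prediction and
# mixture-fraction fitting.
#
# Fluorophores are carried at a uniform (plug) velocity through two thin
# Gaussian excitation "curtains" spanning the flow channel. Passage through
# the first curtain drives part of the population into the dark state;
# recovery between the curtains is purely thermal, so the relative
# amplitude of the second fluorescence peak encodes the thermal
# back-isomerization rate and, for mixtures, the fraction of the
# isomerizing species.

#' Two-curtain excitation field
#'
#' Two Gaussian excitation lobes along the flow axis x:
#' `Phi(x) = peak * (exp(-((x - c1)/r)^2) + exp(-((x - c2)/r)^2))`,
#' with 1/e radius `r`. If `total_power` is supplied, the peak irradiance
#' is calibrated so the field integrated over both curtains (area
#' `2 sqrt(pi) r L` times the peak) matches that power.
#'
#' @param peak_irradiance Peak irradiance of each curtain (W/cm^2).
#' @param centers Curtain center positions along x (m), increasing;
#'   default 40 and 90 um (50 um separation).
#' @param e_radius 1/e radius along x (m), default 15 um.
#' @param length_y Curtain extent across the channel (m), default 100 um.
#' @param total_power Optional total beam power (W) used to calibrate the
#'   peak irradiance instead of `peak_irradiance`.
#' @return An object of class `"curtain_field"`.
#' @export
curtain_field <- function(peak_irradiance = 1.3e3,
                          centers = c(40e-6, 90e-6), e_radius = 15e-6,
                          length_y = 100e-6, total_power = NULL) {
  stopifnot(length(centers) == 2, e_radius > 0, length_y > 0)
  if (centers[2] <= centers[1]) stop("centers must be increasing")
  if (!is.null(total_power)) {
    # per-curtain integral over x: sqrt(pi) * r * peak; times length_y (m^2
    # -> cm^2 conversion 1e4) and two curtains
    area_cm2 <- 2 * sqrt(pi) * e_radius * length_y * 1e4
    peak_irradiance <- total_power / area_cm2
  }
  if (peak_irradiance < 0) stop("peak irradiance must be >= 0")
  structure(list(peak_irradiance = peak_irradiance, centers = centers,
                 e_radius = e_radius, length_y = length_y,
                 total_power = total_power),
            class = "curtain_field")
}

# Field along x (m), in W/cm^2
curtain_irradiance_x <- function(field, x) {
  field$peak_irradiance *
    (exp(-((x - field$centers[1]) / field$e_radius)^2) +
       exp(-((x - field$centers[2]) / field$e_radius)^2))
}

#' Flow-channel configuration
#'
#' @param volumetric_ul_min Volumetric pump rate (uL/min).
#' @param width Channel width (m), default 500 um.
#' @param depth Channel depth (m), default 50 um.
#' @return Object of class `"flow_config"` with derived `velocity` (m/s).
#' @export
flow_config <- function(volumetric_ul_min, width = 500e-6, depth = 50e-6) {
  if (volumetric_ul_min <= 0 || width <= 0 || depth <= 0)
    stop("flow rate and channel dimensions must be > 0")
  q_m3s <- volumetric_ul_min * 1e-9 / 60
  structure(list(volumetric_ul_min = volumetric_ul_min, width = width,
                 depth = depth, velocity = q_m3s / (width * depth)),
            class = "flow_config")
}

#' Flow velocity from a volumetric pump rate
#'
#' Plug-flow velocity: pumped volume per time divided by the channel
#' cross-section.
#'
#' @param rate_ul_min Volumetric rate (uL/min), > 0.
#' @param width,depth Channel cross-section (m), > 0.
#' @return Velocity in mm/s.
#' @examples
#' velocity_from_volumetric(1000) # ~667 mm/s
#' velocity_from_volumetric(200)  # ~133 mm/s
#' @export
velocity_from_volumetric <- function(rate_ul_min, width = 500e-6,
                                     depth = 50e-6) {
  flow_config(rate_ul_min, width, depth)$velocity * 1e3
}

#' Excitation irradiance along the transit-time axis
#'
#' Converts the stationary two-curtain field into the irradiance
#' experienced by a fluorophore moving at the plug velocity, via
#' `x = v * t`.
#'
#' @param field A [curtain_field()].
#' @param flow A [flow_config()].
#' @param t_grid Transit times (s); must span both curtains.
#' @return Irradiance Phi(t) (W/cm^2) at each time.
#' @export
excitation_time_profile <- function(field, flow, t_grid) {
  x <- flow$velocity * t_grid
  if (min(x) > field$centers[1] - field$e_radius ||
      max(x) < field$centers[2] + field$e_radius)
    stop("t_grid does not span both excitation curtains")
  curtain_irradiance_x(field, x)
}

# Default transit-time grid: spans [0, c2 + 4r] with the step-size rule
# dt = min(0.05 / max total rate, curtain transit / 200).
flow_time_grid <- function(field, flow, model = NULL, wavelength = 638) {
  v <- flow$velocity
  t_end <- (field$centers[2] + 4 * field$e_radius) / v
  dt <- (2 * field$e_radius / v) / 200
  if (!is.null(model)) {
    r <- dark_rates(model, excitation(field$peak_irradiance, wavelength))
    if (sum(r) > 0) dt <- min(dt, 0.98 * 0.05 / sum(r))
  }
  seq(0, t_end, by = dt)
}

#' Propagate the bright-state fraction through a time-varying field
#'
#' Integrates the two-state kinetics
#' `dN/dt = -k'_iso(t) N + k'_biso(t) (1 - N)` along the transit of a
#' fluorophore through the excitation field, starting from `N(0) = 1`
#' (fully bright on entering). Each step applies the exact exponential
#' relaxation for the rates frozen at the step midpoint, which keeps
#' `N` in [0, 1] unconditionally. Steps must satisfy
#' `dt <= 0.05 / max(k'_iso + k'_biso)`; coarser grids are refused.
#'
#' @param model An [iso_model()].
#' @param phi_t Irradiance at each grid time (W/cm^2).
#' @param t_grid Strictly increasing times (s).
#' @param wavelength Excitation wavelength (nm).
#' @param N0 Initial bright fraction.
#' @return Numeric vector N(t) on `t_grid`.
#' @export
propagate_N <- function(model, phi_t, t_grid, wavelength = 638, N0 = 1) {
  stopifnot(inherits(model, "iso_model"), length(phi_t) == length(t_grid))
  n <- length(t_grid)
  dt <- diff(t_grid)
  if (any(dt <= 0)) stop("t_grid must be strictly increasing")
  flux1 <- (wavelength * 1e-9) / (.HC)      # photon flux per unit irradiance
  phi_mid <- (phi_t[-1] + phi_t[-n]) / 2
  k_exc <- model$sigma_N * flux1 * phi_mid
  k_on <- ifelse(k_exc > 0, k_exc / (k_exc + model$k10) * model$k_iso, 0)
  k_off <- model$sigma_biso * flux1 * phi_mid + model$k_biso_th
  tot <- k_on + k_off
  if (any(dt * tot > 0.05 * 1.001))
    stop("time grid too coarse for the local rates; need dt <= 0.05/(k'_iso+k'_biso)")
  N <- numeric(n)
  N[1] <- N0
  n_ss <- ifelse(tot > 0, k_off / tot, 1)
  decay <- exp(-tot * dt)
  for (i in seq_len(n - 1))
    N[i + 1] <- n_ss[i] + (N[i] - n_ss[i]) * decay[i]
  N
}

#' Construct a flow profile object
#'
#' @param t Transit times (s).
#' @param f_norm Normalized mean fluorescence (unit first-curtain peak).
#' @param label Species/mixture tag.
#' @param velocity Plug velocity (m/s), stored as an attribute.
#' @return Data frame of class `"flow_profile"` with columns `t_s`,
#'   `f_norm`.
#' @export
new_flow_profile <- function(t, f_norm, label = "", velocity = NA_real_) {
  stopifnot(length(t) == length(f_norm))
  structure(data.frame(t_s = t, f_norm = f_norm),
            label = label, velocity = velocity,
            class = c("flow_profile", "data.frame"))
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("Flow-TRAST profile '%s': %d points, %.3g-%.3g s\n",
              attr(x, "label"), nrow(x), min(x$t_s), max(x$t_s)))
  invisible(x)
}

#' @export
plot.flow_profile <- function(x, ...) {
  graphics::plot(x$t_s * 1e6, x$f_norm, type = "l",
                 xlab = "transit time (us)", ylab = "normalized <F>", ...)
  invisible(x)
}

# normalize a raw profile to unit peak within the first-curtain window
normalize_first_peak <- function(t, f, field, flow) {
  t_split <- mean(field$centers) / flow$velocity
  peak1 <- max(f[t <= t_split])
  if (peak1 <= 0) stop("no signal in the first-curtain window")
  f / peak1
}

#' Predict a flow-TRAST fluorescence profile
#'
#' For a non-isomerizing species the mean fluorescence is directly
#' proportional to the excitation field, so the normalized profile equals
#' the unit-peak excitation profile. For an isomerizing species the signal
#' is proportional to `Phi(t) * N(t)` with the bright fraction N(t)
#' propagated through the field; cis-state buildup in the first curtain
#' and incomplete thermal recovery in between suppress the second peak.
#'
#' @param model An [iso_model()], or the string `"non_isomerizing"`.
#' @param field A [curtain_field()].
#' @param flow A [flow_config()].
#' @param t_grid Optional transit-time grid (s); an adequate grid is
#'   constructed if omitted.
#' @param wavelength Excitation wavelength (nm).
#' @return A `"flow_profile"`, normalized to unit first-curtain peak.
#' @export
predict_profile <- function(model, field, flow, t_grid = NULL,
                            wavelength = 638) {
  is_flat <- identical(model, "non_isomerizing")
  grid <- flow_time_grid(field, flow, if (is_flat) NULL else model,
                         wavelength)
  phi <- excitation_time_profile(field, flow, grid)
  f <- if (is_flat) phi else
    phi * propagate_N(model, phi, grid, wavelength)
  f <- normalize_first_peak(grid, f, field, flow)
  if (!is.null(t_grid)) {
    # integration always runs on an internally refined grid; the result is
    # interpolated onto the requested output grid
    f <- stats::approx(grid, f, xout = t_grid, rule = 2)$y
    grid <- t_grid
  }
  new_flow_profile(grid, f,
                   label = if (is_flat) "non_isomerizing" else model$name,
                   velocity = flow$velocity)
}

#' Brightness-weighted mixture flow profile
#'
#' Combines the normalized profiles of an isomerizing (Cy5-like) and a
#' non-isomerizing (CF640R-like) species with fractions `R` and `1 - R`
#' and brightness ratio `Q` (flat/relaxing):
#' `(1 - R) Q F_CF + R F_Cy5`, renormalized to unit first-curtain peak.
#'
#' @param R_cy5 Fraction of the isomerizing species, in [0, 1].
#' @param Q_ratio Brightness ratio, > 0.
#' @param profile_cy5,profile_cf `"flow_profile"` objects on a common
#'   time grid.
#' @param field,flow Geometry used for first-peak renormalization.
#' @return A `"flow_profile"`.
#' @export
mixture_profile <- function(R_cy5, Q_ratio, profile_cy5, profile_cf,
                            field, flow) {
  if (R_cy5 < 0 || R_cy5 > 1) stop("R_cy5 must be in [0, 1]")
  if (!isTRUE(all.equal(profile_cy5$t_s, profile_cf$t_s)))
    stop("profiles must share a common time grid")
  f <- (1 - R_cy5) * Q_ratio * profile_cf$f_norm +
    R_cy5 * profile_cy5$f_norm
  new_flow_profile(profile_cy5$t_s,
                   normalize_first_peak(profile_cy5$t_s, f, field, flow),
                   label = sprintf("mixture R=%.2f", R_cy5),
                   velocity = attr(profile_cy5, "velocity"))
}

#' Second-peak suppression ratio of a flow profile
#'
#' Ratio of the profile's second-curtain peak to the second-curtain peak
#' of the normalized excitation profile; 1 for a non-isomerizing species,
#' < 1 when dark-state carry-over suppresses the downstream peak.
#'
#' @param profile A `"flow_profile"`.
#' @param field,flow Geometry.
#' @return Scalar ratio.
#' @export
second_peak_ratio <- function(profile, field, flow) {
  t_split <- mean(field$centers) / flow$velocity
  phi <- excitation_time_profile(field, flow, profile$t_s)
  phi_hat <- normalize_first_peak(profile$t_s, phi, field, flow)
  sel <- profile$t_s > t_split
  max(profile$f_norm[sel]) / max(phi_hat[sel])
}

#' Fit flow-TRAST profiles
#'
#' Global Levenberg-Marquardt fit of one or more flow profiles with the
#' excitation cross sections, back-isomerization cross section and
#' isomerization rate fixed (e.g. to values determined by FCS), the
#' thermal back-isomerization rate `k_biso_th` fitted globally across all
#' profiles, and (for mixtures) one fraction `R` per profile.
#'
#' @param profiles List of `"flow_profile"` objects.
#' @param fields List of [curtain_field()] (recycled if one).
#' @param flows List of [flow_config()], one per profile.
#' @param model Template [iso_model()] carrying the fixed parameters.
#' @param Q_ratio Brightness ratio for mixtures; `NULL` for pure
#'   isomerizing-species profiles (no fractions fitted).
#' @param fit_R If `TRUE` (default when `Q_ratio` is given), one fraction
#'   per profile is fitted; pure profiles fit only `k_biso_th`.
#' @param k_biso_th_start Start value (1/s).
#' @param wavelength Excitation wavelength (nm).
#' @return A `"flow_fit"` with coefficients `k_biso_th` (and `R_i`).
#' @export
fit_flow <- function(profiles, fields, flows, model, Q_ratio = NULL,
                     fit_R = !is.null(Q_ratio), k_biso_th_start = 1e3,
                     wavelength = 638) {
  n <- length(profiles)
  if (inherits(fields, "curtain_field")) fields <- list(fields)
  if (length(fields) == 1) fields <- rep(fields, n)
  if (inherits(flows, "flow_config")) flows <- list(flows)
  stopifnot(length(flows) == n)
  model_profile <- function(k_th, R, i) {
    m <- model
    m$k_biso_th <- k_th
    pc <- predict_profile(m, fields[[i]], flows[[i]],
                          t_grid = profiles[[i]]$t_s,
                          wavelength = wavelength)
    if (is.null(Q_ratio)) return(pc$f_norm)
    pf <- predict_profile("non_isomerizing", fields[[i]], flows[[i]],
                          t_grid = profiles[[i]]$t_s,
                          wavelength = wavelength)
    mixture_profile(R, Q_ratio, pc, pf, fields[[i]], flows[[i]])$f_norm
  }
  if (fit_R) {
    par0 <- c(log10(k_biso_th_start), rep(0.5, n))
    lower <- c(-2, rep(0, n)); upper <- c(6, rep(1, n))
  } else {
    par0 <- log10(k_biso_th_start); lower <- -2; upper <- 6
  }
  resid_fun <- function(par) {
    k_th <- 10^par[1]
    R <- if (fit_R) par[-1] else rep(1, n)
    unlist(lapply(seq_len(n), function(i)
      profiles[[i]]$f_norm - model_profile(k_th, R[i], i)))
  }
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  nms <- if (fit_R) c("k_biso_th", paste0("R_", seq_len(n))) else "k_biso_th"
  pp <- nlslm_pars(res, nms)
  est <- pp$coef; se <- pp$se
  est[1] <- 10^est[1]
  se[1] <- log(10) * est[1] * se[1]
  fitted_all <- unlist(lapply(seq_len(n), function(i)
    model_profile(est[1], if (fit_R) est[1 + i] else 1, i)))
  obs <- unlist(lapply(profiles, function(p) p$f_norm))
  new_tk_fit("flow_fit", est, se,
             residuals = obs - fitted_all, fitted = fitted_all,
             data = profiles, converged = pp$converged,
             message = pp$message,
             model = sprintf("Flow-TRAST %s fit (%d profiles)",
                             if (fit_R) "mixture" else "kinetics", n))
}
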