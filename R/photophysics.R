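# Fluorophore state models and excitation-driven effective rates.
#
# Two schemes are supported:
#   * isomerization: fluorescent all-trans state N <-> dark cis photoisomer P,
#     with excitation-driven forward and backward transitions plus a thermal
#     back-isomerization channel (cyanines such as Cy5);
#   * triplet: emissive singlet manifold S <-> dark triplet T, with
#     excitation-driven intersystem crossing and a fixed triplet decay rate
#     (rhodamines such as CF640R).
#
# Cross sections are stored in cm^2, irradiance in W/cm^2, rates in 1/s.

# CODATA constants; hc in J*m.
.PLANCK_H <- 6.62607015e-34
.LIGHT_C <- 2.99792458e8
.HC <- .PLANCK_H * .LIGHT_C

#' Excitation condition
#'
#' Bundle an excitation irradiance and wavelength. Irradiance is the local
#' time-averaged excitation intensity \eqn{\Phi_{exc}} in W/cm^2; wavelength
#' is in nm.
#'
#' @param irradiance Excitation irradiance (W/cm^2), >= 0.
#' @param wavelength Excitation wavelength (nm), in [300, 1000].
#' @return An object of class `"excitation"`.
#' @examples
#' excitation(16e3, 640)
#' @export
excitation <- function(irradiance, wavelength = 638) {
  stopifnot(is.numeric(irradiance), length(irradiance) == 1L,
            is.numeric(wavelength), length(wavelength) == 1L)
  if (irradiance < 0) stop("irradiance must be >= 0")
  if (wavelength < 300 || wavelength > 1000)
    stop("wavelength must be between 300 and 1000 nm")
  structure(list(irradiance = irradiance, wavelength = wavelength),
            class = "excitation")
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("Excitation: %.4g kW/cm^2 at %g nm\n",
              x$irradiance / 1e3, x$wavelength))
  invisible(x)
}

#' Photon flux per unit area
#'
#' Convert an irradiance into a photon flux (photons cm^-2 s^-1) at the
#' excitation wavelength: \eqn{\Phi \lambda / (h c)}.
#'
#' @param exc An [excitation()] object.
#' @return Photon flux (photons cm^-2 s^-1).
#' @export
photon_flux <- function(exc) {
  stopifnot(inherits(exc, "excitation"))
  exc$irradiance * (exc$wavelength * 1e-9) / .HC
}

#' Excitation (photon absorption) rate
#'
#' The rate at which a chromophore with absorption cross section `sigma`
#' absorbs photons: \eqn{k_{exc} = \sigma \Phi \lambda / (h c)}. Linear in
#' both the cross section and the irradiance.
#'
#' @param sigma Absorption cross section (cm^2), >= 0.
#' @param exc An [excitation()] object.
#' @return Excitation rate (1/s).
#' @examples
#' excitation_rate(6.2e-16, excitation(16e3, 640)) # ~3.2e7 /s
#' @export
excitation_rate <- function(sigma, exc) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("sigma must be >= 0")
  sigma * photon_flux(exc)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name))
  x
}

#' Trans-cis isomerization fluorophore model
#'
#' Two-state scheme with a fluorescent all-trans state N and a dark cis
#' photoisomer P. Forward isomerization proceeds from the excited singlet of
#' N at rate `k_iso`; back-isomerization is lumped into a single effective
#' cross section `sigma_biso` (the individual cis-state cross section, its
#' excited-state decay rate and back-isomerization rate are not separately
#' identifiable) plus a thermal rate `k_biso_th`. An optional triplet branch
#' (`k_isc`, `k_T`) models the minor triplet buildup seen at high irradiance.
#'
#' @param sigma_N Excitation cross section of N (cm^2).
#' @param k_iso Isomerization rate from S1 of N (1/s).
#' @param sigma_biso Lumped back-isomerization cross section (cm^2),
#'   must not exceed `sigma_N`.
#' @param k10 Excited-singlet decay rate of N (1/s); default 1e9
#'   (1 ns lifetime). Must exceed `k_iso`.
#' @param k_biso_th Thermal back-isomerization rate P -> N (1/s).
#' @param k_isc,k_T Optional triplet branch rates (1/s); both 0 disables it.
#' @param name Optional label.
#' @return An object of class `c("iso_model", "fluorophore_model")`.
#' @seealso [triplet_model()], [fluorophore()] for shipped presets.
#' @examples
#' iso_model(sigma_N = 6.2e-16, k_iso = 29e6, sigma_biso = 0.15e-16)
#' @export
iso_model <- function(sigma_N, k_iso, sigma_biso, k10 = 1e9, k_biso_th = 0,
                      k_isc = 0, k_T = 0, name = "isomerization") {
  .check_nonneg(sigma_N, "sigma_N")
  .check_nonneg(k_iso, "k_iso")
  .check_nonneg(sigma_biso, "sigma_biso")
  .check_nonneg(k10, "k10")
  .check_nonneg(k_biso_th, "k_biso_th")
  .check_nonneg(k_isc, "k_isc")
  .check_nonneg(k_T, "k_T")
  if (k10 <= k_iso) stop("k10 must exceed k_iso (fluorescence decay dominates)")
  if (sigma_biso > sigma_N) stop("sigma_biso must not exceed sigma_N")
  structure(list(name = name, scheme = "isomerization",
                 sigma_N = sigma_N, k_iso = k_iso, sigma_biso = sigma_biso,
                 k10 = k10, k_biso_th = k_biso_th, k_isc = k_isc, k_T = k_T),
            class = c("iso_model", "fluorophore_model"))
}

#' Triplet-crossing fluorophore model
#'
#' Two-state scheme with an emissive singlet manifold S (S0 + S1) and a dark
#' triplet T, populated by intersystem crossing from S1 and decaying back to
#' S0 at an excitation-independent rate.
#'
#' @param sigma_S Ground-singlet excitation cross section (cm^2).
#' @param k_isc Intersystem crossing rate from S1 (1/s); must be < `k10`.
#' @param k_T Triplet decay rate (1/s).
#' @param k10 S1 -> S0 decay rate (1/s).
#' @param name Optional label.
#' @return An object of class `c("triplet_model", "fluorophore_model")`.
#' @examples
#' triplet_model(sigma_S = 4e-16, k_isc = 0.7e6, k_T = 0.5e6)
#' @export
triplet_model <- function(sigma_S, k_isc, k_T, k10 = 1e9, name = "triplet") {
  .check_nonneg(sigma_S, "sigma_S")
  .check_nonneg(k_isc, "k_isc")
  .check_nonneg(k_T, "k_T")
  .check_nonneg(k10, "k10")
  if (k_isc >= k10) stop("k_isc must be smaller than k10")
  structure(list(name = name, scheme = "triplet",
                 sigma_S = sigma_S, k_isc = k_isc, k_T = k_T, k10 = k10),
            class = c("triplet_model", "fluorophore_model"))
}

#' @export
print.fluorophore_model <- function(x, ...) {
  cat(sprintf("Fluorophore model '%s' (%s scheme)\n", x$name, x$scheme))
  if (x$scheme == "isomerization") {
    cat(sprintf("  sigma_N    = %.3g cm^2\n", x$sigma_N))
    cat(sprintf("  k_iso      = %.3g us^-1\n", x$k_iso / 1e6))
    cat(sprintf("  sigma_biso = %.3g cm^2\n", x$sigma_biso))
    cat(sprintf("  k_biso_th  = %.3g us^-1\n", x$k_biso_th / 1e6))
    if (x$k_isc > 0)
      cat(sprintf("  triplet branch: k_isc = %.3g us^-1, k_T = %.3g us^-1\n",
                  x$k_isc / 1e6, x$k_T / 1e6))
  } else {
    cat(sprintf("  sigma_S = %.3g cm^2\n", x$sigma_S))
    cat(sprintf("  k_isc   = %.3g us^-1\n", x$k_isc / 1e6))
    cat(sprintf("  k_T     = %.3g us^-1\n", x$k_T / 1e6))
  }
  cat(sprintf("  k10 = %.3g s^-1\n", x$k10))
  invisible(x)
}

#' Effective isomerization and back-isomerization rates
#'
#' Effective ground-state rates between N and P under constant excitation:
#' \deqn{k'_{iso} = \frac{k_{exc}}{k_{exc} + k_{10}} k_{iso}, \qquad
#'       k'_{biso} = \sigma_{biso} \Phi \lambda/(hc) + k_{biso}^{Th}.}
#' The forward rate saturates at `k_iso`; the backward rate tends to the
#' thermal rate as the irradiance vanishes.
#'
#' @param model An [iso_model()].
#' @param exc An [excitation()] object.
#' @return Named numeric vector `c(k_iso_eff=, k_biso_eff=)` (1/s).
#' @export
effective_iso_rates <- function(model, exc) {
  stopifnot(inherits(model, "iso_model"))
  k_exc <- excitation_rate(model$sigma_N, exc)
  k_iso_eff <- if (k_exc == 0) 0 else k_exc / (k_exc + model$k10) * model$k_iso
  k_biso_eff <- model$sigma_biso * photon_flux(exc) + model$k_biso_th
  c(k_iso_eff = unname(k_iso_eff), k_biso_eff = unname(k_biso_eff))
}

#' Effective intersystem crossing rate
#'
#' \deqn{k'_{isc} = \frac{k_{exc}}{k_{exc} + k_{10}} k_{isc}} for a triplet
#' model; tends to `k_isc` in saturation and to 0 at zero irradiance.
#'
#' @param model A [triplet_model()].
#' @param exc An [excitation()] object.
#' @return Effective intersystem crossing rate (1/s).
#' @export
effective_isc_rate <- function(model, exc) {
  stopifnot(inherits(model, "triplet_model"))
  k_exc <- excitation_rate(model$sigma_S, exc)
  if (k_exc == 0) return(0)
  k_exc / (k_exc + model$k10) * model$k_isc
}

# Effective on/off rates of the dark state for either scheme: k_on drives
# bright -> dark, k_off drives dark -> bright.
dark_rates <- function(model, exc) {
  if (inherits(model, "iso_model")) {
    r <- effective_iso_rates(model, exc)
    c(k_on = unname(r["k_iso_eff"]), k_off = unname(r["k_biso_eff"]))
  } else if (inherits(model, "triplet_model")) {
    c(k_on = effective_isc_rate(model, exc), k_off = model$k_T)
  } else stop("not a fluorophore model")
}

#' Steady-state dark fraction
#'
#' Closed-form stationary dark-state occupancy of the two-state kinetics,
#' `k_on / (k_on + k_off)`, where `k_on` is the effective bright-to-dark rate
#' (isomerization or intersystem crossing) and `k_off` the dark-to-bright
#' rate at the given excitation.
#'
#' @param model An [iso_model()] or [triplet_model()].
#' @param exc An [excitation()] object.
#' @return Dark-state fraction in [0, 1].
#' @examples
#' steady_state(fluorophore("Cy5_free"), excitation(16e3, 640)) # ~0.54
#' @export
steady_state <- function(model, exc) {
  r <- dark_rates(model, exc)
  if (sum(r) == 0) stop("all rates are zero; steady state undefined")
  unname(r["k_on"] / sum(r))
}

# 3-state rate matrix (N, P, T) for an isomerization model with a triplet
# branch, at fixed excitation. Columns are source states.
iso_triplet_rate_matrix <- function(model, exc) {
  r <- effective_iso_rates(model, exc)
  k_exc <- excitation_rate(model$sigma_N, exc)
  k_isc_eff <- if (k_exc == 0) 0 else k_exc / (k_exc + model$k10) * model$k_isc
  kon <- unname(r["k_iso_eff"]); koff <- unname(r["k_biso_eff"])
  matrix(c(-(kon + k_isc_eff), kon,  k_isc_eff,
           koff,              -koff, 0,
           model$k_T,          0,   -model$k_T),
         nrow = 3, byrow = FALSE,
         dimnames = list(c("bright", "dark", "triplet"), NULL))
}

#' Time evolution of bright/dark occupancies
#'
#' Relaxation of the state populations after excitation is switched on at
#' t = 0 with the fluorophore initially fully bright. For the two-state
#' schemes the analytic solution is used: the bright occupancy is
#' \eqn{S(t) = S_\infty + (1 - S_\infty) e^{-t/\tau}} with
#' \eqn{\tau = 1/(k_{on}+k_{off})}. For an isomerization model with a
#' triplet branch, the 3-state master equation is solved by matrix
#' exponential when `triplet_extension` is active (by default only above
#' `triplet_threshold` irradiance, where the triplet buildup matters).
#'
#' @param model An [iso_model()] or [triplet_model()].
#' @param exc An [excitation()] object.
#' @param t_grid Sorted non-negative times (s).
#' @param triplet_extension One of `"auto"`, `"on"`, `"off"`. `"auto"`
#'   enables the 3-state branch when the model carries triplet rates and the
#'   irradiance exceeds `triplet_threshold`.
#' @param triplet_threshold Irradiance (W/cm^2) above which `"auto"` enables
#'   the triplet branch; default 1e5 (100 kW/cm^2).
#' @return Matrix with one row per time and columns `bright`, `dark`
#'   (and `triplet` for the 3-state branch); rows sum to 1.
#' @export
evolve_population <- function(model, exc, t_grid,
                              triplet_extension = c("auto", "on", "off"),
                              triplet_threshold = 1e5) {
  triplet_extension <- match.arg(triplet_extension)
  stopifnot(is.numeric(t_grid))
  if (is.unsorted(t_grid)) stop("t_grid must be sorted increasing")
  if (any(t_grid < 0)) stop("t_grid must be non-negative")

  use3 <- inherits(model, "iso_model") && model$k_isc > 0 &&
    (triplet_extension == "on" ||
       (triplet_extension == "auto" && exc$irradiance > triplet_threshold))
  if (use3) {
    K <- iso_triplet_rate_matrix(model, exc)
    p0 <- c(1, 0, 0)
    out <- t(vapply(t_grid, function(t)
      as.numeric(Matrix::expm(K * t) %*% p0), numeric(3)))
    colnames(out) <- c("bright", "dark", "triplet")
    return(out)
  }
  r <- dark_rates(model, exc)
  tot <- sum(r)
  s_inf <- if (tot == 0) 1 else unname(r["k_off"]) / tot
  bright <- s_inf + (1 - s_inf) * exp(-tot * t_grid)
  cbind(bright = bright, dark = 1 - bright)
}
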