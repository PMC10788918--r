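# Synthetic-data generation with known ground truth for all four
# modalities. Every generator is deterministic under a fixed integer seed.
#
# Shot noise is applied to expected photon counts and the noisy values are
# then renormalized, mirroring how a real TRAST normalization divides a
# noisy point by the (equally noisy) reference point.

#' Synthetic TRAST curve with shot noise
#'
#' Forward-models a TRAST curve ([trast_curve()] or
#' [mixture_trast_curve()]), converts each point to an expected photon
#' count via the photon budget, draws Poisson counts, and renormalizes
#' the noisy curve at `w0`.
#'
#' @param object A fluorophore model or [monoexp_params()].
#' @param exc [excitation()] for fluorophore models.
#' @param widths Pulse widths (s).
#' @param w0 Reference width.
#' @param photon_budget Expected counts per point at unit normalized
#'   value; `Inf` for a noiseless curve.
#' @param seed Integer seed.
#' @return List with `curve` (a `"trast_curve"` with `sd` from Poisson
#'   propagation) and `truth` (the noiseless curve and generating
#'   parameters).
#' @export
synth_trast_curve <- function(object, exc = NULL, widths = trast_widths(),
                              w0 = min(widths), photon_budget = 1e5,
                              seed = 1) {
  # the generator renormalizes its own exact forward model, so residual
  # dark buildup at w0 introduces no bias here; the user-facing warning
  # threshold is left to analysis-side calls
  clean <- trast_curve(object, exc, widths, w0, w0_tol = Inf)
  p <- as_monoexp(object, exc)
  if (!is.finite(photon_budget)) {
    curve <- clean
  } else {
    set.seed(as.integer(seed))
    lambda <- clean$value * photon_budget
    counts <- stats::rpois(length(lambda), lambda)
    ref <- counts[widths == w0]
    if (ref == 0) ref <- 1
    vals <- counts / ref
    # first-order Poisson error propagation through the ratio
    sd <- vals * sqrt(1 / pmax(counts, 1) + 1 / ref)
    sd[widths == w0] <- 0
    curve <- new_trast_curve(widths, vals, sd = sd, w0 = w0)
  }
  list(curve = curve, truth = list(A = p$A, tau = p$tau, clean = clean))
}

#' Synthetic mixture TRAST curve
#'
#' @param params_cy5 [monoexp_params()] of the relaxing species.
#' @param R_cy5,Q_ratio Mixture fraction and brightness ratio.
#' @param widths,w0,photon_budget,seed As in [synth_trast_curve()].
#' @return List with `curve` and `truth`.
#' @export
synth_mixture_trast <- function(params_cy5, R_cy5, Q_ratio,
                                widths = trast_widths(), w0 = min(widths),
                                photon_budget = 1e5, seed = 1) {
  clean <- mixture_trast_curve(params_cy5, R_cy5, Q_ratio, widths, w0)
  if (!is.finite(photon_budget)) {
    curve <- clean
  } else {
    set.seed(as.integer(seed))
    counts <- stats::rpois(length(clean$value), clean$value * photon_budget)
    ref <- counts[widths == w0]
    if (ref == 0) ref <- 1
    curve <- new_trast_curve(widths, counts / ref, w0 = w0)
  }
  list(curve = curve,
       truth = list(R_cy5 = R_cy5, Q_ratio = Q_ratio,
                    A = params_cy5$A, tau = params_cy5$tau, clean = clean))
}

#' Synthetic FCS curve with correlator-like noise
#'
#' Forward-models the dark-state FCS curve and adds lag-dependent
#' multiplicative Gaussian noise with relative standard deviation
#' `noise / sqrt(lag index)`, mimicking the larger scatter of a
#' multi-tau correlator at short lags.
#'
#' @param model Fluorophore model (with `exc`), or an [fcs_params()]
#'   directly.
#' @param exc [excitation()] (for fluorophore models).
#' @param n_mol,tau_d,structure Diffusion parameters used when `model` is
#'   a fluorophore model.
#' @param lags Lag grid (s).
#' @param noise Relative noise level at the first lag (0 = noiseless).
#' @param seed Integer seed.
#' @return List with `curve` (an `"fcs_curve"`) and `truth` (clean curve
#'   + generating dark-state terms).
#' @export
synth_fcs_curve <- function(model, exc = NULL, n_mol = 1, tau_d = 1e-4,
                            structure = 5, lags = fcs_lag_grid(),
                            noise = 0.02, seed = 1) {
  if (inherits(model, "fluorophore_model")) {
    dt <- dark_terms_from_model(model, exc)
    params <- fcs_params(n_mol, tau_d, unname(dt["a_dark"]),
                         unname(dt["tau_dark"]), structure)
  } else if (inherits(model, "fcs_params")) {
    params <- model
  } else stop("expected a fluorophore model or fcs_params")
  clean <- fcs_model(params, lags)
  g <- clean$g
  if (noise > 0) {
    set.seed(as.integer(seed))
    rel <- noise / sqrt(seq_along(lags))
    g <- g * (1 + stats::rnorm(length(g), 0, rel))
  }
  list(curve = new_fcs_curve(lags, g, sd = clean$g * noise /
                               sqrt(seq_along(lags))),
       truth = list(params = params, clean = clean))
}

#' Synthetic flow-TRAST profile
#'
#' Forward-models a flow profile (pure species or mixture) and adds
#' additive Gaussian noise scaled to the unit first-curtain peak.
#'
#' @param model [iso_model()] or `"non_isomerizing"`.
#' @param field,flow Geometry ([curtain_field()], [flow_config()]).
#' @param R_cy5,Q_ratio If not `NULL`, generate a mixture of `model` and
#'   a non-isomerizing species with these parameters.
#' @param noise Additive noise SD relative to the first peak.
#' @param seed Integer seed.
#' @param wavelength Excitation wavelength (nm).
#' @return List with `profile` and `truth`.
#' @export
synth_flow_profile <- function(model, field, flow, R_cy5 = NULL,
                               Q_ratio = NULL, noise = 0.01, seed = 1,
                               wavelength = 638) {
  clean <- if (!is.null(R_cy5)) {
    pc <- predict_profile(model, field, flow, wavelength = wavelength)
    pf <- predict_profile("non_isomerizing", field, flow,
                          t_grid = pc$t_s, wavelength = wavelength)
    mixture_profile(R_cy5, Q_ratio, pc, pf, field, flow)
  } else {
    predict_profile(model, field, flow, wavelength = wavelength)
  }
  f <- clean$f_norm
  if (noise > 0) {
    set.seed(as.integer(seed))
    f <- f + stats::rnorm(length(f), 0, noise)
  }
  prof <- new_flow_profile(clean$t_s, f, label = attr(clean, "label"),
                           velocity = attr(clean, "velocity"))
  list(profile = prof,
       truth = list(clean = clean, R_cy5 = R_cy5, Q_ratio = Q_ratio,
                    k_biso_th = if (inherits(model, "iso_model"))
                      model$k_biso_th else NA_real_))
}

#' Synthetic dual-label cell image stack
#'
#' Emulates a TRAST image stack of an immunostained cell carrying two
#' labels with distinct dark-state kinetics: a nuclear-rim (ring)
#' structure labeled with a fast, low-amplitude triplet-like species and
#' a filament structure labeled with a slow, high-amplitude
#' isomerization-like species. Per-pixel monoexponential ground truth
#' (species identity, A, tau, intensity) is emitted alongside the
#' Poisson-noisy frames.
#'
#' @param size Image side length in pixels.
#' @param widths Pulse widths (s).
#' @param w0 Reference width.
#' @param species1,species2 Lists `list(A=, tau=)` for the filament
#'   (Cy5-like; default A 0.45, tau 30 us) and rim (AS635-like; default
#'   A 0.2, tau 2 us) labels.
#' @param photon_budget Expected per-pixel counts per frame on the
#'   structures at unit model value; `Inf` disables noise.
#' @param background Expected background counts per pixel per frame.
#' @param overlap Fraction of structure pixels where both labels overlap
#'   (mixed pixels); 0 keeps the two structures disjoint.
#' @param label `"both"` (dual-labeled cell), or `"species1"` /
#'   `"species2"` for mono-labeled reference samples (the other structure
#'   is left unstained).
#' @param seed Integer seed.
#' @return List with `stack` (a [trast_stack()]), and `truth` (matrices
#'   `R1` — fraction of species 1 —, `A`, `tau`, `intensity`, plus the
#'   species parameters).
#' @export
synth_cell_stack <- function(size = 48, widths = trast_widths(),
                             w0 = min(widths),
                             species1 = list(A = 0.45, tau = 30e-6),
                             species2 = list(A = 0.2, tau = 2e-6),
                             photon_budget = 2e4, background = 20,
                             overlap = 0, label = c("both", "species1",
                                                    "species2"), seed = 1) {
  label <- match.arg(label)
  set.seed(as.integer(seed))
  h <- w <- size
  xy <- expand.grid(i = seq_len(h), j = seq_len(w))
  cx <- h / 2; cy <- w / 2
  r <- sqrt((xy$i - cx)^2 + (xy$j - cy)^2)
  rim <- matrix(r > size * 0.28 & r < size * 0.36, h, w)    # nuclear rim
  fil <- matrix(FALSE, h, w)                                # filaments
  for (off in round(seq(-size * 0.35, size * 0.35, length.out = 5))) {
    d <- abs((xy$i - cx) - 0.7 * (xy$j - cy) - off)
    fil <- fil | matrix(d < 1.2 & r > size * 0.38, h, w)
  }
  both <- rim & fil
  if (overlap == 0) rim[both] <- FALSE
  if (label == "species1") rim[] <- FALSE
  if (label == "species2") fil[] <- FALSE
  R1 <- matrix(NA_real_, h, w)
  R1[fil] <- 1
  R1[rim & !fil] <- 0
  # per-pixel intensity: brightness variation on the structures
  intens <- matrix(0, h, w)
  n_struct <- sum(fil | rim)
  scale <- if (is.finite(photon_budget)) photon_budget else 1
  intens[fil | rim] <- scale * stats::runif(n_struct, 0.6, 1.4)
  A_map <- matrix(NA_real_, h, w)
  tau_map <- matrix(NA_real_, h, w)
  A_map[fil] <- species1$A; tau_map[fil] <- species1$tau
  A_map[rim & !fil] <- species2$A; tau_map[rim & !fil] <- species2$tau
  frames <- array(0, dim = c(h, w, length(widths)))
  for (k in seq_along(widths)) {
    m <- matrix(1, h, w)
    on <- !is.na(A_map)
    m[on] <- 1 - A_map[on] +
      A_map[on] * (tau_map[on] / widths[k]) *
        (-expm1(-widths[k] / tau_map[on]))
    lambda <- intens * m + background
    frames[, , k] <- if (is.finite(photon_budget))
      matrix(stats::rpois(h * w, lambda), h, w) else lambda
  }
  stack <- trast_stack(frames, widths, w0 = w0, background = background)
  list(stack = stack,
       truth = list(R1 = R1, A = A_map, tau = tau_map, intensity = intens,
                    species1 = species1, species2 = species2))
}
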